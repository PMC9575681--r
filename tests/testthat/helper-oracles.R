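# Independent brute-force oracles and fixture builders used across tests.

# Brute-force transition table: walk every adjacent pair of every candidate
# with a plain double loop, then normalise. Deliberately naive and
# independent of the package's vectorised path.
oracleTransitionTable <- function(candidates) {
    nucs <- c("A", "C", "G", "T")
    counts <- matrix(0L, 4, 4, dimnames = list(nucs, nucs))
    for (s in candidates) {
        ch <- strsplit(s, "")[[1]]
        if (length(ch) < 2) next
        for (i in seq_len(length(ch) - 1)) {
            a <- match(ch[i], nucs); b <- match(ch[i + 1], nucs)
            counts[a, b] <- counts[a, b] + 1L
        }
    }
    probs <- matrix(0, 4, 4, dimnames = list(nucs, nucs))
    for (r in 1:4) {
        rs <- sum(counts[r, ])
        if (rs > 0) probs[r, ] <- counts[r, ] / rs
    }
    list(counts = counts, probs = probs)
}

randomSeq <- function(n) paste(sample(c("A", "C", "G", "T"), n,
                                      replace = TRUE), collapse = "")

# A random, internally consistent alignment hit for fuzzing the extension
# arithmetic. Query geometry: flanks of length `flank` around a gap of
# length `gapLength`.
randomHit <- function(gapStart, gapEnd, subjectLength) {
    side <- sample(c("left", "right"), 1)
    if (side == "left") {
        qe <- sample(seq(2, gapStart), 1)
        qs <- sample(seq(0, qe - 1), 1)
    } else {
        qs <- sample(seq(gapEnd, gapEnd + 200), 1)
        qe <- qs + sample(10:100, 1)
    }
    alen <- qe - qs
    ss <- sample(seq(0, max(0, subjectLength - alen)), 1)
    data.frame(queryId = "gap", subjectId = "read1",
               pident = 100, alnLength = alen,
               qstart = qs, qend = qe,
               sstart = ss, send = min(subjectLength, ss + alen),
               orientation = sample(c("forward", "reverse"), 1),
               flankSide = side, stringsAsFactors = FALSE)
}

# Small deterministic end-to-end fixture written to disk; returns paths and
# truth.
writePipelineFixture <- function(dir, genomeLength = 12000L, nGaps = 3L,
                                 seed = 11L, minLen = 40L, maxLen = 120L) {
    cfg <- simulationConfig(genomeLength = genomeLength,
                            gapSpec = list(c(nGaps, minLen, maxLen)),
                            readLengthMean = 1500L, coverage = 12,
                            errorRate = 0, seed = seed)
    ref <- simulateGenome(cfg)
    gs <- makeGappedScaffold(ref, cfg$gapSpec, seed = seed + 1L)
    reads <- simulateLongReads(ref, cfg)
    dir.create(dir, showWarnings = FALSE, recursive = TRUE)
    scafPath <- file.path(dir, "scaffold.fasta")
    readPath <- file.path(dir, "reads.fasta")
    writeFasta(gs$scaffold, scafPath)
    writeFasta(stats::setNames(as.character(reads), names(reads)), readPath)
    list(scaffolds = scafPath, reads = readPath, truth = gs$truth,
         scaffold = gs$scaffold, reference = ref, config = cfg)
}
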