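NUCS <- c("A", "C", "G", "T")

#' TransitionTable: first-order nucleotide transition matrix
#'
#' Holds the aggregated dinucleotide counts of a gap's candidate sequences
#' and the row-normalised transition probabilities. Rows index the current
#' nucleotide, columns the next, in the fixed encoding A=0, C=1, G=2, T=3
#' (stored with dimnames A/C/G/T). A row whose counts are all zero (a
#' nucleotide never observed as a predecessor, e.g. from single-base
#' candidates) stays all zero in the probability matrix rather than being
#' divided by zero.
#'
#' @slot counts 4x4 non-negative integer matrix of dinucleotide frequencies.
#' @slot probs 4x4 numeric matrix; each row sums to 1 (within 1e-9) or is
#'   all zeros.
#' @export
setClass("TransitionTable",
         representation(counts = "matrix", probs = "matrix"))

setValidity("TransitionTable", function(object) {
    co <- object@counts; pr <- object@probs
    if (!identical(dim(co), c(4L, 4L)) || !identical(dim(pr), c(4L, 4L)))
        return("counts and probs must be 4x4 matrices")
    if (any(co < 0))
        return("counts must be non-negative")
    rs <- rowSums(pr)
    if (!all(abs(rs - 1) < 1e-9 | abs(rs) < 1e-9))
        return("each probability row must sum to 1 or be all zero")
    zero <- rowSums(co) == 0
    if (any(zero & rowSums(pr) != 0))
        return("a zero count row must have a zero probability row")
    TRUE
})

#' @describeIn TransitionTable accessor for the count matrix.
#' @param x,object A `TransitionTable`.
#' @export
transitionCounts <- function(x) x@counts

#' @describeIn TransitionTable accessor for the probability matrix.
#' @export
transitionProbs <- function(x) x@probs

#' @describeIn TransitionTable compact display.
#' @export
setMethod("show", "TransitionTable", function(object) {
    cat("TransitionTable (", sum(object@counts), " observed pairs)\n",
        sep = "")
    print(round(object@probs, 3))
})

#' Encode a nucleotide as its numeric state
#'
#' Fixed encoding A=0, C=1, G=2, T=3; input is uppercased first.
#'
#' @param ch Single character.
#' @return Integer in 0..3.
#' @export
encodeNucleotide <- function(ch) {
    i <- match(toupper(ch), NUCS)
    if (is.na(i))
        stop("cannot encode nucleotide '", ch, "' (expected A, C, G or T)")
    i - 1L
}

#' Extract candidate gap sequences from extension records
#'
#' Converts BED-style intervals on the long reads into sequences: plus-strand
#' records take the read substring directly; minus-strand records take its
#' reverse complement. Results are uppercase. Candidates containing N are
#' dropped (the transition table is defined over A/C/G/T only); the number
#' dropped is attached as attribute `nDropped`.
#'
#' @param bed Extension-record data.frame ([extendAll()] output or
#'   [readBed()] with a `strand` column).
#' @param reads Named [Biostrings::DNAStringSet].
#' @param gapLength Gap length used to set the `fullLength` flag.
#' @return data.frame with columns `gapId`, `sequence`, `subjectId`,
#'   `start`, `end`, `strand`, `fullLength`; attribute `nDropped`.
#' @export
extractCandidates <- function(bed, reads, gapLength = NA_integer_) {
    seqs <- character(nrow(bed))
    for (i in seq_len(nrow(bed))) {
        j <- match(bed$subjectId[i], names(reads))
        if (is.na(j))
            stop("extension record refers to unknown read id: ",
                 bed$subjectId[i])
        s <- as.character(Biostrings::subseq(reads[[j]],
                                             bed$start[i] + 1L, bed$end[i]))
        if (bed$strand[i] == "-")
            s <- as.character(Biostrings::reverseComplement(
                Biostrings::DNAString(s)))
        seqs[i] <- toupper(s)
    }
    hasN <- grepl("[^ACGT]", seqs)
    out <- data.frame(gapId = bed$name, sequence = seqs,
                      subjectId = bed$subjectId, start = bed$start,
                      end = bed$end, strand = bed$strand,
                      stringsAsFactors = FALSE)[!hasN, , drop = FALSE]
    out$fullLength <- if (is.na(gapLength)) NA else nchar(out$sequence) == gapLength
    rownames(out) <- NULL
    attr(out, "nDropped") <- sum(hasN)
    out
}

#' Count nucleotide pair transitions in one sequence
#'
#' Tallies how often each nucleotide follows each other nucleotide in the
#' candidate: `counts[from, to]` is incremented for every adjacent pair, so
#' the total count is `nchar(seq) - 1`. A single-base candidate yields the
#' all-zero matrix.
#'
#' @param seq Candidate sequence (uppercase A/C/G/T).
#' @return 4x4 integer matrix with A/C/G/T dimnames.
#' @export
countTransitions <- function(seq) {
    counts <- matrix(0L, 4L, 4L, dimnames = list(NUCS, NUCS))
    n <- nchar(seq)
    if (n < 2L) return(counts)
    idx <- match(strsplit(toupper(seq), "", fixed = TRUE)[[1L]], NUCS)
    if (anyNA(idx))
        stop("candidate contains a non-ACGT character")
    pair <- idx[-n] + 4L * (idx[-1L] - 1L)       # from + 4*(to-1), 1..16
    # from + 4*(to-1) is exactly R's column-major index of (from, to)
    matrix(tabulate(pair, nbins = 16L), 4L, 4L,
           dimnames = list(NUCS, NUCS))
}

#' Build the aggregated transition table of a gap
#'
#' Sums the raw dinucleotide counts of every candidate sequence, then
#' normalises each row once by its total. Summing counts (rather than
#' averaging per-candidate probability tables) weights candidates by the
#' number of pairs they contribute, matching the frequency framing of the
#' construction. Rows with zero total stay all zero.
#'
#' @param candidates Character vector of candidate sequences, or the
#'   data.frame from [extractCandidates()] (its `sequence` column is used).
#' @return A [TransitionTable-class] object.
#' @export
buildTransitionTable <- function(candidates) {
    if (is.data.frame(candidates))
        candidates <- candidates$sequence
    if (length(candidates) == 0L)
        stop("no candidate sequences; gap left unfilled")
    counts <- Reduce(`+`, lapply(candidates, countTransitions))
    rs <- rowSums(counts)
    probs <- counts / ifelse(rs > 0, rs, 1)      # zero rows stay zero
    methods::new("TransitionTable", counts = counts, probs = probs)
}

#' Generate one anchored Markov sample
#'
#' Starts from the state of `lastChar` — the last (uppercased) scaffold base
#' before the gap, guaranteeing the chain is anchored in the gap's context
#' rather than at a random state — and draws `gapLength` successive states
#' from the current state's probability row. The emitted characters
#' (excluding the anchor) form the fill. If the chain reaches a state whose
#' row is all zero before `gapLength` characters are emitted, generation
#' stops and the partial sequence is returned flagged as partial.
#'
#' @param table A [TransitionTable-class].
#' @param gapLength Number of bases to generate.
#' @param lastChar Anchor character (case-insensitive A/C/G/T).
#' @return list with `sequence` (possibly shorter than `gapLength`, possibly
#'   empty) and logical `partial`.
#' @export
generateFill <- function(table, gapLength, lastChar) {
    stopifnot(gapLength >= 1L)
    state <- encodeNucleotide(lastChar) + 1L
    probs <- transitionProbs(table)
    out <- character(gapLength)
    n <- 0L
    while (n < gapLength) {
        row <- probs[state, ]
        if (sum(row) == 0) break                 # dead state: partial fill
        state <- sample.int(4L, 1L, prob = row)
        n <- n + 1L
        out[n] <- NUCS[state]
    }
    list(sequence = paste(out[seq_len(n)], collapse = ""),
         partial = n < gapLength)
}

#' Average transition cost of a sequence
#'
#' The mean of the n-1 per-step transition probabilities along an n-base
#' sequence, read off the transition table. Sequences of length < 2 have no
#' transitions and score 0 by convention.
#'
#' @param sequence Generated fill (uppercase A/C/G/T).
#' @param table A [TransitionTable-class].
#' @return Numeric in \[0, 1\].
#' @export
scoreFill <- function(sequence, table) {
    n <- nchar(sequence)
    if (n < 2L) return(0)
    idx <- match(strsplit(toupper(sequence), "", fixed = TRUE)[[1L]], NUCS)
    probs <- transitionProbs(table)
    mean(probs[cbind(idx[-n], idx[-1L])])
}

#' Fill one gap by repeated Markov sampling
#'
#' Generates `nSamples` anchored Markov samples from the gap's aggregated
#' transition table, scores each by average transition cost, and returns the
#' highest-scoring one. Sampling is repeated because generation is
#' stochastic; 5-10 repeats are used (default 8). Ties are broken by the
#' lexicographically smallest sequence, then the lowest sample index, so
#' output is deterministic under a fixed seed. Full-length fills are always
#' preferred over partial ones; a partial fill is only selected when no
#' sample reached the full gap length. A 1 bp gap is unfillable: at least
#' 2 bp are needed for a dinucleotide pattern to exist.
#'
#' @param candidates Character vector (or [extractCandidates()] data.frame)
#'   of candidate sequences.
#' @param gapLength Gap length in bases.
#' @param lastChar Anchor: last scaffold base before the gap, or `NA` when
#'   the gap has no left neighbour (then the gap is unfillable:
#'   anchor_missing).
#' @param nSamples Number of Markov samples (default 8; range 5-10 enforced
#'   unless `enforceRange = FALSE`).
#' @param seed Optional integer; when given, sampling runs in a local RNG
#'   state seeded with it (the caller's RNG is untouched).
#' @param enforceRange Enforce `5 <= nSamples <= 10` (default TRUE).
#' @return list with `status` (`"filled"`, `"partial"` or
#'   `"unfillable:<reason>"`), `sequence`, `avgCost`, `sampleIndex`,
#'   `nCandidates`.
#' @export
fillGap <- function(candidates, gapLength, lastChar, nSamples = 8L,
                    seed = NULL, enforceRange = TRUE) {
    if (is.data.frame(candidates))
        candidates <- candidates$sequence
    if (enforceRange && (nSamples < 5L || nSamples > 10L))
        stop("nSamples must be between 5 and 10")
    unfillable <- function(reason)
        list(status = paste0("unfillable:", reason), sequence = "",
             avgCost = NA_real_, sampleIndex = NA_integer_,
             nCandidates = length(candidates))
    if (gapLength == 1L)
        return(unfillable("gap_too_short"))
    if (length(candidates) == 0L)
        return(unfillable("no_candidates"))
    if (is.na(lastChar) || !nzchar(lastChar) ||
        !toupper(lastChar) %in% NUCS)
        return(unfillable("anchor_missing"))
    table <- buildTransitionTable(candidates)
    if (sum(transitionCounts(table)) == 0L)
        return(unfillable("zero_table"))
    runOne <- function() {
        samples <- vector("list", nSamples)
        for (k in seq_len(nSamples)) {
            g <- generateFill(table, gapLength, lastChar)
            samples[[k]] <- list(sequence = g$sequence, partial = g$partial,
                                 avgCost = scoreFill(g$sequence, table),
                                 sampleIndex = k)
        }
        samples
    }
    samples <- if (is.null(seed)) runOne() else withLocalSeed(seed, runOne())
    full <- Filter(function(s) !s$partial, samples)
    pool <- if (length(full)) full else
        Filter(function(s) nzchar(s$sequence), samples)
    if (!length(pool))
        return(unfillable("dead_anchor"))
    costs <- vapply(pool, `[[`, numeric(1), "avgCost")
    seqs <- vapply(pool, `[[`, character(1), "sequence")
    idxs <- vapply(pool, `[[`, integer(1), "sampleIndex")
    best <- order(-costs, seqs, idxs)[1L]
    list(status = if (length(full)) "filled" else "partial",
         sequence = seqs[best], avgCost = costs[best],
         sampleIndex = idxs[best], nCandidates = length(candidates))
}

# Run expr under a temporary RNG state seeded with `seed`, restoring the
# caller's stream afterwards.
withLocalSeed <- function(seed, expr) {
    had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
    if (had) old <- get(".Random.seed", envir = globalenv())
    on.exit(if (had) assign(".Random.seed", old, envir = globalenv())
            else if (exists(".Random.seed", envir = globalenv(),
                            inherits = FALSE))
                rm(".Random.seed", envir = globalenv()))
    set.seed(seed)
    expr
}

# Stable 31-bit string hash used to derive per-gap RNG streams from the
# master seed, so per-gap results are independent of processing order.
stableHash <- function(s) {
    h <- 0
    for (c in utf8ToInt(s)) h <- (h * 31 + c) %% 2147483647
    as.integer(h)
}

#' Derive the per-gap RNG seed
#'
#' @param masterSeed Integer master seed of the run.
#' @param gapId Gap identifier.
#' @return Integer seed below 2^31.
#' @export
gapSeed <- function(masterSeed, gapId) {
    as.integer((as.numeric(masterSeed) + stableHash(gapId)) %% 2147483647)
}
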