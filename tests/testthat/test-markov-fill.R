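detTable <- function() buildTransitionTable("ACGTACGTACGTA")  # A->C->G->T->A

test_that("nucleotide encoding is A=0 C=1 G=2 T=3, uppercased first", {
    expect_equal(vapply(c("A", "C", "G", "T"), encodeNucleotide, integer(1),
                        USE.NAMES = FALSE), 0:3)
    expect_equal(encodeNucleotide("a"), 0L)
    expect_error(encodeNucleotide("N"), "N")
})

test_that("candidate extraction honours strand and drops N", {
    reads <- Biostrings::DNAStringSet(c(r1 = "AAGGTTCC", r2 = "AAGNTTCC"))
    bed <- data.frame(subjectId = c("r1", "r1", "r2"),
                      start = c(2L, 2L, 2L), end = c(6L, 6L, 6L),
                      name = "g", strand = c("+", "-", "+"),
                      stringsAsFactors = FALSE)
    cands <- extractCandidates(bed, reads, gapLength = 4L)
    expect_equal(cands$sequence, c("GGTT", "AACC"))
    expect_equal(attr(cands, "nDropped"), 1L)
    expect_true(all(cands$fullLength))
    expect_error(extractCandidates(
        data.frame(subjectId = "nope", start = 0L, end = 2L, name = "g",
                   strand = "+", stringsAsFactors = FALSE), reads),
        "nope")
})

test_that("countTransitions tallies adjacent pairs", {
    m <- countTransitions("ACGT")
    expect_equal(sum(m), 3L)
    expect_equal(m["A", "C"], 1L)
    expect_equal(m["C", "G"], 1L)
    expect_equal(m["G", "T"], 1L)

    expect_equal(sum(countTransitions("A")), 0L)
    m <- countTransitions("AAAA")
    expect_equal(m["A", "A"], 3L)
    expect_equal(sum(m), 3L)
})

test_that("buildTransitionTable normalises rows, zero rows stay zero", {
    tt <- buildTransitionTable(c("ACGT", "ACGT"))
    p <- transitionProbs(tt)
    expect_equal(p["A", "C"], 1)
    expect_equal(p["C", "G"], 1)
    expect_equal(p["G", "T"], 1)
    expect_equal(unname(rowSums(p)["T"]), 0)

    tt <- buildTransitionTable(c("AA", "AC"))
    p <- transitionProbs(tt)
    expect_equal(p["A", "A"], 0.5)
    expect_equal(p["A", "C"], 0.5)
    expect_equal(sum(p[c("C", "G", "T"), ]), 0)

    expect_equal(sum(transitionProbs(buildTransitionTable("G"))), 0)
    expect_error(buildTransitionTable(character(0)), "no candidate")
})

test_that("transition tables match the brute-force oracle on random sets", {
    set.seed(340)
    for (i in 1:100) {
        cands <- vapply(seq_len(sample(1:20, 1)),
                        function(j) randomSeq(sample(1:50, 1)), character(1))
        tt <- buildTransitionTable(cands)
        oracle <- oracleTransitionTable(cands)
        expect_identical(unname(transitionCounts(tt)) + 0L,
                         unname(oracle$counts))
        expect_lt(max(abs(transitionProbs(tt) - oracle$probs)), 1e-12)
    }
})

test_that("probability rows sum to 1 or 0 for every constructed table", {
    set.seed(341)
    for (i in 1:50) {
        cands <- vapply(seq_len(sample(1:10, 1)),
                        function(j) randomSeq(sample(1:30, 1)), character(1))
        rs <- rowSums(transitionProbs(buildTransitionTable(cands)))
        expect_true(all(abs(rs - 1) < 1e-9 | rs == 0))
    }
})

test_that("TransitionTable validity rejects malformed objects", {
    tt <- detTable()
    expect_error(methods::new("TransitionTable",
                              counts = transitionCounts(tt),
                              probs = transitionProbs(tt) * 2),
                 "sum to 1")
    expect_s4_class(tt, "TransitionTable")
    expect_output(show(tt), "TransitionTable")
})

test_that("a deterministic chain reproduces its cycle from any anchor", {
    tt <- detTable()
    expect_equal(generateFill(tt, 4L, "A")$sequence, "CGTA")
    expect_equal(generateFill(tt, 8L, "T")$sequence, "ACGTACGT")
    expect_false(generateFill(tt, 8L, "T")$partial)

    # dead state: anchor row all zero -> empty partial fill
    tt2 <- buildTransitionTable("CGCGCG")           # A row is zero
    g <- generateFill(tt2, 5L, "A")
    expect_equal(g$sequence, "")
    expect_true(g$partial)
})

test_that("scoreFill averages the n-1 transition probabilities", {
    tt <- detTable()
    expect_equal(scoreFill("CGTA", tt), 1)
    expect_equal(scoreFill("A", tt), 0)
    ttA <- buildTransitionTable(c("AA", "AC"))      # A->A 0.5, A->C 0.5
    expect_equal(scoreFill("AAAA", ttA), 0.5)
})

test_that("fillGap selects the best sample and handles edge contracts", {
    # 1 bp gaps are unfillable whatever the candidates
    f <- fillGap(c("A", "C"), 1L, "A")
    expect_equal(f$status, "unfillable:gap_too_short")

    f <- fillGap(character(0), 10L, "A")
    expect_equal(f$status, "unfillable:no_candidates")

    f <- fillGap("ACGTACGT", 10L, NA_character_)
    expect_equal(f$status, "unfillable:anchor_missing")

    f <- fillGap(c("A", "C", "G"), 5L, "A")        # only 1-nt candidates
    expect_equal(f$status, "unfillable:zero_table")

    # deterministic table: every sample identical, cost exactly 1
    f <- fillGap("ACGTACGTACGTA", 4L, "A", seed = 1L)
    expect_equal(f$status, "filled")
    expect_equal(f$sequence, "CGTA")
    expect_equal(f$avgCost, 1)

    expect_error(fillGap("ACGT", 4L, "A", nSamples = 3L), "between 5 and 10")
})

test_that("fillGap is bit-reproducible under a fixed seed", {
    cands <- c("AACAAGAATAAC", "AAGAACAATAAG")
    a <- fillGap(cands, 20L, "A", seed = 99L)
    b <- fillGap(cands, 20L, "A", seed = 99L)
    expect_identical(a, b)
    # per-gap seeds derived from the master seed are stable
    expect_identical(gapSeed(42L, "s_gap1"), gapSeed(42L, "s_gap1"))
    expect_false(gapSeed(42L, "s_gap1") == gapSeed(42L, "s_gap2"))
})

test_that("partial fills are only selected when no full sample exists", {
    # C row is zero: chains anchored at A die once they emit C
    cands <- c("AC", "AA")                           # A->{A,C}, C dead
    f <- fillGap(cands, 6L, "A", seed = 3L)
    expect_true(f$status %in% c("filled", "partial"))
    if (f$status == "partial")
        expect_lt(nchar(f$sequence), 6L)
})
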