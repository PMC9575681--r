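mkHit <- function(flankSide, orientation, qstart = 0L, qend = 10L,
                  sstart = 0L, send = 10L)
    data.frame(queryId = "gap1", subjectId = "read1", pident = 100,
               alnLength = qend - qstart, qstart = qstart, qend = qend,
               sstart = sstart, send = send, orientation = orientation,
               flankSide = flankSide, stringsAsFactors = FALSE)

test_that("left extension follows the index formulas with clamping", {
    # forward: new_start = sstart - (gapLength + (qstart - gapEnd))
    r <- leftExtend(mkHit("right", "forward", qstart = 25L, sstart = 100L),
                    gapStart = 10L, gapEnd = 20L, gapLength = 10L,
                    subjectLength = 1000L)
    expect_equal(c(r$start, r$end), c(85L, 95L))
    expect_false(r$clamped)
    expect_equal(r$strand, "+")

    # forward with the start clamped at the read boundary
    r <- leftExtend(mkHit("right", "forward", qstart = 25L, sstart = 5L),
                    gapStart = 10L, gapEnd = 20L, gapLength = 10L,
                    subjectLength = 1000L)
    expect_equal(c(r$start, r$end), c(0L, 10L))
    expect_true(r$clamped)

    # reverse: new_end = send + (gapLength + (qstart - gapEnd)), clamped
    r <- leftExtend(mkHit("right", "reverse", qstart = 25L, send = 995L),
                    gapStart = 10L, gapEnd = 20L, gapLength = 10L,
                    subjectLength = 1000L)
    expect_equal(c(r$start, r$end), c(990L, 1000L))
    expect_true(r$clamped)
    expect_equal(r$strand, "-")

    expect_error(leftExtend(mkHit("left", "forward"), 10L, 20L, 10L, 100L),
                 "right-flank")
})

test_that("right extension follows the index formulas with clamping", {
    # forward: new_start = send + (gapStart - qend)
    r <- rightExtend(mkHit("left", "forward", qend = 10L, send = 200L),
                     gapStart = 10L, gapEnd = 20L, gapLength = 10L,
                     subjectLength = 1000L)
    expect_equal(c(r$start, r$end), c(200L, 210L))
    expect_false(r$clamped)

    # alignment ends short of the gap: interval shifts by the offset
    r <- rightExtend(mkHit("left", "forward", qend = 8L, send = 200L),
                     gapStart = 10L, gapEnd = 20L, gapLength = 10L,
                     subjectLength = 1000L)
    expect_equal(c(r$start, r$end), c(202L, 212L))

    # forward near the read end: end clamps to the subject length
    r <- rightExtend(mkHit("left", "forward", qend = 10L, send = 995L),
                     gapStart = 10L, gapEnd = 20L, gapLength = 10L,
                     subjectLength = 1000L)
    expect_equal(c(r$start, r$end), c(995L, 1000L))
    expect_true(r$clamped)

    expect_error(rightExtend(mkHit("right", "forward"), 10L, 20L, 10L, 100L),
                 "left-flank")
})

test_that("extendAll maps every classified hit and keeps counts", {
    reads <- Biostrings::DNAStringSet(
        stats::setNames(rep(strrep("A", 1000), 5), paste0("r", 1:5)))
    hits <- do.call(rbind, c(
        lapply(1:2, function(i)
            mkHit("left", "forward", qstart = 400L, qend = 500L,
                  sstart = 300L, send = 400L)),
        lapply(3:5, function(i)
            mkHit("right", "forward", qstart = 560L, qend = 660L,
                  sstart = 500L, send = 600L))))
    hits$subjectId <- paste0("r", 1:5)
    bed <- extendAll(hits, 500L, 550L, 50L, reads)
    expect_equal(nrow(bed), 5L)
    expect_true(all(bed$end - bed$start == 50L))

    empty <- extendAll(hits[0, ], 500L, 550L, 50L, reads)
    expect_equal(nrow(empty), 0L)
})

test_that("a spanning hit maps to a gap-sized interval on the read", {
    reads <- Biostrings::DNAStringSet(c(r1 = strrep("A", 1000)))
    hit <- mkHit("spanning", "forward", qstart = 450L, qend = 700L,
                 sstart = 100L, send = 350L)
    hit$subjectId <- "r1"
    bed <- extendAll(hit, 500L, 550L, 50L, reads)
    expect_equal(nrow(bed), 1L)
    expect_equal(c(bed$start, bed$end), c(150L, 200L))
})

test_that("extension of an error-free read recovers the true gap interval", {
    set.seed(330)
    ref <- randomSeq(2000)
    gapStart <- 900L; gapLen <- 80L                 # 0-based on ref
    truth <- substr(ref, gapStart + 1, gapStart + gapLen)
    gap <- list(leftFlank = substr(ref, gapStart - 199, gapStart),
                rightFlank = substr(ref, gapStart + gapLen + 1,
                                    gapStart + gapLen + 200),
                gapLength = gapLen)
    q <- buildGapQuery(gap)
    readStart <- 600L                                # 0-based on ref
    reads <- Biostrings::DNAStringSet(
        c(r1 = substr(ref, readStart + 1, readStart + 1000)))
    hits <- filterHits(alignGapRegion(q$query, reads, filterParams()),
                       q$gapStart, q$gapEnd)
    bed <- extendAll(hits, q$gapStart, q$gapEnd, gapLen, reads)
    expect_gte(nrow(bed), 1L)
    cands <- extractCandidates(bed, reads, gapLen)
    expect_true(all(cands$sequence == toupper(truth)))
})

test_that("fuzzed extensions always stay inside the read", {
    set.seed(331)
    gapStart <- 300L; gapEnd <- 400L; gapLength <- 100L
    for (i in 1:1000) {
        L <- sample(150:2000, 1)
        hit <- randomHit(gapStart, gapEnd, L)
        rec <- if (hit$flankSide == "left")
            rightExtend(hit, gapStart, gapEnd, gapLength, L)
        else leftExtend(hit, gapStart, gapEnd, gapLength, L)
        if (is.null(rec)) next                       # interval fully clamped
        expect_true(rec$start >= 0 && rec$start < rec$end &&
                    rec$end <= L)
        if (!rec$clamped)
            expect_equal(rec$end - rec$start, gapLength)
    }
})
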