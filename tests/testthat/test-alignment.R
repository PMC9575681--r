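test_that("an exact substring aligns at 100 percent identity", {
    set.seed(320)
    query <- "ACGTACGTACGTACGTACGT"
    read <- Biostrings::DNAStringSet(
        c(r1 = paste0(randomSeq(30), query, randomSeq(30))))
    hits <- alignGapRegion(query, read, filterParams(), queryId = "g")
    expect_gte(nrow(hits), 1L)
    top <- hits[which.max(hits$alnLength), ]
    expect_equal(top$pident, 100)
    expect_equal(top$alnLength, nchar(query))
    expect_equal(top$orientation, "forward")
    expect_equal(top$sstart, 30L)
    expect_equal(top$send, 30L + nchar(query))
})

test_that("a reverse-complement match is reported with reverse orientation", {
    set.seed(321)
    seg <- randomSeq(40)
    read <- Biostrings::DNAStringSet(
        c(r1 = paste0(randomSeq(25), revComp(seg), randomSeq(25))))
    hits <- alignGapRegion(seg, read, filterParams(), queryId = "g")
    expect_gte(nrow(hits), 1L)
    top <- hits[which.max(hits$alnLength), ]
    expect_equal(top$orientation, "reverse")
    expect_equal(top$pident, 100)
    # subject interval refers to the original read
    expect_equal(c(top$sstart, top$send), c(25L, 65L))
})

test_that("an all-N query yields no hits", {
    read <- Biostrings::DNAStringSet(c(r1 = randomSeq(100)))
    hits <- alignGapRegion(strrep("N", 50), read, filterParams())
    expect_equal(nrow(hits), 0L)
})

test_that("filterHits enforces identity, length and gap distance", {
    mkhit <- function(pident, qstart, qend, alen = qend - qstart)
        data.frame(queryId = "g", subjectId = "r", pident = pident,
                   alnLength = alen, qstart = qstart, qend = qend,
                   sstart = 0L, send = alen, orientation = "forward",
                   flankSide = "unassigned", stringsAsFactors = FALSE)
    p <- filterParams(maxGapDistance = 10L)
    gapStart <- 500L; gapEnd <- 600L

    expect_equal(nrow(filterHits(mkhit(96.9, 450L, 500L), gapStart, gapEnd, p)),
                 0L)
    kept <- filterHits(mkhit(98.5, 450L, 500L), gapStart, gapEnd, p)
    expect_equal(nrow(kept), 1L)
    expect_equal(kept$flankSide, "left")
    expect_true(kept$highQuality)
    # high identity but located far from the gap: removed
    p2 <- filterParams(maxGapDistance = 100L)
    expect_equal(nrow(filterHits(mkhit(99, 0L, 60L), gapStart, gapEnd, p2)),
                 0L)
    # short alignment: removed
    expect_equal(nrow(filterHits(mkhit(100, 480L, 500L), gapStart, gapEnd, p)),
                 0L)
    # right-flank classification
    kept <- filterHits(mkhit(100, 600L, 700L), gapStart, gapEnd, p)
    expect_equal(kept$flankSide, "right")
    # spanning classification
    kept <- filterHits(mkhit(100, 450L, 650L), gapStart, gapEnd, p)
    expect_equal(kept$flankSide, "spanning")
})

test_that("filtering is idempotent and monotone in the identity threshold", {
    set.seed(322)
    hits <- do.call(rbind, lapply(1:40, function(i) {
        qs <- sample(0:700, 1); qe <- qs + sample(20:120, 1)
        data.frame(queryId = "g", subjectId = paste0("r", i),
                   pident = runif(1, 90, 100), alnLength = qe - qs,
                   qstart = qs, qend = qe, sstart = 0L, send = qe - qs,
                   orientation = "forward", flankSide = "unassigned",
                   stringsAsFactors = FALSE)
    }))
    p <- filterParams()
    once <- filterHits(hits, 500L, 600L, p)
    twice <- filterHits(once, 500L, 600L, p)
    expect_equal(once, twice)

    loose <- filterParams(minIdentity = 92, hqIdentity = 98)
    keptLoose <- filterHits(hits, 500L, 600L, loose)
    expect_true(all(once$subjectId %in% keptLoose$subjectId))
})

test_that("error-free reads over a gap flank survive with pident 100", {
    set.seed(323)
    ref <- randomSeq(3000)
    gapStart <- 1400L; gapLen <- 60L
    gap <- list(leftFlank = toupper(substr(ref, gapStart - 299, gapStart)),
                rightFlank = toupper(substr(ref, gapStart + gapLen + 1,
                                            gapStart + gapLen + 300)),
                gapLength = gapLen)
    q <- buildGapQuery(gap)
    # reads copied exactly from the reference over each flank
    reads <- Biostrings::DNAStringSet(c(
        left = substr(ref, gapStart - 500, gapStart + 20),
        right = revComp(substr(ref, gapStart + gapLen - 20,
                               gapStart + gapLen + 500))))
    hits <- filterHits(alignGapRegion(q$query, reads, filterParams()),
                       q$gapStart, q$gapEnd)
    expect_true(any(hits$subjectId == "left" & hits$pident == 100))
    expect_true(any(hits$subjectId == "right" & hits$pident == 100))
})
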