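#' Alignment filtering parameters
#'
#' Thresholds controlling which local alignments survive as candidate
#' anchors. Identity below 97\% is discarded; 98\% or better is flagged as a
#' high-quality match. Hits that are short or located far from the gap carry
#' no information about it and are removed.
#'
#' @param minIdentity Minimum percent identity to keep a hit (default 97).
#' @param hqIdentity Percent identity at or above which a hit is flagged
#'   high-quality (default 98).
#' @param minAlnLength Minimum aligned columns (default 40).
#' @param maxGapDistance Maximum distance, in bases, between a hit's query
#'   interval and the gap's N-run (default 10).
#' @param seedLength Exact-match seed length for the internal aligner
#'   (default 15).
#' @return list of validated parameters.
#' @export
filterParams <- function(minIdentity = 97, hqIdentity = 98,
                         minAlnLength = 40L, maxGapDistance = 10L,
                         seedLength = 15L) {
    stopifnot(minIdentity > 0, minIdentity <= hqIdentity, hqIdentity <= 100,
              minAlnLength >= 1L, maxGapDistance >= 0L, seedLength >= 4L)
    list(minIdentity = minIdentity, hqIdentity = hqIdentity,
         minAlnLength = as.integer(minAlnLength),
         maxGapDistance = as.integer(maxGapDistance),
         seedLength = as.integer(seedLength))
}

# Non-N segments of a gap query with their query-local 0-based offsets.
querySegments <- function(query) {
    m <- gregexpr("[ACGTacgt]+", query)[[1L]]
    if (m[1L] == -1L)
        return(list())
    lapply(seq_along(m), function(i) {
        list(seq = toupper(substr(query, m[i], m[i] + attr(m, "match.length")[i] - 1L)),
             offset = as.integer(m[i]) - 1L)
    })
}

# Seed k-mers (stride k, plus the final window) of a segment, as DNAStringSet.
seedKmers <- function(seg, k) {
    n <- nchar(seg)
    if (n < k) return(NULL)
    starts <- unique(c(seq.int(1L, n - k + 1L, by = k), n - k + 1L))
    Biostrings::DNAStringSet(substring(seg, starts, starts + k - 1L))
}

#' Align long reads to a gap-region query
#'
#' Seed-and-extend local alignment of the gap query against a read set and
#' its reverse complements. Exact `seedLength`-mers from the query's non-N
#' segments are matched against the reads ([Biostrings::vwhichPDict]); each
#' seeded read/strand pair is then aligned with Smith-Waterman
#' ([Biostrings::pairwiseAlignment], match 1, mismatch -2, gap open 2, gap
#' extend 1). Because only the non-N flank segments are ever aligned, N
#' positions of the query can never count as matches. Percent identity is
#' matches over aligned columns (including internal indel columns).
#'
#' @param query Gap-region query string from [buildGapQuery()].
#' @param reads Named [Biostrings::DNAStringSet] of long reads.
#' @param params [filterParams()] list (only `seedLength` is used here;
#'   filtering happens in [filterHits()]).
#' @param queryId Identifier stored in the hits (the gap id).
#' @return data.frame of alignment hits (see [parseAlignmentTable()] for
#'   columns), ordered by `subjectId` then `sstart`; zero rows when nothing
#'   aligns. Reverse-orientation subject coordinates refer to the original
#'   read.
#' @export
alignGapRegion <- function(query, reads, params = filterParams(),
                           queryId = "query") {
    stopifnot(length(reads) >= 1L)
    segs <- querySegments(query)
    res <- list()
    for (seg in segs) {
        kmers <- seedKmers(seg$seq, params$seedLength)
        if (is.null(kmers)) next
        fwdIdx <- which(lengths(Biostrings::vwhichPDict(
            Biostrings::PDict(kmers), reads)) > 0L)
        revIdx <- which(lengths(Biostrings::vwhichPDict(
            Biostrings::PDict(Biostrings::reverseComplement(kmers)),
            reads)) > 0L)
        pat <- Biostrings::DNAString(seg$seq)
        for (j in fwdIdx)
            res[[length(res) + 1L]] <-
                alignOne(pat, reads[[j]], names(reads)[j], seg$offset,
                         reverse = FALSE, queryId = queryId)
        for (j in revIdx)
            res[[length(res) + 1L]] <-
                alignOne(pat, Biostrings::reverseComplement(reads[[j]]),
                         names(reads)[j], seg$offset,
                         reverse = TRUE, queryId = queryId)
    }
    res <- res[!vapply(res, is.null, logical(1))]
    if (!length(res))
        return(emptyHits())
    hits <- do.call(rbind, res)
    hits <- hits[order(hits$subjectId, hits$sstart, hits$orientation,
                       hits$qstart), , drop = FALSE]
    rownames(hits) <- NULL
    hits
}

# Smith-Waterman of one query segment vs one (possibly reverse-complemented)
# read; coordinates lifted to query-local / original-read space.
alignOne <- function(pat, subj, subjectId, offset, reverse, queryId) {
    aln <- Biostrings::pairwiseAlignment(
        pat, subj, type = "local",
        substitutionMatrix = Biostrings::nucleotideSubstitutionMatrix(
            match = 1, mismatch = -2),
        gapOpening = 2, gapExtension = 1)
    w <- Biostrings::nchar(aln)           # aligned columns incl. indels
    if (w < 1L || Biostrings::nmatch(aln) < 1L) return(NULL)
    qs <- Biostrings::start(Biostrings::pattern(aln)) - 1L + offset
    qe <- Biostrings::end(Biostrings::pattern(aln)) + offset
    ss <- Biostrings::start(Biostrings::subject(aln)) - 1L
    se <- Biostrings::end(Biostrings::subject(aln))
    if (reverse) {                        # map back to original read coords
        L <- Biostrings::nchar(subj)
        tmp <- ss
        ss <- L - se
        se <- L - tmp
    }
    data.frame(queryId = queryId, subjectId = subjectId,
               pident = Biostrings::pid(aln, type = "PID1"),
               alnLength = w,
               qstart = qs, qend = qe, sstart = ss, send = se,
               orientation = if (reverse) "reverse" else "forward",
               flankSide = "unassigned", stringsAsFactors = FALSE)
}

#' Filter alignment hits by identity, length and location
#'
#' Keeps a hit iff its percent identity is at least `minIdentity`, its
#' aligned length at least `minAlnLength`, and its query interval lies within
#' `maxGapDistance` bases of the gap's N-run (touching or overlapping a flank
#' adjacent to the gap). Surviving hits are classified by the flank they
#' anchor: `left` (ends at or before the gap start, within tolerance),
#' `right` (starts at or after the gap end, within tolerance), `spanning`
#' (query interval covers the whole N-run) or `unassigned`. Filtering is
#' idempotent, and lowering `minIdentity` never removes hits.
#'
#' @param hits data.frame of hits for one gap query.
#' @param gapStart,gapEnd Query-local N-run coordinates from
#'   [buildGapQuery()].
#' @param params [filterParams()] list.
#' @return Filtered, classified hits data.frame (adds logical `highQuality`).
#' @export
filterHits <- function(hits, gapStart, gapEnd, params = filterParams()) {
    if (!nrow(hits)) {
        hits$highQuality <- logical(0)
        return(hits)
    }
    tol <- params$maxGapDistance
    dist <- pmax(0L, gapStart - hits$qend, hits$qstart - gapEnd)
    keep <- hits$pident >= params$minIdentity &
        hits$alnLength >= params$minAlnLength &
        dist <= tol
    hits <- hits[keep, , drop = FALSE]
    side <- rep("unassigned", nrow(hits))
    side[hits$qend <= gapStart + tol] <- "left"
    side[hits$qstart >= gapEnd - tol] <- "right"
    side[hits$qstart <= gapStart & hits$qend >= gapEnd] <- "spanning"
    hits$flankSide <- side
    hits$highQuality <- hits$pident >= params$hqIdentity
    rownames(hits) <- NULL
    hits
}
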