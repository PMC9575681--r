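#' Extend a right-flank hit leftwards across the gap
#'
#' A hit anchored on the gap's right flank locates, on the long read, the
#' region immediately left of the aligned block — the region that should hold
#' the gap sequence. For a forward-orientation hit the new start index is
#' `sstart - (gapLength + (qstart - gapEnd))`; if it falls before the read
#' start it is clamped to zero and the record flagged. The end index is the
#' start plus the gap length, capped at the read length. For a
#' reverse-orientation hit the roles of the read ends swap: the new end is
#' `send + (gapLength + (qstart - gapEnd))`, clamped to the read length, and
#' the start is the end minus the gap length, floored at zero. The strand of
#' the emitted record is `-` for reverse hits.
#'
#' @param hit One-row alignment-hit data.frame with `flankSide == "right"`.
#' @param gapStart,gapEnd Query-local N-run coordinates.
#' @param gapLength Gap length in bases.
#' @param subjectLength Length of the long read the hit lies on.
#' @return One-row extension-record data.frame with columns `subjectId`,
#'   `start`, `end`, `name` (gap id), `strand`, `clamped`; or `NULL` when
#'   clamping leaves an empty interval.
#' @export
leftExtend <- function(hit, gapStart, gapEnd, gapLength, subjectLength) {
    if (hit$flankSide != "right")
        stop("leftExtend requires a right-flank hit (got '",
             hit$flankSide, "')")
    g <- gapLength
    clamped <- FALSE
    if (hit$orientation == "forward") {
        ns <- hit$sstart - (g + (hit$qstart - gapEnd))
        if (ns < 0L) { ns <- 0L; clamped <- TRUE }
        ne <- ns + g
        if (ne > subjectLength) { ne <- subjectLength; clamped <- TRUE }
        strand <- "+"
    } else {
        ne <- hit$send + (g + (hit$qstart - gapEnd))
        if (ne > subjectLength) { ne <- subjectLength; clamped <- TRUE }
        ns <- ne - g
        if (ns < 0L) { ns <- 0L; clamped <- TRUE }
        strand <- "-"
    }
    extensionRecord(hit$subjectId, ns, ne, hit$queryId, strand, clamped)
}

#' Extend a left-flank hit rightwards across the gap
#'
#' Mirror image of [leftExtend()] for hits anchored on the left flank. For a
#' forward hit the new start index is `send + (gapStart - qend)` and the end
#' is the start plus the gap length, clamped at the read boundaries. For a
#' reverse hit the gap region lies before the aligned block on the read:
#' the new end is `sstart - (gapStart - qend)` and the start is the end minus
#' the gap length (the formulation consistent with producing a gap-sized
#' interval adjacent to the aligned block; it coincides with
#' `send - (gapLength + alignedLength)` when the alignment touches the gap).
#'
#' @inheritParams leftExtend
#' @param hit One-row alignment-hit data.frame with `flankSide == "left"`.
#' @return One-row extension-record data.frame, or `NULL` when clamping
#'   leaves an empty interval.
#' @export
rightExtend <- function(hit, gapStart, gapEnd, gapLength, subjectLength) {
    if (hit$flankSide != "left")
        stop("rightExtend requires a left-flank hit (got '",
             hit$flankSide, "')")
    g <- gapLength
    clamped <- FALSE
    if (hit$orientation == "forward") {
        ns <- hit$send + (gapStart - hit$qend)
        if (ns < 0L) { ns <- 0L; clamped <- TRUE }
        ne <- ns + g
        if (ne > subjectLength) { ne <- subjectLength; clamped <- TRUE }
        strand <- "+"
    } else {
        ne <- hit$sstart - (gapStart - hit$qend)
        if (ne > subjectLength) { ne <- subjectLength; clamped <- TRUE }
        ns <- ne - g
        if (ns < 0L) { ns <- 0L; clamped <- TRUE }
        strand <- "-"
    }
    extensionRecord(hit$subjectId, ns, ne, hit$queryId, strand, clamped)
}

extensionRecord <- function(subjectId, start, end, name, strand, clamped) {
    start <- max(0L, as.integer(start))
    end <- as.integer(end)
    if (start >= end) return(NULL)        # clamping consumed the interval
    data.frame(subjectId = subjectId, start = start, end = end,
               name = name, strand = strand, clamped = clamped,
               stringsAsFactors = FALSE)
}

# A spanning hit already covers the N-run; map the gap offsets through the
# alignment onto the read.
spanExtend <- function(hit, gapStart, gapEnd, gapLength, subjectLength) {
    g <- gapLength
    clamped <- FALSE
    if (hit$orientation == "forward") {
        ns <- hit$sstart + (gapStart - hit$qstart)
        ne <- ns + g
    } else {
        ne <- hit$send - (gapStart - hit$qstart)
        ns <- ne - g
    }
    if (ns < 0L) { ns <- 0L; clamped <- TRUE }
    if (ne > subjectLength) { ne <- subjectLength; clamped <- TRUE }
    extensionRecord(hit$subjectId, ns, ne, hit$queryId,
                    if (hit$orientation == "forward") "+" else "-", clamped)
}

#' Extend all filtered hits of one gap
#'
#' Applies [leftExtend()] to every right-flank hit, [rightExtend()] to every
#' left-flank hit, and direct coordinate mapping to spanning hits.
#' Unclamped records always have length exactly `gapLength`; clamped
#' (shorter) records are retained — they are the carriers of partial fills.
#'
#' @param hits Filtered hits data.frame for one gap (from [filterHits()]).
#' @param gapStart,gapEnd Query-local N-run coordinates.
#' @param gapLength Gap length in bases.
#' @param reads Named [Biostrings::DNAStringSet] (read lengths are taken
#'   from here).
#' @return data.frame of extension records in deterministic order
#'   (`subjectId`, `start`, `strand`); zero rows when no hit is extendable.
#' @export
extendAll <- function(hits, gapStart, gapEnd, gapLength, reads) {
    recs <- list()
    for (i in seq_len(nrow(hits))) {
        hit <- hits[i, , drop = FALSE]
        L <- Biostrings::width(reads)[match(hit$subjectId, names(reads))]
        if (is.na(L))
            stop("hit refers to unknown read id: ", hit$subjectId)
        r <- switch(hit$flankSide,
                    right = leftExtend(hit, gapStart, gapEnd, gapLength, L),
                    left = rightExtend(hit, gapStart, gapEnd, gapLength, L),
                    spanning = spanExtend(hit, gapStart, gapEnd, gapLength, L),
                    NULL)
        if (!is.null(r)) recs[[length(recs) + 1L]] <- r
    }
    if (!length(recs))
        return(data.frame(subjectId = character(), start = integer(),
                          end = integer(), name = character(),
                          strand = character(), clamped = logical(),
                          stringsAsFactors = FALSE))
    out <- do.call(rbind, recs)
    out <- out[order(out$subjectId, out$start, out$strand), , drop = FALSE]
    rownames(out) <- NULL
    out
}
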