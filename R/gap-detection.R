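#' Locate N-gaps in a scaffold
#'
#' Scans one scaffold sequence for maximal runs of N (case-insensitive) of at
#' least `minGapLen` bases. Coordinates are 0-based half-open throughout the
#' package.
#'
#' @param sequence Scaffold sequence (character scalar, or a length-1
#'   [Biostrings::BStringSet] element coerced with `as.character`).
#' @param scaffoldId Scaffold identifier used to derive gap ids
#'   (`"<scaffoldId>_gap<k>"`, k counting from 1, left to right).
#' @param minGapLen Minimum N-run length to report (default 1; 1 bp gaps are
#'   detected here but are unfillable downstream).
#' @return data.frame with columns `gapId`, `scaffoldId`, `gapStart`,
#'   `gapEnd`, `gapLength`; zero rows when the scaffold has no qualifying
#'   N-run.
#' @export
findGaps <- function(sequence, scaffoldId, minGapLen = 1L) {
    stopifnot(minGapLen >= 1L)
    sequence <- as.character(sequence)
    m <- gregexpr("[Nn]+", sequence)[[1L]]
    if (m[1L] == -1L)
        return(emptyGaps())
    start <- as.integer(m) - 1L
    len <- attr(m, "match.length")
    keep <- len >= minGapLen
    start <- start[keep]; len <- len[keep]
    if (!length(start))
        return(emptyGaps())
    data.frame(gapId = paste0(scaffoldId, "_gap", seq_along(start)),
               scaffoldId = scaffoldId,
               gapStart = start, gapEnd = start + len, gapLength = len,
               stringsAsFactors = FALSE)
}

emptyGaps <- function() {
    data.frame(gapId = character(), scaffoldId = character(),
               gapStart = integer(), gapEnd = integer(),
               gapLength = integer(), stringsAsFactors = FALSE)
}

#' Extract gap flanking sequences
#'
#' Retrieves up to `flankLen` bases on each side of every gap, truncated at
#' the scaffold boundary or at the nearest neighbouring ambiguous base
#' (N or any other IUPAC ambiguity code), whichever is closer — a flank never
#' spans another gap and never contains a non-ACGT character. Each gap is
#' labelled with its flank scenario:
#' \describe{
#'   \item{both_full}{both flanks reach `flankLen`}
#'   \item{left_short / right_short}{one flank shorter but non-empty}
#'   \item{single_left / single_right}{exactly one (named) flank present}
#'   \item{no_flank}{both flanks empty; the gap is unfillable and no
#'     alignment is attempted}
#' }
#' Flanks are uppercased (the aligner and the transition table are defined
#' over uppercase A/C/G/T; the scaffold itself keeps its original case).
#'
#' @param sequence Scaffold sequence (character scalar).
#' @param gaps data.frame from [findGaps()] for the same scaffold.
#' @param flankLen Maximum flank length in bases (default 500).
#' @return `gaps` with added columns `leftFlank`, `rightFlank`, `scenario`.
#' @export
extractFlanks <- function(sequence, gaps, flankLen = 500L) {
    stopifnot(flankLen >= 1L)
    sequence <- toupper(as.character(sequence))
    n <- nchar(sequence)
    chars <- strsplit(sequence, "", fixed = TRUE)[[1L]]
    ok <- chars %in% c("A", "C", "G", "T")
    left <- character(nrow(gaps)); right <- character(nrow(gaps))
    scenario <- character(nrow(gaps))
    for (i in seq_len(nrow(gaps))) {
        gs <- gaps$gapStart[i]; ge <- gaps$gapEnd[i]
        # walk left from gs-1 (0-based) while bases are plain ACGT
        lo <- gs
        while (lo > 0L && gs - lo < flankLen && ok[lo]) lo <- lo - 1L
        left[i] <- substr(sequence, lo + 1L, gs)
        hi <- ge
        while (hi < n && hi - ge < flankLen && ok[hi + 1L]) hi <- hi + 1L
        right[i] <- substr(sequence, ge + 1L, hi)
        ll <- nchar(left[i]); rl <- nchar(right[i])
        scenario[i] <-
            if (ll == 0L && rl == 0L) "no_flank"
            else if (ll == 0L) "single_right"
            else if (rl == 0L) "single_left"
            else if (ll == flankLen && rl == flankLen) "both_full"
            else if (ll < rl) "left_short"
            else if (rl < ll) "right_short"
            else "both_full"   # equal but both truncated below threshold
    }
    gaps$leftFlank <- left
    gaps$rightFlank <- right
    gaps$scenario <- scenario
    gaps
}

#' Assemble the gap-region alignment query
#'
#' The query used for long-read alignment is the concatenation
#' `leftFlank + N*gapLength + rightFlank`; restricting it to the flanks
#' bounds the search space around the gap. The returned offsets locate the
#' N-run in query-local 0-based half-open coordinates; they are the
#' "gap start"/"gap end" all extension arithmetic refers to.
#'
#' @param gap One-row data.frame (or list) with `leftFlank`, `rightFlank`,
#'   `gapLength`.
#' @return list with `query` (character), `gapStart`, `gapEnd`
#'   (query-local coordinates of the N-run).
#' @export
buildGapQuery <- function(gap) {
    lf <- gap$leftFlank; rf <- gap$rightFlank; g <- gap$gapLength
    if (!nzchar(lf) && !nzchar(rf))
        stop("gap has no flanks; no alignment query can be built")
    list(query = paste0(lf, strrep("N", g), rf),
         gapStart = nchar(lf),
         gapEnd = nchar(lf) + g)
}

#' Detect and annotate gaps across a scaffold set
#'
#' Convenience wrapper running [findGaps()] and [extractFlanks()] over every
#' record of a scaffold set.
#'
#' @param scaffolds Named character vector or [Biostrings::BStringSet].
#' @param minGapLen Minimum N-run length (default 1).
#' @param flankLen Maximum flank length (default 500).
#' @return data.frame of annotated gaps (possibly zero rows) across all
#'   scaffolds, in scaffold then position order.
#' @export
scanScaffolds <- function(scaffolds, minGapLen = 1L, flankLen = 500L) {
    if (methods::is(scaffolds, "XStringSet"))
        scaffolds <- stats::setNames(as.character(scaffolds),
                                     names(scaffolds))
    out <- lapply(names(scaffolds), function(id) {
        g <- findGaps(scaffolds[[id]], id, minGapLen = minGapLen)
        if (nrow(g)) extractFlanks(scaffolds[[id]], g, flankLen = flankLen)
        else cbind(g, leftFlank = character(), rightFlank = character(),
                   scenario = character())
    })
    do.call(rbind, out)
}

#' Write the tab-separated gap manifest
#'
#' @param gaps Annotated gap data.frame from [scanScaffolds()].
#' @param path Output TSV path.
#' @return Invisibly, `path`.
#' @export
writeGapManifest <- function(gaps, path) {
    cols <- c("gapId", "scaffoldId", "gapStart", "gapEnd", "gapLength",
              "scenario")
    utils::write.table(gaps[, cols], path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    invisible(path)
}
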