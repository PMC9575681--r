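#' Splice selected fills into the scaffolds
#'
#' Replaces each filled gap's N-run with its generated sequence, leaving
#' every other byte of the scaffold — including character case — unchanged.
#' A partial fill replaces only the leading `filledLength` Ns; the remainder
#' stays N. A fill longer than its gap is a contract violation and errors
#' (never silently truncated). Fills are written uppercase by default;
#' `lowercaseFills = TRUE` marks inserted sequence in lowercase instead.
#'
#' @param scaffolds Named character vector or [Biostrings::BStringSet].
#' @param gaps Annotated gap data.frame ([scanScaffolds()] output).
#' @param fills Named list of [fillGap()] results keyed by `gapId` (gaps
#'   without an entry, or with unfillable status, are left as N).
#' @param lowercaseFills Write inserted bases in lowercase (default FALSE).
#' @return list with `scaffolds` (filled, same class/names/order as input),
#'   `report` (per-gap data.frame: `gapId`, `scaffoldId`, `gapLength`,
#'   `status`, `filledLength`, `avgCost`, `nCandidates`) and `summary`
#'   (named totals per status).
#' @export
applyFills <- function(scaffolds, gaps, fills, lowercaseFills = FALSE) {
    isXSS <- methods::is(scaffolds, "XStringSet")
    seqs <- if (isXSS) stats::setNames(as.character(scaffolds),
                                       names(scaffolds)) else scaffolds
    rows <- vector("list", nrow(gaps))
    for (i in seq_len(nrow(gaps))) {
        gid <- gaps$gapId[i]; sid <- gaps$scaffoldId[i]
        g <- gaps$gapLength[i]
        fill <- fills[[gid]]
        status <- if (is.null(fill)) "unfillable:no_result" else fill$status
        filled <- 0L
        avgCost <- NA_real_
        nCand <- if (is.null(fill)) 0L else fill$nCandidates
        if (!is.null(fill) && fill$status %in% c("filled", "partial") &&
            nzchar(fill$sequence)) {
            s <- fill$sequence
            if (nchar(s) > g)
                stop("fill for ", gid, " is longer than the gap (",
                     nchar(s), " > ", g, ")")
            if (lowercaseFills) s <- tolower(s)
            filled <- nchar(s)
            avgCost <- fill$avgCost
            pos <- gaps$gapStart[i]          # 0-based; splice at pos+1
            substr(seqs[[sid]], pos + 1L, pos + filled) <- s
        }
        rows[[i]] <- data.frame(gapId = gid, scaffoldId = sid,
                                gapLength = g, status = status,
                                filledLength = filled, avgCost = avgCost,
                                nCandidates = nCand,
                                stringsAsFactors = FALSE)
    }
    report <- if (length(rows)) do.call(rbind, rows) else
        data.frame(gapId = character(), scaffoldId = character(),
                   gapLength = integer(), status = character(),
                   filledLength = integer(), avgCost = numeric(),
                   nCandidates = integer(), stringsAsFactors = FALSE)
    out <- if (isXSS) Biostrings::BStringSet(seqs) else seqs
    list(scaffolds = out, report = report,
         summary = as.list(table(report$status)))
}

#' Write the fill report
#'
#' Tab-separated per-gap table plus a JSON summary of status totals.
#'
#' @param result [applyFills()] return value.
#' @param tsvPath Path for the per-gap TSV.
#' @param jsonPath Path for the JSON summary.
#' @return Invisibly, `tsvPath`.
#' @export
writeFillReport <- function(result, tsvPath, jsonPath) {
    utils::write.table(result$report, tsvPath, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    jsonlite::write_json(result$summary, jsonPath, auto_unbox = TRUE)
    invisible(tsvPath)
}
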