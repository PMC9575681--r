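#' Pipeline run configuration
#'
#' @param scaffolds Path to the draft scaffold FASTA.
#' @param reads Path to the long-read FASTA/FASTQ (qualities ignored).
#' @param out Output directory (created if absent).
#' @param flankLen Maximum flank length extracted per gap side (default 500).
#' @param minGapLen Minimum N-run length to report (default 1).
#' @param minIdentity Minimum percent identity of kept hits (default 97).
#' @param hqIdentity High-quality identity threshold (default 98).
#' @param minAlnLength Minimum aligned length of kept hits (default 40).
#' @param maxGapDistance Maximum hit-to-gap distance in bases (default 10).
#' @param nSamples Markov samples per gap, 5-10 (default 8).
#' @param seed Master seed; per-gap streams are derived from it and the gap
#'   id, so results do not depend on gap processing order (default 42).
#' @param aligner `"internal"` (seed-and-extend) or `"external-tabular"`
#'   (pre-computed 12-column alignments via `alignmentTable`).
#' @param alignmentTable Path to a tabular alignment file whose query ids
#'   are gap ids (required for the external aligner).
#' @param keepIntermediates Write per-gap query FASTA, hit tables and BED
#'   files under `out/intermediates/` (default FALSE).
#' @param lineWidth FASTA wrap width of the output (default 60).
#' @return Validated list of class `runConfig`.
#' @export
runConfig <- function(scaffolds, reads, out,
                      flankLen = 500L, minGapLen = 1L,
                      minIdentity = 97, hqIdentity = 98,
                      minAlnLength = 40L, maxGapDistance = 10L,
                      nSamples = 8L, seed = 42L,
                      aligner = c("internal", "external-tabular"),
                      alignmentTable = NULL, keepIntermediates = FALSE,
                      lineWidth = 60L) {
    aligner <- match.arg(aligner)
    stopifnot(flankLen >= 1L, minGapLen >= 1L, minIdentity > 0,
              minIdentity <= hqIdentity, hqIdentity <= 100,
              minAlnLength >= 1L, maxGapDistance >= 0L,
              nSamples >= 5L, nSamples <= 10L, lineWidth >= 1L)
    if (aligner == "external-tabular" && is.null(alignmentTable))
        stop("aligner 'external-tabular' requires alignmentTable")
    structure(list(scaffolds = scaffolds, reads = reads, out = out,
                   flankLen = as.integer(flankLen),
                   minGapLen = as.integer(minGapLen),
                   minIdentity = minIdentity, hqIdentity = hqIdentity,
                   minAlnLength = as.integer(minAlnLength),
                   maxGapDistance = as.integer(maxGapDistance),
                   nSamples = as.integer(nSamples), seed = as.integer(seed),
                   aligner = aligner, alignmentTable = alignmentTable,
                   keepIntermediates = keepIntermediates,
                   lineWidth = as.integer(lineWidth)),
              class = "runConfig")
}

#' Run the gap-filling pipeline end to end
#'
#' Executes gap detection, long-read alignment, hit filtering, read
#' extension, candidate extraction, transition-table construction, anchored
#' Markov generation and gap writing, and writes the filled scaffold FASTA
#' (`filled.fasta`), the per-gap report (`fill_report.tsv`), a JSON status
#' summary (`fill_summary.json`), a JSON-lines per-gap log
#' (`gap_log.jsonl`), the gap manifest (`gap_manifest.tsv`) and the
#' effective configuration (`config.txt`) into the output directory.
#' Identical configuration and inputs produce byte-identical outputs. An
#' error confined to one gap marks that gap `unfillable:error` and never
#' aborts the run.
#'
#' @param config A [runConfig()].
#' @return Invisibly, a list with `scaffolds`, `gaps`, `report`, `summary`
#'   and the output `paths`.
#' @export
runPipeline <- function(config) {
    stopifnot(inherits(config, "runConfig"))
    if (!file.exists(config$scaffolds))
        stop("scaffold file not found: ", config$scaffolds)
    if (!file.exists(config$reads))
        stop("read file not found: ", config$reads)
    scaffolds <- readFasta(config$scaffolds)
    reads <- readLongReads(config$reads)
    dir.create(config$out, recursive = TRUE, showWarnings = FALSE)
    intDir <- file.path(config$out, "intermediates")
    if (config$keepIntermediates)
        dir.create(intDir, showWarnings = FALSE)

    params <- filterParams(minIdentity = config$minIdentity,
                           hqIdentity = config$hqIdentity,
                           minAlnLength = config$minAlnLength,
                           maxGapDistance = config$maxGapDistance)
    gaps <- scanScaffolds(scaffolds, minGapLen = config$minGapLen,
                          flankLen = config$flankLen)
    externalHits <- if (config$aligner == "external-tabular")
        parseAlignmentTable(config$alignmentTable) else NULL

    scafChar <- stats::setNames(as.character(scaffolds), names(scaffolds))
    fills <- list()
    logLines <- character(0)
    for (i in seq_len(nrow(gaps))) {
        gap <- gaps[i, , drop = FALSE]
        fills[[gap$gapId]] <- tryCatch(
            fillOneGap(gap, reads, params, config, externalHits, intDir),
            error = function(e)
                list(status = "unfillable:error", sequence = "",
                     avgCost = NA_real_, sampleIndex = NA_integer_,
                     nCandidates = 0L, message = conditionMessage(e)))
        f <- fills[[gap$gapId]]
        logLines <- c(logLines, jsonlite::toJSON(
            list(gapId = gap$gapId, nCandidates = f$nCandidates,
                 nSamples = config$nSamples,
                 avgCost = if (is.na(f$avgCost)) NULL else f$avgCost,
                 status = f$status),
            auto_unbox = TRUE, digits = NA))
    }

    result <- applyFills(scaffolds, gaps, fills)
    paths <- list(fasta = file.path(config$out, "filled.fasta"),
                  report = file.path(config$out, "fill_report.tsv"),
                  summary = file.path(config$out, "fill_summary.json"),
                  log = file.path(config$out, "gap_log.jsonl"),
                  manifest = file.path(config$out, "gap_manifest.tsv"),
                  config = file.path(config$out, "config.txt"))
    writeFasta(result$scaffolds, paths$fasta, lineWidth = config$lineWidth)
    writeFillReport(result, paths$report, paths$summary)
    writeLines(logLines, paths$log)
    writeGapManifest(gaps, paths$manifest)
    scalar <- vapply(config, function(v)
        is.null(v) || (is.atomic(v) && length(v) == 1L), logical(1))
    writeLines(paste0(names(config)[scalar], "=",
                      vapply(config[scalar], function(v)
                          if (is.null(v)) "" else as.character(v),
                          character(1))),
               paths$config)
    invisible(list(scaffolds = result$scaffolds, gaps = gaps,
                   report = result$report, summary = result$summary,
                   paths = paths))
}

# One gap through alignment -> filtering -> extension -> candidates ->
# Markov fill. Returns a fillGap()-shaped list.
fillOneGap <- function(gap, reads, params, config, externalHits, intDir) {
    empty <- function(reason)
        list(status = paste0("unfillable:", reason), sequence = "",
             avgCost = NA_real_, sampleIndex = NA_integer_,
             nCandidates = 0L)
    if (gap$scenario == "no_flank")
        return(empty("no_flank"))
    if (gap$gapLength == 1L)
        return(empty("gap_too_short"))
    q <- buildGapQuery(gap)
    hits <- if (is.null(externalHits))
        alignGapRegion(q$query, reads, params, queryId = gap$gapId)
    else
        externalHits[externalHits$queryId == gap$gapId, , drop = FALSE]
    hits <- filterHits(hits, q$gapStart, q$gapEnd, params)
    bed <- extendAll(hits, q$gapStart, q$gapEnd, gap$gapLength, reads)
    if (config$keepIntermediates) {
        utils::write.table(hits,
                           file.path(intDir, paste0(gap$gapId, "_hits.tsv")),
                           sep = "\t", quote = FALSE, row.names = FALSE)
        writeBed(bed, file.path(intDir, paste0(gap$gapId, ".bed")))
    }
    cands <- extractCandidates(bed, reads, gapLength = gap$gapLength)
    lastChar <- if (nzchar(gap$leftFlank))
        substr(gap$leftFlank, nchar(gap$leftFlank), nchar(gap$leftFlank))
    else NA_character_
    fillGap(cands, gap$gapLength, lastChar, nSamples = config$nSamples,
            seed = gapSeed(config$seed, gap$gapId))
}
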