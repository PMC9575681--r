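#' Read a FASTA file preserving character case
#'
#' Scaffold assemblies frequently mix upper- and lowercase bases (soft-masked
#' repeats), and the filler must leave untouched bases byte-identical, so
#' scaffolds are kept in a case-preserving [Biostrings::BStringSet].
#' The record id is the first whitespace-delimited token of the header.
#'
#' @param path Path to a FASTA file.
#' @return A named [Biostrings::BStringSet], one element per record, in file
#'   order, with wrapped lines concatenated and case preserved.
#' @export
readFasta <- function(path) {
    if (!file.exists(path))
        stop("FASTA file not found: ", path)
    x <- Biostrings::readBStringSet(path)
    if (length(x) == 0L)
        stop("empty FASTA file (no records): ", path)
    ids <- vapply(strsplit(names(x), "[[:space:]]+"), `[`, character(1), 1L)
    if (anyNA(ids) || any(!nzchar(ids)))
        stop("malformed FASTA header (empty id) in ", path,
             " at record ", which(is.na(ids) | !nzchar(ids))[1L])
    if (anyDuplicated(ids))
        stop("duplicate FASTA id in ", path, ": ",
             ids[anyDuplicated(ids)])
    if (any(Biostrings::width(x) < 1L))
        stop("zero-length sequence in ", path, " for id ",
             ids[which(Biostrings::width(x) < 1L)[1L]])
    names(x) <- ids
    x
}

#' Write sequences to FASTA
#'
#' Inverse of [readFasta()]: `readFasta(writeFasta(x, f))` returns records
#' identical to `x` in id, sequence and case.
#'
#' @param records Named character vector or [Biostrings::BStringSet].
#' @param path Output file path.
#' @param lineWidth Sequence line wrap width (default 60).
#' @return Invisibly, `path`.
#' @export
writeFasta <- function(records, path, lineWidth = 60L) {
    stopifnot(lineWidth >= 1L)
    if (methods::is(records, "XStringSet"))
        records <- stats::setNames(as.character(records), names(records))
    if (is.null(names(records)) || any(!nzchar(names(records))))
        stop("all records must be named")
    con <- file(path, open = "wt")
    on.exit(close(con))
    for (i in seq_along(records)) {
        writeLines(paste0(">", names(records)[i]), con)
        s <- records[[i]]
        n <- nchar(s)
        starts <- seq.int(1L, n, by = lineWidth)
        writeLines(substring(s, starts, pmin(starts + lineWidth - 1L, n)), con)
    }
    invisible(path)
}

#' Read long reads from FASTA or FASTQ
#'
#' Base qualities are discarded: the gap-filling algorithm never uses them.
#' Read sequences are uppercased into a [Biostrings::DNAStringSet].
#'
#' @param path Path to a FASTA or FASTQ file; format is sniffed from the
#'   first non-empty character (`>` vs `@`) unless given.
#' @param format `"auto"`, `"fasta"` or `"fastq"`.
#' @return A named [Biostrings::DNAStringSet].
#' @export
readLongReads <- function(path, format = c("auto", "fasta", "fastq")) {
    format <- match.arg(format)
    if (!file.exists(path))
        stop("read file not found: ", path)
    if (format == "auto") {
        first <- readLines(path, n = 1L)
        if (length(first) == 0L)
            stop("empty read file: ", path)
        format <- if (startsWith(first, "@")) "fastq" else "fasta"
    }
    x <- Biostrings::readDNAStringSet(path, format = format)
    if (length(x) == 0L)
        stop("no reads in ", path)
    names(x) <- vapply(strsplit(names(x), "[[:space:]]+"), `[`,
                       character(1), 1L)
    x
}

#' Reverse complement of a nucleotide string
#'
#' Operates on plain character vectors over \{A, C, G, T, N\}
#' (case-insensitive); the result is uppercase. N is self-complementary.
#'
#' @param seq Character vector of nucleotide strings.
#' @return Character vector of reverse complements, uppercase.
#' @export
revComp <- function(seq) {
    vapply(seq, function(s) {
        up <- toupper(s)
        bad <- regmatches(up, regexpr("[^ACGTN]", up))
        if (length(bad) && nzchar(bad))
            stop("invalid nucleotide character: '", bad, "'")
        as.character(Biostrings::reverseComplement(Biostrings::DNAString(up)))
    }, character(1), USE.NAMES = FALSE)
}

#' Write BED6 interval records
#'
#' Columns: chrom (read id), start, end, name (gap id), score (fixed 0),
#' strand. Coordinates are 0-based half-open, as in the BED standard.
#'
#' @param records data.frame with columns `subjectId`, `start`, `end`,
#'   `name`, `strand`.
#' @param path Output file path.
#' @return Invisibly, `path`.
#' @export
writeBed <- function(records, path) {
    records <- as.data.frame(records)
    if (nrow(records)) {
        if (any(records$start < 0L) || any(records$start >= records$end))
            stop("invalid BED interval: start must satisfy 0 <= start < end")
        if (!all(records$strand %in% c("+", "-")))
            stop("BED strand must be '+' or '-'")
    }
    out <- data.frame(records$subjectId, records$start, records$end,
                      records$name, 0L, records$strand)
    utils::write.table(out, path, sep = "\t", quote = FALSE,
                       row.names = FALSE, col.names = FALSE)
    invisible(path)
}

#' Read BED6 interval records
#'
#' @param path Path to a BED6 file written by [writeBed()].
#' @return data.frame with columns `subjectId`, `start`, `end`, `name`,
#'   `score`, `strand`.
#' @export
readBed <- function(path) {
    cols <- c("subjectId", "start", "end", "name", "score", "strand")
    if (file.size(path) == 0)
        return(stats::setNames(
            data.frame(character(), integer(), integer(), character(),
                       integer(), character(), stringsAsFactors = FALSE),
            cols))
    x <- utils::read.table(path, sep = "\t", header = FALSE,
                           colClasses = c("character", "integer", "integer",
                                          "character", "integer", "character"),
                           stringsAsFactors = FALSE)
    if (ncol(x) != 6L)
        stop("expected 6 BED columns, found ", ncol(x))
    stats::setNames(x, cols)
}

#' Parse a 12-column tabular alignment file
#'
#' Accepts the conventional BLAST `outfmt 6` column order (qseqid, sseqid,
#' pident, length, mismatch, gapopen, qstart, qend, sstart, send, evalue,
#' bitscore). The file's 1-based inclusive coordinates are converted exactly
#' once, here, to the package-wide 0-based half-open convention. A reversed
#' coordinate pair on either axis (start > end) marks a reverse-orientation
#' hit; coordinates are normalised to ascending order and the orientation
#' retained.
#'
#' @param path Path to a tab-separated 12-column alignment file.
#' @return data.frame of alignment hits with columns `queryId`, `subjectId`,
#'   `pident`, `alnLength`, `qstart`, `qend`, `sstart`, `send`,
#'   `orientation` (`"forward"`/`"reverse"`) and `flankSide`
#'   (`"unassigned"` until [filterHits()]).
#' @export
parseAlignmentTable <- function(path) {
    if (!file.exists(path))
        stop("alignment table not found: ", path)
    lines <- readLines(path)
    lines <- lines[nzchar(trimws(lines))]
    if (length(lines) == 0L)
        return(emptyHits())
    fields <- strsplit(lines, "\t", fixed = TRUE)
    nf <- lengths(fields)
    if (any(nf != 12L))
        stop("expected 12 tab-separated columns at line ",
             which(nf != 12L)[1L], " (found ", nf[nf != 12L][1L], ")")
    m <- do.call(rbind, fields)
    qs <- as.integer(m[, 7L]); qe <- as.integer(m[, 8L])
    ss <- as.integer(m[, 9L]); se <- as.integer(m[, 10L])
    revq <- qs > qe
    revs <- ss > se
    hits <- data.frame(
        queryId = m[, 1L], subjectId = m[, 2L],
        pident = as.numeric(m[, 3L]), alnLength = as.integer(m[, 4L]),
        qstart = ifelse(revq, qe, qs) - 1L, qend = ifelse(revq, qs, qe),
        sstart = ifelse(revs, se, ss) - 1L, send = ifelse(revs, ss, se),
        orientation = ifelse(xor(revq, revs), "reverse", "forward"),
        flankSide = "unassigned",
        stringsAsFactors = FALSE)
    if (any(hits$qstart >= hits$qend) || any(hits$sstart >= hits$send))
        stop("degenerate alignment interval (start == end) at line ",
             which(hits$qstart >= hits$qend | hits$sstart >= hits$send)[1L])
    hits
}

emptyHits <- function() {
    data.frame(queryId = character(), subjectId = character(),
               pident = numeric(), alnLength = integer(),
               qstart = integer(), qend = integer(),
               sstart = integer(), send = integer(),
               orientation = character(), flankSide = character(),
               stringsAsFactors = FALSE)
}
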