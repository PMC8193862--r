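## FASTQ input/output on top of Biostrings. Phred+33 only; qualities are
## contractually in [0, 41]. gzip is detected by the ".gz" suffix.

#' Decode a Phred+33 quality string to integer scores
#'
#' @param x character vector of quality strings.
#' @return For a single string, an integer vector; otherwise a list of
#'   integer vectors.
#' @examples
#' decodePhred("II")  # c(40, 40)
#' decodePhred("!")   # 0
#' @export
decodePhred <- function(x) {
    out <- lapply(x, function(s) as.integer(utf8ToInt(s)) - 33L)
    bad <- vapply(out, function(q) any(q < 0L | q > 41L), logical(1))
    if (any(bad))
        stop("quality score outside [0, 41] in element ", which(bad)[1L])
    if (length(out) == 1L) out[[1L]] else out
}

#' Encode integer Phred scores as a Phred+33 quality string
#'
#' @param q integer vector of scores in [0, 41].
#' @return A single quality string.
#' @examples
#' encodePhred(c(40, 0))  # "I!"
#' @export
encodePhred <- function(q) {
    q <- as.integer(q)
    if (length(q) && (anyNA(q) || any(q < 0L | q > 41L)))
        stop("quality score outside [0, 41]")
    if (!length(q)) return("")
    intToUtf8(q + 33L)
}

## Scan a FASTQ file with base R to name the first malformed record.
## Runs before the Biostrings parser so structural defects (truncated
## records, missing "+" lines, sequence/quality length mismatches) are
## reported with their record index.
.diagnoseFastq <- function(path) {
    con <- if (grepl("\\.gz$", path)) gzfile(path, "rt") else file(path, "rt")
    on.exit(close(con))
    lines <- readLines(con, warn = FALSE)
    if (length(lines) %% 4L != 0L)
        stop("malformed FASTQ '", path, "': line count ", length(lines),
             " is not a multiple of 4 (record ",
             length(lines) %/% 4L + 1L, " is truncated)")
    n <- length(lines) %/% 4L
    for (i in seq_len(n)) {
        rec <- lines[(i - 1L) * 4L + 1:4]
        if (!startsWith(rec[1L], "@"))
            stop("malformed FASTQ '", path, "': record ", i,
                 " does not start with '@'")
        if (!startsWith(rec[3L], "+"))
            stop("malformed FASTQ '", path, "': record ", i,
                 " is missing the '+' separator line")
        if (nchar(rec[2L]) != nchar(rec[4L]))
            stop("malformed FASTQ '", path, "': record ", i,
                 " has sequence length ", nchar(rec[2L]),
                 " but quality length ", nchar(rec[4L]))
    }
    invisible(TRUE)
}

#' Read a FASTQ file
#'
#' Reads a 4-line-per-record FASTQ file (plain or gzip-compressed, detected
#' by the \code{.gz} suffix) into a
#' [Biostrings::QualityScaledDNAStringSet-class] with Phred+33 qualities.
#' Element names carry the full FASTQ header (without the leading
#' \code{"@"}). Malformed records raise an error naming the record index.
#'
#' @param path path to the FASTQ file.
#' @return A \code{QualityScaledDNAStringSet}.
#' @export
readFastq <- function(path) {
    if (!file.exists(path))
        stop("FASTQ file not found: ", path)
    .diagnoseFastq(path)
    x <- withCallingHandlers(
        tryCatch(
            readQualityScaledDNAStringSet(path),
            error = function(e) {
                stop("malformed FASTQ '", path, "': ", conditionMessage(e))
            }),
        ## the parser notes that it drops the (unused) per-record mcols
        warning = function(w) {
            if (grepl("metadata columns", conditionMessage(w)))
                invokeRestart("muffleWarning")
        })
    if (length(x))
        decodePhred(as.character(quality(x)))  # range check, [0, 41]
    S4Vectors::mcols(x) <- NULL
    x
}

## Identity of a read up to its mate token: strips a trailing "/1" or "/2"
## and, for the space-delimited Illumina dialect, everything after the
## first whitespace.
.mateIdentity <- function(id) {
    id <- sub("[ \t].*$", "", id)
    sub("/[12]$", "", id)
}

#' Read a synchronized pair of FASTQ files
#'
#' Reads R1 and R2 files, checks that they hold the same number of records
#' and that identifiers match pairwise after stripping the mate token
#' (trailing \code{"/1"}/\code{"/2"} or the space-delimited Illumina mate
#' field).
#'
#' @param pathR1,pathR2 paths to the two FASTQ files.
#' @return A list with elements \code{r1} and \code{r2}, each a
#'   \code{QualityScaledDNAStringSet}.
#' @export
readFastqPaired <- function(pathR1, pathR2) {
    r1 <- readFastq(pathR1)
    r2 <- readFastq(pathR2)
    if (length(r1) != length(r2))
        stop("paired FASTQ files differ in record count: ",
             length(r1), " (R1) vs ", length(r2), " (R2)")
    id1 <- .mateIdentity(names(r1))
    id2 <- .mateIdentity(names(r2))
    mism <- which(id1 != id2)
    if (length(mism))
        stop("paired FASTQ identifier mismatch at record ", mism[1L],
             ": '", id1[mism[1L]], "' vs '", id2[mism[1L]], "'")
    list(r1 = r1, r2 = r2)
}

#' Write a FASTQ file
#'
#' Writes a \code{QualityScaledDNAStringSet} as Phred+33 FASTQ, gzip
#' compressed when \code{path} ends in \code{.gz}.
#'
#' @param x a \code{QualityScaledDNAStringSet} (qualities in [0, 41]).
#' @param path output path.
#' @return (Invisibly) the number of records written.
#' @export
writeFastq <- function(x, path) {
    if (!is(x, "QualityScaledDNAStringSet"))
        stop("x must be a QualityScaledDNAStringSet")
    if (length(x)) {
        q <- unlist(lapply(as.character(quality(x)), utf8ToInt)) - 33L
        if (any(q < 0L | q > 41L))
            stop("quality score outside [0, 41]")
    }
    writeQualityScaledXStringSet(x, path, compress = grepl("\\.gz$", path))
    invisible(length(x))
}

#' Output path for a corrected FASTQ file
#'
#' The corrected file keeps the input root name with the suffix
#' \code{"_corrected"} inserted before the extension, and is placed in
#' \code{outputDir}; e.g. \code{sampleA_R1.fastq} becomes
#' \code{sampleA_R1_corrected.fastq}.
#'
#' @param path input FASTQ path.
#' @param outputDir directory for the corrected file.
#' @return The output path.
#' @export
correctedFastqPath <- function(path, outputDir) {
    base <- basename(path)
    gz <- grepl("\\.gz$", base)
    if (gz) base <- sub("\\.gz$", "", base)
    root <- tools::file_path_sans_ext(base)
    ext <- tools::file_ext(base)
    out <- paste0(root, "_corrected",
                  if (nzchar(ext)) paste0(".", ext),
                  if (gz) ".gz")
    file.path(outputDir, out)
}
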