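## End-to-end orchestration: discover FASTQ files, extract UMIs, group,
## clean, merge, and write corrected FASTQ plus summary_table.csv.

.LOG_LEVELS <- c(DEBUG = 1L, INFO = 2L, WARN = 3L, QUIET = 4L)

.log <- function(level, logLevel, ...) {
    if (.LOG_LEVELS[[level]] >= .LOG_LEVELS[[logLevel]])
        message("[", level, "] ", ...)
    invisible(NULL)
}

## Pair up input files: every file whose name carries an "R1" token is
## matched with the file obtained by substituting "R2".
.discoverInputs <- function(inputDir, paired) {
    files <- sort(list.files(inputDir,
                             pattern = "\\.(fastq|fq)(\\.gz)?$",
                             full.names = TRUE))
    if (!length(files))
        stop("no FASTQ files (*.fastq, *.fq, optionally .gz) found in ",
             inputDir)
    if (!paired)
        return(lapply(files, function(f) list(r1 = f, r2 = NULL)))
    r1files <- files[grepl("R1", basename(files), fixed = TRUE)]
    if (!length(r1files))
        stop("paired mode: no file with an 'R1' token found in ", inputDir)
    lapply(r1files, function(f) {
        mate <- file.path(dirname(f), sub("R1", "R2", basename(f)))
        if (!file.exists(mate))
            stop("paired mode: missing mate file ", mate, " for ", f)
        list(r1 = f, r2 = mate)
    })
}

## root name used in the summary table: file name without extension(s)
.fileRoot <- function(path) {
    base <- sub("\\.gz$", "", basename(path))
    tools::file_path_sans_ext(base)
}

.meanQual2 <- function(qsds, i) {
    round(mean(decodePhred(as.character(quality(qsds[i]))[1L])), 2)
}

.summaryRows <- function(clusters, fileRoot) {
    k <- length(clusters)
    paired <- !is.null(clusters@consensusR2)
    data.frame(
        input_file_root = rep(fileRoot, k),
        representative_umi = representativeUmi(clusters),
        absorbed_umis = vapply(absorbedUmis(clusters), paste,
                               character(1), collapse = ";"),
        n_umis_merged = 1L + lengths(absorbedUmis(clusters)),
        pooled_count = pooledCount(clusters),
        consensus_r1 = unname(as.character(clusters@consensusR1)),
        mean_quality_r1 = vapply(seq_len(k), function(i)
            .meanQual2(clusters@consensusR1, i), numeric(1)),
        consensus_r2 = if (paired) unname(as.character(clusters@consensusR2))
                       else rep("", k),
        mean_quality_r2 = if (paired) vapply(seq_len(k), function(i)
            .meanQual2(clusters@consensusR2, i), numeric(1))
            else rep(NA_real_, k),
        stringsAsFactors = FALSE)
}

#' Write the run summary table
#'
#' Writes one row per output consensus read as \code{summary_table.csv}
#' (comma-separated, header first, UTF-8): input file root, representative
#' UMI, absorbed UMIs (semicolon-joined), number of UMIs merged, pooled
#' read count, consensus sequence(s) and their mean qualities.
#'
#' @param rows data frame of summary rows (as built by [runUmiPipeline()]).
#' @param path output file path.
#' @return (Invisibly) the number of data rows written.
#' @export
writeSummary <- function(rows, path) {
    utils::write.csv(rows, path, row.names = FALSE, quote = FALSE,
                     fileEncoding = "UTF-8", na = "")
    invisible(nrow(rows))
}

#' Run the full deduplication and correction pipeline
#'
#' Discovers FASTQ files in \code{inputDir(config)} (paired mates are
#' matched by the "R1"/"R2" file-name token), then for each input unit:
#' extracts UMIs, groups reads by exact UMI, drops groups below
#' \code{countsCutoff}, computes per-group consensus reads, greedily
#' merges near-identical UMI groups, recomputes the final consensus per
#' cluster, and writes corrected FASTQ files (input root +
#' \code{"_corrected"}, UMI removed) into \code{outputDir} together with a
#' single \code{summary_table.csv}. Output record identifiers have the
#' form \code{"umi=<UMI>;reads=<count>"}.
#'
#' @param config a [UmiRunConfig-class].
#' @param logLevel one of \code{"DEBUG"}, \code{"INFO"}, \code{"WARN"},
#'   \code{"QUIET"}.
#' @return (Invisibly) a list with \code{stats} (named counts: input
#'   reads, reads after cleaning, UMIs at start / after cleaning / after
#'   merging), \code{clusters} (list of [UmiClusterSet-class], one per
#'   input unit), \code{summary} (the summary data frame) and
#'   \code{outputFiles}.
#' @export
runUmiPipeline <- function(config, logLevel = "INFO") {
    stopifnot(is(config, "UmiRunConfig"))
    logLevel <- match.arg(logLevel, names(.LOG_LEVELS))
    if (!dir.exists(config@inputDir))
        stop("input directory does not exist: ", config@inputDir)
    units <- .discoverInputs(config@inputDir, config@pairedData)
    if (!dir.exists(config@outputDir))
        dir.create(config@outputDir, recursive = TRUE)

    stats <- c(input_reads = 0L, reads_after_cleaning = 0L,
               umis_start = 0L, umis_after_cleaning = 0L,
               umis_after_merging = 0L)
    allRows <- list()
    clusterSets <- list()
    outFiles <- character(0)

    for (unit in units) {
        root <- .fileRoot(unit$r1)
        .log("INFO", logLevel, "processing ", basename(unit$r1),
             if (!is.null(unit$r2)) paste0(" + ", basename(unit$r2)))
        if (is.null(unit$r2)) {
            r1 <- readFastq(unit$r1)
            r2 <- NULL
        } else {
            pair <- readFastqPaired(unit$r1, unit$r2)
            r1 <- pair$r1
            r2 <- pair$r2
        }
        extracted <- extractUmi(r1, r2, config)
        groups <- groupByUmi(extracted)
        cleaned <- cleanGroups(groups, config@countsCutoff)
        dropped <- length(groups) - length(cleaned)
        .log("INFO", logLevel, length(r1), " reads, ", length(groups),
             " UMIs; cleaning dropped ", dropped, " UMI group",
             if (dropped != 1L) "s", " below cutoff ", config@countsCutoff)
        clusters <- mergeUmiGroups(cleaned, config)
        .log("INFO", logLevel, length(cleaned), " UMIs merged into ",
             length(clusters), " clusters")
        for (i in seq_len(length(clusters))) {
            ab <- absorbedUmis(clusters)[[i]]
            if (length(ab))
                .log("DEBUG", logLevel, representativeUmi(clusters)[i],
                     " absorbed ", paste(ab, collapse = ", "))
        }

        stats["input_reads"] <- stats["input_reads"] + length(r1)
        stats["reads_after_cleaning"] <- stats["reads_after_cleaning"] +
            sum(groupCounts(cleaned))
        stats["umis_start"] <- stats["umis_start"] + length(groups)
        stats["umis_after_cleaning"] <- stats["umis_after_cleaning"] +
            length(cleaned)
        stats["umis_after_merging"] <- stats["umis_after_merging"] +
            length(clusters)

        out1 <- correctedFastqPath(unit$r1, config@outputDir)
        writeFastq(clusters@consensusR1, out1)
        outFiles <- c(outFiles, out1)
        if (!is.null(unit$r2)) {
            out2 <- correctedFastqPath(unit$r2, config@outputDir)
            writeFastq(clusters@consensusR2, out2)
            outFiles <- c(outFiles, out2)
        }
        allRows <- c(allRows, list(.summaryRows(clusters, root)))
        clusterSets <- c(clusterSets, list(clusters))
    }

    summary <- do.call(rbind, allRows)
    sumPath <- file.path(config@outputDir, "summary_table.csv")
    writeSummary(summary, sumPath)
    outFiles <- c(outFiles, sumPath)
    .log("INFO", logLevel, "stats: ",
         paste(names(stats), stats, sep = "=", collapse = ", "))
    invisible(list(stats = stats, clusters = clusterSets,
                   summary = summary, outputFiles = outFiles))
}
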