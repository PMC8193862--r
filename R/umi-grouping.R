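## UMI extraction and exact grouping. The UMI is a fixed-length prefix at
## the 5' start of R1 (and of R2 in the dual-UMI layout, where the two
## prefixes are concatenated into a single key).

#' Extract 5' UMIs and split reads into key + insert
#'
#' Splits each read into its UMI key and the remaining insert according to
#' the library layout in \code{config}:
#' \itemize{
#'   \item single-end, or paired with UMI on R1 only: the key is the first
#'     \code{UMIlength} bases of R1; the R1 insert is the remainder; R2 (if
#'     present) is left untouched.
#'   \item paired with UMIs on both mates: the key is the R1 prefix
#'     concatenated with the R2 prefix; both inserts are trimmed by
#'     \code{UMIlength}.
#' }
#' UMI base qualities are discarded. Insert lengths are validated against
#' \code{sequenceLength(config)}; a mismatch is an error rather than a
#' silent trim, since the method assumes a single shared read length.
#'
#' @param r1 \code{QualityScaledDNAStringSet} of raw R1 reads.
#' @param r2 \code{NULL} or the raw R2 reads (paired layouts).
#' @param config a [UmiRunConfig-class].
#' @return A [UmiReadSet-class].
#' @examples
#' cfg <- UmiRunConfig(UMIlength = 2, sequenceLength = 2)
#' r1 <- Biostrings::QualityScaledDNAStringSet(
#'     Biostrings::DNAStringSet(c(r = "ACGT")),
#'     Biostrings::PhredQuality("+5?I"))
#' umiKeys(extractUmi(r1, config = cfg))  # "AC"
#' @export
extractUmi <- function(r1, r2 = NULL, config) {
    stopifnot(is(config, "UmiRunConfig"))
    k <- config@UMIlength
    n <- config@sequenceLength
    paired <- !is.null(r2)
    if (config@pairedData && !paired)
        stop("config declares paired data but no R2 reads were given")
    if (!config@pairedData && paired)
        stop("config declares single-end data but R2 reads were given")
    if (paired && length(r1) != length(r2))
        stop("r1 and r2 differ in read count")
    dual <- config@UMIlocation == "R1andR2"

    if (length(r1) && any(width(r1) < k + 1L))
        stop("R1 read shorter than UMIlength + 1 (", k + 1L, ")")
    umi <- unname(substr(as.character(r1), 1L, k))
    insert1 <- narrow(r1, start = k + 1L)
    if (length(insert1) && any(width(insert1) != n))
        stop("R1 insert length ", unique(width(insert1))[1L],
             " does not match sequenceLength ", n)

    insert2 <- NULL
    if (paired) {
        if (dual) {
            if (length(r2) && any(width(r2) < k + 1L))
                stop("R2 read shorter than UMIlength + 1 (", k + 1L, ")")
            umi <- unname(paste0(umi, substr(as.character(r2), 1L, k)))
            insert2 <- narrow(r2, start = k + 1L)
            if (length(insert2) && any(width(insert2) != n))
                stop("R2 insert length does not match sequenceLength ", n)
        } else {
            insert2 <- r2
            if (length(insert2) && any(width(insert2) != n + k))
                stop("R2 read length does not match UMIlength + ",
                     "sequenceLength (", n + k, ")")
        }
    }
    if (length(umi) == 0L) umi <- character(0)
    new("UmiReadSet", umi = umi, r1 = insert1, r2 = insert2)
}

#' Group reads by exact UMI key
#'
#' Builds one group per distinct UMI key. Groups are ordered by descending
#' read count, with ties broken by lexicographic UMI order, so downstream
#' processing is deterministic regardless of input read order.
#'
#' @param readSet a [UmiReadSet-class] from [extractUmi()].
#' @return A [UmiGroupSet-class]; group counts sum to the input read count.
#' @export
groupByUmi <- function(readSet) {
    stopifnot(is(readSet, "UmiReadSet"))
    idx <- split(seq_along(readSet@umi), readSet@umi)  # lexicographic keys
    counts <- lengths(idx)
    ord <- order(-counts, names(idx), method = "radix")
    new("UmiGroupSet",
        umi = if (length(idx)) names(idx)[ord] else character(0),
        members = unname(idx[ord]),
        readSet = readSet)
}

#' Drop UMI groups below the read-count cutoff
#'
#' Data-cleaning step: keeps exactly the groups whose read count is at
#' least \code{countsCutoff} (the cutoff itself passes). Relative group
#' order is preserved.
#'
#' @param groups a [UmiGroupSet-class].
#' @param countsCutoff non-negative integer minimum reads per UMI.
#' @return The filtered [UmiGroupSet-class] (possibly empty).
#' @export
cleanGroups <- function(groups, countsCutoff) {
    stopifnot(is(groups, "UmiGroupSet"))
    countsCutoff <- as.integer(countsCutoff)
    if (countsCutoff < 0L) stop("countsCutoff must be >= 0")
    keep <- lengths(groups@members) >= countsCutoff
    new("UmiGroupSet",
        umi = groups@umi[keep],
        members = groups@members[keep],
        readSet = groups@readSet)
}
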