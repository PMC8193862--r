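#' @import methods
#' @importFrom Biostrings DNAStringSet QualityScaledDNAStringSet PhredQuality
#'   quality readQualityScaledDNAStringSet writeQualityScaledXStringSet
#' @importFrom IRanges narrow width
NULL

#' Run configuration for the deduplication pipeline
#'
#' Holds the seven user-facing parameters of the workflow (library layout,
#' UMI length, insert length, cleaning cutoff and the two merge distance
#' bounds) together with the input and output directories.
#'
#' @slot pairedData logical; \code{TRUE} for paired-end libraries.
#' @slot UMIlocation \code{"R1"} (UMI on the forward read only) or
#'   \code{"R1andR2"} (a UMI at the 5' start of both mates).
#' @slot UMIlength integer; UMI length in nucleotides (per read carrying one).
#' @slot sequenceLength integer; length of the insert, i.e. the biological
#'   sequence that remains after the UMI prefix is removed.
#' @slot countsCutoff integer; minimum read count a UMI group must reach to
#'   survive data cleaning (inclusive).
#' @slot UMIdistance integer; maximum Hamming distance between UMIs for
#'   merging.
#' @slot sequenceDistance integer; maximum Hamming distance between group
#'   consensus sequences for merging.
#' @slot inputDir,outputDir character paths.
#'
#' @seealso [UmiRunConfig()] for the user constructor.
#' @export
setClass("UmiRunConfig",
    slots = c(
        pairedData       = "logical",
        UMIlocation      = "character",
        UMIlength        = "integer",
        sequenceLength   = "integer",
        countsCutoff     = "integer",
        UMIdistance      = "integer",
        sequenceDistance = "integer",
        inputDir         = "character",
        outputDir        = "character"
    )
)

setValidity("UmiRunConfig", function(object) {
    msg <- character()
    if (!object@UMIlocation %in% c("R1", "R1andR2"))
        msg <- c(msg, "UMIlocation must be \"R1\" or \"R1andR2\"")
    if (object@UMIlocation == "R1andR2" && !object@pairedData)
        msg <- c(msg, "UMIlocation \"R1andR2\" requires pairedData = TRUE")
    if (object@UMIlength < 1L)
        msg <- c(msg, "UMIlength must be >= 1")
    if (object@sequenceLength < 1L)
        msg <- c(msg, "sequenceLength must be >= 1")
    if (object@countsCutoff < 0L)
        msg <- c(msg, "countsCutoff must be >= 0")
    if (object@UMIdistance < 0L)
        msg <- c(msg, "UMIdistance must be >= 0")
    if (object@sequenceDistance < 0L)
        msg <- c(msg, "sequenceDistance must be >= 0")
    if (length(msg)) msg else TRUE
})

#' Construct a run configuration
#'
#' @param pairedData logical; paired-end input?
#' @param UMIlocation \code{"R1"} or \code{"R1andR2"}.
#' @param UMIlength UMI length (nt) per UMI-carrying read.
#' @param sequenceLength insert length (nt), i.e. read length minus
#'   \code{UMIlength} for UMI-carrying reads. Output consensus reads have
#'   exactly this length.
#' @param countsCutoff minimum reads per UMI group (inclusive) for cleaning.
#' @param UMIdistance maximum Hamming distance between UMIs for merging.
#' @param sequenceDistance maximum Hamming distance between group consensus
#'   sequences for merging.
#' @param inputDir,outputDir directories holding the raw FASTQ input and
#'   receiving the corrected output.
#' @return A validated [UmiRunConfig-class] object.
#' @examples
#' cfg <- UmiRunConfig(pairedData = FALSE, UMIlength = 12,
#'                     sequenceLength = 50, countsCutoff = 6,
#'                     UMIdistance = 1, sequenceDistance = 3)
#' @export
UmiRunConfig <- function(pairedData = FALSE, UMIlocation = "R1",
                         UMIlength, sequenceLength,
                         countsCutoff = 1L, UMIdistance = 1L,
                         sequenceDistance = 3L,
                         inputDir = ".", outputDir = "corrected") {
    new("UmiRunConfig",
        pairedData       = as.logical(pairedData),
        UMIlocation      = as.character(UMIlocation),
        UMIlength        = as.integer(UMIlength),
        sequenceLength   = as.integer(sequenceLength),
        countsCutoff     = as.integer(countsCutoff),
        UMIdistance      = as.integer(UMIdistance),
        sequenceDistance = as.integer(sequenceDistance),
        inputDir         = as.character(inputDir),
        outputDir        = as.character(outputDir))
}

setMethod("show", "UmiRunConfig", function(object) {
    cat("UmiRunConfig\n",
        "  pairedData:       ", object@pairedData, "\n",
        "  UMIlocation:      ", object@UMIlocation, "\n",
        "  UMIlength:        ", object@UMIlength, "\n",
        "  sequenceLength:   ", object@sequenceLength, "\n",
        "  countsCutoff:     ", object@countsCutoff, "\n",
        "  UMIdistance:      ", object@UMIdistance, "\n",
        "  sequenceDistance: ", object@sequenceDistance, "\n",
        "  inputDir:         ", object@inputDir, "\n",
        "  outputDir:        ", object@outputDir, "\n", sep = "")
})

#' UMI-extracted read set
#'
#' Reads after UMI extraction: one UMI key per read plus the insert
#' (and untouched or trimmed mate for paired data). In the dual-UMI layout
#' the key is the concatenation of the R1 and R2 UMIs.
#'
#' @slot umi character vector, one UMI key per read.
#' @slot r1 [Biostrings::QualityScaledDNAStringSet-class] of R1 inserts.
#' @slot r2 \code{NULL}, or a \code{QualityScaledDNAStringSet} of mates.
#' @export
setClass("UmiReadSet",
    slots = c(umi = "character", r1 = "QualityScaledDNAStringSet",
              r2 = "ANY")
)

setValidity("UmiReadSet", function(object) {
    msg <- character()
    if (length(object@umi) != length(object@r1))
        msg <- c(msg, "one UMI key per read required")
    if (length(object@r1) && length(unique(width(object@r1))) != 1L)
        msg <- c(msg, "all R1 inserts must have equal length")
    if (!is.null(object@r2)) {
        if (!is(object@r2, "QualityScaledDNAStringSet"))
            msg <- c(msg, "r2 must be NULL or a QualityScaledDNAStringSet")
        else if (length(object@r2) != length(object@r1))
            msg <- c(msg, "r1 and r2 must have equal length")
        else if (length(object@r2) &&
                 length(unique(width(object@r2))) != 1L)
            msg <- c(msg, "all R2 reads must have equal length")
    }
    if (length(msg)) msg else TRUE
})

setMethod("show", "UmiReadSet", function(object) {
    cat("UmiReadSet of ", length(object@r1), " read",
        if (length(object@r1) != 1L) "s", " (",
        if (is.null(object@r2)) "single-end" else "paired-end", ")\n",
        "  distinct UMI keys: ", length(unique(object@umi)), "\n",
        sep = "")
})

#' Reads grouped by exact UMI
#'
#' One group per distinct UMI key, ordered by descending read count with
#' lexicographic tie-break on the UMI, holding indices into the underlying
#' [UmiReadSet-class].
#'
#' @slot umi character vector of distinct UMI keys (group order).
#' @slot members list of integer vectors; read indices per group.
#' @slot readSet the underlying [UmiReadSet-class].
#' @export
setClass("UmiGroupSet",
    slots = c(umi = "character", members = "list", readSet = "UmiReadSet")
)

setValidity("UmiGroupSet", function(object) {
    msg <- character()
    if (length(object@umi) != length(object@members))
        msg <- c(msg, "one member index vector per UMI required")
    if (anyDuplicated(object@umi))
        msg <- c(msg, "UMI keys must be distinct across groups")
    n <- lengths(object@members)
    if (length(n) && any(n < 1L))
        msg <- c(msg, "every group must have at least one member")
    if (length(msg)) msg else TRUE
})

setMethod("show", "UmiGroupSet", function(object) {
    n <- lengths(object@members)
    cat("UmiGroupSet of ", length(object@umi), " UMI group",
        if (length(object@umi) != 1L) "s",
        " over ", sum(n), " reads\n", sep = "")
    if (length(n))
        cat("  read counts: max ", max(n), ", median ",
            stats::median(n), ", min ", min(n), "\n", sep = "")
})

#' Merged UMI clusters with final consensus reads
#'
#' Result of greedy UMI merging: each cluster has a representative UMI
#' (the seed, i.e. the member group with the highest read count), the
#' absorbed UMIs, the pooled read count, and the final consensus read(s)
#' recomputed from all pooled raw reads.
#'
#' @slot representativeUmi character vector, one per cluster.
#' @slot absorbedUmis list of character vectors (may be empty), per cluster.
#' @slot pooledCount integer vector of pooled read counts.
#' @slot consensusR1 [Biostrings::QualityScaledDNAStringSet-class] of final
#'   R1 consensus reads, one per cluster.
#' @slot consensusR2 \code{NULL} or the R2 counterpart.
#' @export
setClass("UmiClusterSet",
    slots = c(representativeUmi = "character", absorbedUmis = "list",
              pooledCount = "integer",
              consensusR1 = "QualityScaledDNAStringSet",
              consensusR2 = "ANY")
)

setValidity("UmiClusterSet", function(object) {
    msg <- character()
    k <- length(object@representativeUmi)
    if (length(object@absorbedUmis) != k || length(object@pooledCount) != k ||
        length(object@consensusR1) != k)
        msg <- c(msg, "all per-cluster slots must have equal length")
    if (!is.null(object@consensusR2) &&
        length(object@consensusR2) != k)
        msg <- c(msg, "consensusR2 must be NULL or match cluster count")
    if (length(msg)) msg else TRUE
})

setMethod("show", "UmiClusterSet", function(object) {
    k <- length(object@representativeUmi)
    merged <- sum(lengths(object@absorbedUmis) > 0L)
    cat("UmiClusterSet of ", k, " cluster", if (k != 1L) "s",
        " (", sum(object@pooledCount), " pooled reads; ",
        merged, " cluster", if (merged != 1L) "s",
        " absorbed at least one UMI)\n", sep = "")
})

#' @rdname UmiClusterSet-class
#' @param x a \code{UmiClusterSet}.
#' @export
setGeneric("representativeUmi", function(x) standardGeneric("representativeUmi"))
#' @rdname UmiClusterSet-class
#' @export
setMethod("representativeUmi", "UmiClusterSet", function(x) x@representativeUmi)

#' @rdname UmiClusterSet-class
#' @export
setGeneric("absorbedUmis", function(x) standardGeneric("absorbedUmis"))
#' @rdname UmiClusterSet-class
#' @export
setMethod("absorbedUmis", "UmiClusterSet", function(x) x@absorbedUmis)

#' @rdname UmiClusterSet-class
#' @export
setGeneric("pooledCount", function(x) standardGeneric("pooledCount"))
#' @rdname UmiClusterSet-class
#' @export
setMethod("pooledCount", "UmiClusterSet", function(x) x@pooledCount)

#' @rdname UmiClusterSet-class
#' @export
setGeneric("consensusR1", function(x) standardGeneric("consensusR1"))
#' @rdname UmiClusterSet-class
#' @export
setMethod("consensusR1", "UmiClusterSet", function(x) x@consensusR1)

#' @rdname UmiClusterSet-class
#' @export
setGeneric("consensusR2", function(x) standardGeneric("consensusR2"))
#' @rdname UmiClusterSet-class
#' @export
setMethod("consensusR2", "UmiClusterSet", function(x) x@consensusR2)

#' @rdname UmiGroupSet-class
#' @param x a \code{UmiGroupSet} (or, for \code{umiKeys}, any object with
#'   UMI keys).
#' @export
setGeneric("umiKeys", function(x) standardGeneric("umiKeys"))
#' @rdname UmiGroupSet-class
#' @export
setMethod("umiKeys", "UmiGroupSet", function(x) x@umi)
#' @rdname UmiReadSet-class
#' @param x a \code{UmiReadSet}.
#' @export
setMethod("umiKeys", "UmiReadSet", function(x) x@umi)

#' @rdname UmiGroupSet-class
#' @export
setGeneric("groupCounts", function(x) standardGeneric("groupCounts"))
#' @rdname UmiGroupSet-class
#' @export
setMethod("groupCounts", "UmiGroupSet", function(x) {
    n <- lengths(x@members)
    names(n) <- x@umi
    n
})

#' @rdname UmiGroupSet-class
#' @export
setGeneric("groupMembers", function(x) standardGeneric("groupMembers"))
#' @rdname UmiGroupSet-class
#' @export
setMethod("groupMembers", "UmiGroupSet", function(x) {
    m <- x@members
    names(m) <- x@umi
    m
})

#' Number of groups / clusters
#' @param x a \code{UmiGroupSet} or \code{UmiClusterSet}.
#' @export
setMethod("length", "UmiGroupSet", function(x) length(x@umi))
#' @rdname length-UmiGroupSet-method
#' @export
setMethod("length", "UmiClusterSet", function(x) length(x@representativeUmi))
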