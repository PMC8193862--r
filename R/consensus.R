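## Per-base consensus calling over a group of equal-length reads.
##
## For every position, each observed base b gets a criterion
##     criterion(b) = (freq_pct(b) + meanQ(b)) / 2
## where freq_pct is the percentage of reads showing b at that position
## (0-100) and meanQ the arithmetic mean of their Phred scores (0-41), so
## the two terms live on comparable scales. The base with the maximal
## criterion wins; a criterion tie goes to the base with the higher mean
## quality, and any remaining tie to the lexicographically smallest base
## (A < C < G < N < T). The consensus quality at the position is the
## winner's mean quality, rounded half-up and clipped to [0, 41].

.BASES <- c("A", "C", "G", "N", "T")  # lexicographic order, ties resolve here

#' Per-position base counts and mean qualities of a read group
#'
#' Tallies, for every position of an equal-length read group, how many
#' reads show each base in \{A, C, G, T, N\} and the arithmetic mean Phred
#' score of those reads.
#'
#' @param x non-empty \code{QualityScaledDNAStringSet} of equal-length
#'   reads over \{A, C, G, T, N\}.
#' @return A list with \code{counts} (5 x L integer matrix, rows A, C, G,
#'   N, T), \code{meanQ} (5 x L numeric matrix, \code{NA} where the count
#'   is zero) and \code{total} (the number of reads).
#' @export
positionProfile <- function(x) {
    if (!is(x, "QualityScaledDNAStringSet"))
        stop("x must be a QualityScaledDNAStringSet")
    if (length(x) == 0L)
        stop("cannot profile an empty read group")
    if (length(unique(width(x))) != 1L)
        stop("all reads in a group must have equal length")
    sm <- as.matrix(x)
    if (!all(sm %in% .BASES))
        stop("sequences may only contain A, C, G, T or N")
    qm <- as(quality(x), "matrix")
    counts <- matrix(0L, nrow = 5L, ncol = ncol(sm),
                     dimnames = list(.BASES, NULL))
    sumQ <- matrix(0, nrow = 5L, ncol = ncol(sm),
                   dimnames = list(.BASES, NULL))
    for (b in .BASES) {
        hit <- sm == b
        counts[b, ] <- as.integer(colSums(hit))
        sumQ[b, ] <- colSums(qm * hit)
    }
    meanQ <- sumQ / counts  # NaN where count == 0
    meanQ[counts == 0L] <- NA_real_
    list(counts = counts, meanQ = meanQ, total = length(x))
}

## round half up to integer, clip to the Phred range
.phredRound <- function(q) {
    pmin(pmax(as.integer(floor(q + 0.5)), 0L), 41L)
}

#' Call the consensus base at one position
#'
#' Applies the frequency/quality criterion to one position profile column.
#'
#' @param counts named integer vector of base counts at the position
#'   (names from \{A, C, G, N, T\}); at least one count must be positive.
#' @param meanQ named numeric vector of mean Phred scores, parallel to
#'   \code{counts} (values for zero-count bases are ignored).
#' @return A list with \code{base} (character) and \code{quality}
#'   (integer, the winner's mean quality rounded half-up into [0, 41]).
#' @examples
#' consensusBase(c(A = 3, C = 1), c(A = 30, C = 40))
#' # criterion A = (75 + 30)/2 = 52.5 beats C = (25 + 40)/2 = 32.5
#' @export
consensusBase <- function(counts, meanQ) {
    total <- sum(counts)
    if (total < 1L) stop("all-zero position profile")
    ord <- order(names(counts), method = "radix")  # lexicographic tie-break
    counts <- counts[ord]
    meanQ <- meanQ[ord]
    obs <- which(counts > 0L)
    crit <- (100 * counts[obs] / total + meanQ[obs]) / 2
    best <- obs[crit == max(crit)]
    if (length(best) > 1L)
        best <- best[meanQ[best] == max(meanQ[best])]
    best <- best[1L]
    list(base = names(counts)[best],
         quality = unname(.phredRound(meanQ[best])))
}

## Vectorized criterion over all columns of a profile; returns the winning
## row index per column under the same tie-break chain as consensusBase().
.chooseBases <- function(profile) {
    counts <- profile$counts
    meanQ <- profile$meanQ
    crit <- (100 * counts / profile$total + meanQ) / 2  # NA where count 0
    L <- ncol(counts)
    pick <- integer(L)
    for (j in seq_len(L)) {
        cj <- crit[, j]
        top <- which(cj == max(cj, na.rm = TRUE))
        if (length(top) > 1L) {
            qj <- meanQ[top, j]
            top <- top[qj == max(qj)]
        }
        pick[j] <- top[1L]  # rows are in lexicographic base order
    }
    pick
}

#' Collapse a read group into its consensus read
#'
#' Applies the per-position criterion to every column of the group profile.
#' The result is a single sequence with one quality per position (the
#' winning base's mean quality, rounded half-up).
#'
#' @param x non-empty \code{QualityScaledDNAStringSet} of equal-length
#'   reads.
#' @return A list with \code{sequence} (character), \code{quality}
#'   (integer vector) and \code{support} (number of reads collapsed).
#' @examples
#' reads <- Biostrings::QualityScaledDNAStringSet(
#'     Biostrings::DNAStringSet(c("ACGT", "ACGT", "ACGA")),
#'     Biostrings::PhredQuality(c("IIII", "IIII", "III!")))
#' consensusRead(reads)$sequence  # "ACGT"
#' @export
consensusRead <- function(x) {
    profile <- positionProfile(x)
    pick <- .chooseBases(profile)
    j <- seq_along(pick)
    list(sequence = paste(.BASES[pick], collapse = ""),
         quality = .phredRound(profile$meanQ[cbind(pick, j)]),
         support = profile$total)
}

## Stack a list of consensusRead() results into a QualityScaledDNAStringSet
## named by `ids`.
.stackConsensus <- function(cons, ids) {
    seqs <- vapply(cons, `[[`, character(1), "sequence")
    quals <- vapply(cons, function(cr) encodePhred(cr$quality), character(1))
    out <- QualityScaledDNAStringSet(DNAStringSet(seqs), PhredQuality(quals))
    names(out) <- ids
    out
}
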