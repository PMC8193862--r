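## Greedy UMI merging. Seeds on the unassigned UMI group with the most
## reads; absorbs every other unassigned group whose UMI is within
## UMIdistance of the seed's AND whose step-1 consensus sequence(s) are
## within sequenceDistance of the seed's; recomputes the final consensus
## from the pooled raw reads of the cluster; repeats until the pool is
## empty. Merging is seed-centric: a group close to an absorbed member but
## far from the seed is never chained in.

#' Hamming distance between equal-length strings
#'
#' Number of mismatching positions. \code{b} may be a vector; \code{a} is
#' recycled against it.
#'
#' @param a single string.
#' @param b character vector of strings the same length as \code{a}.
#' @return Integer vector of distances.
#' @examples
#' hammingDist("GAGCTTCAACTC", "GCGCTTCAACTC")  # 1
#' @export
hammingDist <- function(a, b) {
    if (length(a) != 1L) stop("a must be a single string")
    ra <- charToRaw(a)
    vapply(b, function(s) {
        rb <- charToRaw(s)
        if (length(rb) != length(ra))
            stop("hamming distance requires equal-length strings (",
                 length(ra), " vs ", length(rb), ")")
        sum(ra != rb)
    }, integer(1), USE.NAMES = FALSE)
}

## Step-1 consensus for every group: list with one consensusRead() result
## per group for R1 (and R2 when paired).
.groupConsensus <- function(groups) {
    rs <- groups@readSet
    paired <- !is.null(rs@r2)
    cons1 <- lapply(groups@members, function(i) consensusRead(rs@r1[i]))
    cons2 <- if (paired)
        lapply(groups@members, function(i) consensusRead(rs@r2[i]))
    list(r1 = cons1, r2 = cons2)
}

#' Greedily merge near-identical UMI groups
#'
#' Implements the merge procedure on cleaned UMI groups: each round seeds
#' on the unassigned group with the maximal read count (ties broken by
#' lexicographically smallest UMI) and absorbs every unassigned group
#' within \code{UMIdistance} of the seed UMI whose step-1 consensus reads
#' are all within \code{sequenceDistance} of the seed's (R1, and R2 when
#' paired, each against the same bound). The final consensus of a cluster
#' is recomputed from the pooled raw member reads, so absorbed groups
#' contribute with their full read weight.
#'
#' @param groups a cleaned [UmiGroupSet-class].
#' @param config a [UmiRunConfig-class] supplying \code{UMIdistance} and
#'   \code{sequenceDistance}.
#' @return A [UmiClusterSet-class] in cluster-creation order. Every input
#'   group lands in exactly one cluster.
#' @export
mergeUmiGroups <- function(groups, config) {
    stopifnot(is(groups, "UmiGroupSet"), is(config, "UmiRunConfig"))
    rs <- groups@readSet
    paired <- !is.null(rs@r2)
    step1 <- .groupConsensus(groups)
    seq1 <- vapply(step1$r1, `[[`, character(1), "sequence")
    seq2 <- if (paired) vapply(step1$r2, `[[`, character(1), "sequence")

    counts <- lengths(groups@members)
    umis <- groups@umi
    remaining <- seq_along(umis)

    repUmi <- character(0)
    absorbed <- list()
    pooled <- integer(0)
    cons1 <- list()
    cons2 <- list()

    while (length(remaining)) {
        ## seed: max count, ties by lexicographically smallest UMI
        seed <- remaining[order(-counts[remaining], umis[remaining],
                                method = "radix")][1L]
        others <- setdiff(remaining, seed)
        take <- integer(0)
        if (length(others)) {
            ok <- hammingDist(umis[seed], umis[others]) <= config@UMIdistance
            ok <- ok & hammingDist(seq1[seed], seq1[others]) <=
                config@sequenceDistance
            if (paired)
                ok <- ok & hammingDist(seq2[seed], seq2[others]) <=
                    config@sequenceDistance
            take <- others[ok]
        }
        cluster <- c(seed, take)
        members <- unlist(groups@members[cluster], use.names = FALSE)
        repUmi <- c(repUmi, umis[seed])
        absorbed <- c(absorbed, list(umis[take]))
        pooled <- c(pooled, sum(counts[cluster]))
        if (length(take)) {
            cons1 <- c(cons1, list(consensusRead(rs@r1[members])))
            if (paired)
                cons2 <- c(cons2, list(consensusRead(rs@r2[members])))
        } else {
            ## singleton cluster: final consensus equals step-1 consensus
            cons1 <- c(cons1, list(step1$r1[[seed]]))
            if (paired) cons2 <- c(cons2, list(step1$r2[[seed]]))
        }
        remaining <- setdiff(remaining, cluster)
    }

    ids <- sprintf("umi=%s;reads=%d", repUmi, pooled)
    new("UmiClusterSet",
        representativeUmi = repUmi,
        absorbedUmis = absorbed,
        pooledCount = pooled,
        consensusR1 = .stackConsensus(cons1, ids),
        consensusR2 = if (paired) .stackConsensus(cons2, ids))
}
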