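## Synthetic UMI-tagged libraries with known ground truth.
##
## Each true molecule gets a random insert and a UMI drawn by rejection
## sampling so that all true UMIs are pairwise well separated (Hamming
## distance >= minUmiDist), which makes "one cluster per molecule" exact
## rather than probable. PCR duplicates are emitted per molecule; every
## emitted base is substituted independently at the applicable rate
## (uniformly over the three alternative bases). Correct bases carry
## qualityHigh, substituted bases qualityLow, so the frequency/quality
## consensus criterion is exercised with a controlled contrast. No indels
## are simulated: the consensus method is strictly columnar.

.randSeq <- function(n, len) {
    vapply(seq_len(n), function(i)
        paste(sample(c("A", "C", "G", "T"), len, replace = TRUE),
              collapse = ""), character(1))
}

## pairwise well-separated UMIs by rejection sampling
.separatedUmis <- function(n, len, minDist, maxTries = 1000L) {
    umis <- character(0)
    tries <- 0L
    while (length(umis) < n) {
        cand <- .randSeq(1L, len)
        if (!length(umis) || all(hammingDist(cand, umis) >= minDist)) {
            umis <- c(umis, cand)
            tries <- 0L
        } else {
            tries <- tries + 1L
            if (tries > maxTries)
                stop("could not draw ", n, " UMIs of length ", len,
                     " at pairwise distance >= ", minDist,
                     "; use longer UMIs or fewer molecules")
        }
    }
    umis
}

## substitute each base independently at `rate`; returns the sequence plus
## the per-base error mask
.mutate <- function(seq, rate) {
    bases <- strsplit(seq, "", fixed = TRUE)[[1L]]
    hit <- stats::runif(length(bases)) < rate
    if (any(hit)) {
        alt <- c("A", "C", "G", "T")
        bases[hit] <- vapply(bases[hit], function(b)
            sample(setdiff(alt, b), 1L), character(1))
    }
    list(seq = paste(bases, collapse = ""), err = hit)
}

.emitRead <- function(umi, insert, umiRate, insRate, qHigh, qLow) {
    mu <- .mutate(umi, umiRate)
    mi <- .mutate(insert, insRate)
    qual <- c(ifelse(mu$err, qLow, qHigh), ifelse(mi$err, qLow, qHigh))
    list(seq = paste0(mu$seq, mi$seq), qual = qual)
}

#' Simulate a UMI-tagged sequencing library with ground truth
#'
#' Generates a synthetic library of \code{nMolecules} true molecules, each
#' tagged with a unique, well-separated UMI and amplified into a known
#' number of PCR duplicates, with independent per-base substitution errors
#' in the UMI and insert portions. Optionally writes standard FASTQ
#' file(s) and a \code{truth.csv} table.
#'
#' @param nMolecules number of true molecules.
#' @param umiLength UMI length (nt) per UMI-carrying read.
#' @param insertLength insert length (nt).
#' @param duplicates PCR duplicates per molecule: a single value for a
#'   fixed count, or a length-2 vector \code{c(lo, hi)} for a uniform
#'   integer draw.
#' @param umiErrorRate,insertErrorRate per-base substitution probabilities
#'   in \code{[0, 0.5)}.
#' @param qualityHigh,qualityLow Phred scores given to correct and
#'   substituted bases (default 37/14, a typical contrast between a clean
#'   Illumina call and a poor one).
#' @param paired emit paired-end reads? The R2 mate is an independent true
#'   sequence per molecule.
#' @param dualUmi put a (distinct) UMI at the start of R2 as well
#'   (requires \code{paired}); R2 then carries its own \code{umiLength}
#'   prefix, otherwise R2 is a full-length read of
#'   \code{umiLength + insertLength} nt with no UMI.
#' @param minUmiDist minimum pairwise Hamming distance enforced between
#'   true UMIs (per tagged read end).
#' @param seed integer seed; the generator is fully reproducible from it.
#' @param outputDir if non-\code{NULL}, FASTQ file(s)
#'   (\code{<prefix>_R1.fastq}, \code{<prefix>_R2.fastq}) and
#'   \code{<prefix>_truth.csv} are written there.
#' @param prefix file-name prefix used with \code{outputDir}.
#' @return (Invisibly when writing) a list with \code{truth} (data frame:
#'   molecule_id, true_umi, true_insert, true_insert_r2, n_duplicates),
#'   \code{r1}/\code{r2} (\code{QualityScaledDNAStringSet}s of emitted
#'   reads) and \code{files} (paths written, if any).
#' @export
simulateUmiLibrary <- function(nMolecules = 200L, umiLength = 12L,
                               insertLength = 50L, duplicates = c(8L, 30L),
                               umiErrorRate = 0.002, insertErrorRate = 0.005,
                               qualityHigh = 37L, qualityLow = 14L,
                               paired = FALSE, dualUmi = FALSE,
                               minUmiDist = 3L, seed = 1L,
                               outputDir = NULL, prefix = "sim") {
    if (umiErrorRate < 0 || umiErrorRate >= 0.5 ||
        insertErrorRate < 0 || insertErrorRate >= 0.5)
        stop("error rates must lie in [0, 0.5)")
    if (any(c(qualityHigh, qualityLow) < 0) ||
        any(c(qualityHigh, qualityLow) > 41))
        stop("quality values must lie in [0, 41]")
    if (dualUmi && !paired)
        stop("dualUmi = TRUE requires paired = TRUE")
    set.seed(as.integer(seed))

    dupRange <- if (length(duplicates) == 1L) rep(as.integer(duplicates), 2L)
                else as.integer(duplicates)
    choices <- seq(dupRange[1L], dupRange[2L])
    nDup <- if (length(choices) == 1L) rep(choices, nMolecules)
            else sample(choices, nMolecules, replace = TRUE)
    umi1 <- .separatedUmis(nMolecules, umiLength, minUmiDist)
    umi2 <- if (dualUmi) .separatedUmis(nMolecules, umiLength, minUmiDist)
    ins1 <- .randSeq(nMolecules, insertLength)
    ins2 <- if (paired && dualUmi)
        .randSeq(nMolecules, insertLength)
    else if (paired)
        .randSeq(nMolecules, umiLength + insertLength)  # full read, no UMI

    seq1 <- character(0); qual1 <- character(0)
    seq2 <- character(0); qual2 <- character(0)
    ids <- character(0)
    for (m in seq_len(nMolecules)) {
        for (d in seq_len(nDup[m])) {
            r <- .emitRead(umi1[m], ins1[m], umiErrorRate, insertErrorRate,
                           qualityHigh, qualityLow)
            seq1 <- c(seq1, r$seq)
            qual1 <- c(qual1, encodePhred(r$qual))
            ids <- c(ids, sprintf("mol%d_dup%d", m, d))
            if (paired) {
                if (dualUmi) {
                    r2 <- .emitRead(umi2[m], ins2[m], umiErrorRate,
                                    insertErrorRate, qualityHigh, qualityLow)
                } else {
                    mi <- .mutate(ins2[m], insertErrorRate)
                    r2 <- list(seq = mi$seq,
                               qual = ifelse(mi$err, qualityLow, qualityHigh))
                }
                seq2 <- c(seq2, r2$seq)
                qual2 <- c(qual2, encodePhred(r2$qual))
            }
        }
    }
    ## shuffle reads so molecule order carries no information
    perm <- sample(length(seq1))
    r1 <- QualityScaledDNAStringSet(DNAStringSet(seq1[perm]),
                                    PhredQuality(qual1[perm]))
    names(r1) <- ids[perm]
    r2 <- NULL
    if (paired) {
        r2 <- QualityScaledDNAStringSet(DNAStringSet(seq2[perm]),
                                        PhredQuality(qual2[perm]))
        names(r2) <- ids[perm]
    }
    truth <- data.frame(
        molecule_id = seq_len(nMolecules),
        true_umi = if (dualUmi) paste0(umi1, umi2) else umi1,
        true_insert = ins1,
        true_insert_r2 = if (paired) ins2 else rep("", nMolecules),
        n_duplicates = nDup,
        stringsAsFactors = FALSE)

    files <- character(0)
    if (!is.null(outputDir)) {
        if (!dir.exists(outputDir)) dir.create(outputDir, recursive = TRUE)
        f1 <- file.path(outputDir, paste0(prefix, "_R1.fastq"))
        writeFastq(r1, f1)
        files <- f1
        if (paired) {
            f2 <- file.path(outputDir, paste0(prefix, "_R2.fastq"))
            writeFastq(r2, f2)
            files <- c(files, f2)
        }
        ft <- file.path(outputDir, paste0(prefix, "_truth.csv"))
        utils::write.csv(truth, ft, row.names = FALSE, quote = FALSE)
        files <- c(files, ft)
    }
    out <- list(truth = truth, r1 = r1, r2 = r2, files = files)
    if (is.null(outputDir)) out else invisible(out)
}
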