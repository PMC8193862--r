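## Independent brute-force oracles and small fixture builders. The oracles
## work on plain character vectors / integer lists and deliberately share
## no code with the package internals.

qsds <- function(seqs, quals) {
    if (is.list(quals) || is.numeric(quals))
        quals <- vapply(if (is.list(quals)) quals else list(quals),
                        encodePhred, character(1))
    x <- Biostrings::QualityScaledDNAStringSet(
        Biostrings::DNAStringSet(seqs),
        Biostrings::PhredQuality(quals))
    names(x) <- sprintf("r%d", seq_along(x))
    x
}

qualsOf <- function(x) {
    lapply(as.character(Biostrings::quality(x)),
           function(s) utf8ToInt(s) - 33L)
}

randomReadGroup <- function(n, len, alphabet = c("A", "C", "G", "T", "N")) {
    seqs <- vapply(seq_len(n), function(i)
        paste(sample(alphabet, len, replace = TRUE), collapse = ""),
        character(1))
    quals <- lapply(seq_len(n), function(i) sample(0:41, len, replace = TRUE))
    qsds(seqs, quals)
}

## Brute-force per-position consensus: for each column, tally bases with
## nested loops, score (freq% + meanQ)/2, break ties by mean quality then
## alphabetically.
oracleConsensus <- function(seqs, quals) {
    n <- length(seqs)
    L <- nchar(seqs[1L])
    outBase <- character(L)
    outQual <- integer(L)
    for (j in seq_len(L)) {
        seen <- list()
        for (i in seq_len(n)) {
            b <- substr(seqs[i], j, j)
            seen[[b]] <- c(seen[[b]], quals[[i]][j])
        }
        bases <- sort(names(seen))
        crit <- numeric(length(bases))
        mq <- numeric(length(bases))
        for (k in seq_along(bases)) {
            qk <- seen[[bases[k]]]
            mq[k] <- sum(qk) / length(qk)
            crit[k] <- (100 * length(qk) / n + mq[k]) / 2
        }
        cand <- which(crit == max(crit))
        if (length(cand) > 1L) cand <- cand[mq[cand] == max(mq[cand])]
        pick <- cand[1L]  # bases sorted, so first is alphabetically smallest
        outBase[j] <- bases[pick]
        outQual[j] <- as.integer(min(max(floor(mq[pick] + 0.5), 0), 41))
    }
    list(sequence = paste(outBase, collapse = ""), quality = outQual)
}

oracleHamming <- function(a, b) {
    sum(strsplit(a, "")[[1L]] != strsplit(b, "")[[1L]])
}

## Direct transcription of the greedy merge procedure on plain lists.
## `inst` is a list of groups, each list(umi=, seqs=, quals=) with optional
## seqs2/quals2 for paired data. Returns clusters as
## list(rep=, absorbed=, pooled=, cons=, cons2=).
oracleMerge <- function(inst, umiDist, seqDist) {
    paired <- !is.null(inst[[1L]]$seqs2)
    step1 <- lapply(inst, function(g) oracleConsensus(g$seqs, g$quals))
    step1b <- if (paired)
        lapply(inst, function(g) oracleConsensus(g$seqs2, g$quals2))
    counts <- vapply(inst, function(g) length(g$seqs), integer(1))
    umis <- vapply(inst, `[[`, character(1), "umi")
    pool <- seq_along(inst)
    clusters <- list()
    while (length(pool)) {
        best <- pool[counts[pool] == max(counts[pool])]
        seed <- best[order(umis[best])][1L]
        grabbed <- seed
        for (g in setdiff(pool, seed)) {
            okU <- oracleHamming(umis[seed], umis[g]) <= umiDist
            okS <- oracleHamming(step1[[seed]]$sequence,
                                 step1[[g]]$sequence) <= seqDist
            okS2 <- !paired || oracleHamming(step1b[[seed]]$sequence,
                                             step1b[[g]]$sequence) <= seqDist
            if (okU && okS && okS2) grabbed <- c(grabbed, g)
        }
        allSeqs <- unlist(lapply(inst[grabbed], `[[`, "seqs"))
        allQuals <- do.call(c, lapply(inst[grabbed], `[[`, "quals"))
        cl <- list(rep = umis[seed],
                   absorbed = umis[setdiff(grabbed, seed)],
                   pooled = sum(counts[grabbed]),
                   cons = oracleConsensus(allSeqs, allQuals))
        if (paired) {
            allSeqs2 <- unlist(lapply(inst[grabbed], `[[`, "seqs2"))
            allQuals2 <- do.call(c, lapply(inst[grabbed], `[[`, "quals2"))
            cl$cons2 <- oracleConsensus(allSeqs2, allQuals2)
        }
        clusters <- c(clusters, list(cl))
        pool <- setdiff(pool, grabbed)
    }
    clusters
}

## Build a UmiGroupSet directly from an oracleMerge-style instance list,
## bypassing extraction (the UMIs act as opaque keys).
groupSetFromInstance <- function(inst) {
    umis <- vapply(inst, `[[`, character(1), "umi")
    seqs <- unlist(lapply(inst, `[[`, "seqs"))
    quals <- do.call(c, lapply(inst, `[[`, "quals"))
    paired <- !is.null(inst[[1L]]$seqs2)
    r2 <- NULL
    if (paired) {
        seqs2 <- unlist(lapply(inst, `[[`, "seqs2"))
        quals2 <- do.call(c, lapply(inst, `[[`, "quals2"))
        r2 <- qsds(seqs2, quals2)
    }
    rs <- methods::new("UmiReadSet",
                       umi = rep(umis, vapply(inst, function(g)
                           length(g$seqs), integer(1))),
                       r1 = qsds(seqs, quals), r2 = r2)
    groupByUmi(rs)
}

## Random merge instance: g groups whose UMIs and reads are perturbations
## of a few templates, so that merges genuinely happen in some trials.
randomMergeInstance <- function(nGroups, umiLen = 6L, readLen = 12L,
                                paired = FALSE) {
    perturb <- function(s, d) {
        b <- strsplit(s, "")[[1L]]
        pos <- sample(length(b), min(d, length(b)))
        for (p in pos) b[p] <- sample(setdiff(c("A", "C", "G", "T"), b[p]), 1L)
        paste(b, collapse = "")
    }
    nTemplates <- max(1L, nGroups %/% 3L)
    umiTemplates <- vapply(seq_len(nTemplates), function(i)
        paste(sample(c("A", "C", "G", "T"), umiLen, replace = TRUE),
              collapse = ""), character(1))
    seqTemplates <- vapply(seq_len(nTemplates), function(i)
        paste(sample(c("A", "C", "G", "T"), readLen, replace = TRUE),
              collapse = ""), character(1))
    umis <- character(0)
    inst <- list()
    for (g in seq_len(nGroups)) {
        t <- sample(nTemplates, 1L)
        umi <- perturb(umiTemplates[t], sample(0:2, 1L))
        while (umi %in% umis) umi <- perturb(umiTemplates[t], sample(0:2, 1L))
        umis <- c(umis, umi)
        n <- sample(1:6, 1L)
        seqs <- vapply(seq_len(n), function(i)
            perturb(seqTemplates[t], sample(0:2, 1L)), character(1))
        quals <- lapply(seq_len(n), function(i)
            sample(0:41, readLen, replace = TRUE))
        grp <- list(umi = umi, seqs = seqs, quals = quals)
        if (paired) {
            grp$seqs2 <- vapply(seq_len(n), function(i)
                perturb(seqTemplates[t], sample(0:2, 1L)), character(1))
            grp$quals2 <- lapply(seq_len(n), function(i)
                sample(0:41, readLen, replace = TRUE))
        }
        inst <- c(inst, list(grp))
    }
    inst
}

## Write a 4-line-per-record FASTQ by hand (independent of writeFastq).
writeRawFastq <- function(path, ids, seqs, quals) {
    stopifnot(length(ids) == length(seqs), length(seqs) == length(quals))
    lines <- character(0)
    for (i in seq_along(ids))
        lines <- c(lines, paste0("@", ids[i]), seqs[i], "+", quals[i])
    writeLines(lines, path)
    invisible(path)
}
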