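test_that("hamming distance counts mismatching positions", {
    expect_identical(hammingDist("GAGCTTCAACTC", "GCGCTTCAACTC"), 1L)
    expect_identical(hammingDist("GCGCTTCAACTC", "GATCTTCAACTC"), 2L)
    expect_identical(hammingDist("ACGT", "ACGT"), 0L)
    expect_identical(hammingDist("AA", c("AA", "AT", "TT")), c(0L, 1L, 2L))
    expect_error(hammingDist("AA", "AAA"), "equal-length")
})

test_that("hamming distance satisfies the metric axioms", {
    set.seed(77)
    for (trial in seq_len(100L)) {
        len <- sample(1:15, 1L)
        s <- vapply(1:3, function(i)
            paste(sample(c("A", "C", "G", "T"), len, replace = TRUE),
                  collapse = ""), character(1))
        dxy <- hammingDist(s[1L], s[2L])
        dyx <- hammingDist(s[2L], s[1L])
        dxz <- hammingDist(s[1L], s[3L])
        dyz <- hammingDist(s[2L], s[3L])
        expect_identical(dxy, dyx)                      # symmetry
        expect_identical(hammingDist(s[1L], s[1L]), 0L) # identity
        expect_true(dxz <= dxy + dyz)                   # triangle
        expect_true(dxy >= 0L && dxy <= len)
    }
})

test_that("greedy merging follows seed-centric absorption without chaining", {
    ## AAAA (10 reads) absorbs AAAT (distance 1) but not AATT (distance 2),
    ## even though AATT is at distance 1 from AAAT
    inst <- list(
        list(umi = "AAAA", seqs = rep("ACGTACGT", 10L),
             quals = lapply(1:10, function(i) rep(30L, 8L))),
        list(umi = "AAAT", seqs = rep("ACGTACGT", 5L),
             quals = lapply(1:5, function(i) rep(30L, 8L))),
        list(umi = "AATT", seqs = rep("ACGTACGT", 3L),
             quals = lapply(1:3, function(i) rep(30L, 8L))))
    cfg <- UmiRunConfig(UMIlength = 4, sequenceLength = 8,
                        UMIdistance = 1, sequenceDistance = 3)
    cl <- mergeUmiGroups(groupSetFromInstance(inst), cfg)
    expect_identical(length(cl), 2L)
    expect_identical(representativeUmi(cl), c("AAAA", "AATT"))
    expect_identical(absorbedUmis(cl), list("AAAT", character(0)))
    expect_identical(pooledCount(cl), c(15L, 3L))
})

test_that("distant UMIs and distant sequences both block merging", {
    mkinst <- function(seqB) list(
        list(umi = "AAAA", seqs = rep("ACGTACGT", 4L),
             quals = lapply(1:4, function(i) rep(30L, 8L))),
        list(umi = "AAAT", seqs = rep(seqB, 2L),
             quals = lapply(1:2, function(i) rep(30L, 8L))))
    cfg <- UmiRunConfig(UMIlength = 4, sequenceLength = 8,
                        UMIdistance = 1, sequenceDistance = 1)
    ## sequence distance 4 > 1: no merge despite UMI distance 1
    cl <- mergeUmiGroups(groupSetFromInstance(mkinst("ACGTTGCA")), cfg)
    expect_identical(length(cl), 2L)
    ## sequence distance 1: merge
    cl2 <- mergeUmiGroups(groupSetFromInstance(mkinst("ACGTACGA")), cfg)
    expect_identical(length(cl2), 1L)
    expect_identical(pooledCount(cl2), 6L)

    ## with UMIdistance 0 every cluster is a singleton equal to its
    ## step-1 consensus
    cfg0 <- UmiRunConfig(UMIlength = 4, sequenceLength = 8,
                         UMIdistance = 0, sequenceDistance = 8)
    inst <- mkinst("ACGTACGA")
    cl0 <- mergeUmiGroups(groupSetFromInstance(inst), cfg0)
    expect_identical(length(cl0), 2L)
    expect_identical(unname(as.character(consensusR1(cl0))),
                     c("ACGTACGT", "ACGTACGA"))
})

test_that("clusters partition the groups and conserve read counts", {
    set.seed(99)
    for (trial in seq_len(30L)) {
        inst <- randomMergeInstance(sample(2:10, 1L))
        gs <- groupSetFromInstance(inst)
        cfg <- UmiRunConfig(UMIlength = 6, sequenceLength = 12,
                            UMIdistance = sample(0:2, 1L),
                            sequenceDistance = sample(0:4, 1L))
        cl <- mergeUmiGroups(gs, cfg)
        allUmis <- c(representativeUmi(cl),
                     unlist(absorbedUmis(cl)))
        expect_identical(sort(allUmis), sort(umiKeys(gs)))  # partition
        expect_identical(sum(pooledCount(cl)),
                         sum(groupCounts(gs)))              # conservation
    }
})

test_that("merging matches the transcription oracle on random instances", {
    set.seed(1234)
    for (trial in seq_len(60L)) {
        paired <- trial %% 3L == 0L
        inst <- randomMergeInstance(sample(2:10, 1L), paired = paired)
        cfg <- UmiRunConfig(pairedData = paired, UMIlength = 6,
                            sequenceLength = 12,
                            UMIdistance = sample(0:3, 1L),
                            sequenceDistance = sample(0:5, 1L))
        got <- mergeUmiGroups(groupSetFromInstance(inst), cfg)
        want <- oracleMerge(inst, cfg@UMIdistance, cfg@sequenceDistance)
        expect_identical(representativeUmi(got),
                         vapply(want, `[[`, character(1), "rep"))
        expect_identical(lapply(absorbedUmis(got), sort),
                         lapply(want, function(w) sort(w$absorbed)))
        expect_identical(pooledCount(got),
                         vapply(want, `[[`, integer(1), "pooled"))
        expect_identical(unname(as.character(consensusR1(got))),
                         vapply(want, function(w) w$cons$sequence,
                                character(1)))
        if (paired)
            expect_identical(unname(as.character(consensusR2(got))),
                             vapply(want, function(w) w$cons2$sequence,
                                    character(1)))
    }
})

test_that("merging is invariant to input read order", {
    set.seed(55)
    inst <- randomMergeInstance(8L)
    gs <- groupSetFromInstance(inst)
    cfg <- UmiRunConfig(UMIlength = 6, sequenceLength = 12,
                        UMIdistance = 2, sequenceDistance = 4)
    cl1 <- mergeUmiGroups(gs, cfg)
    rs <- gs@readSet
    perm <- sample(length(rs@r1))
    rs2 <- methods::new("UmiReadSet", umi = rs@umi[perm],
                        r1 = rs@r1[perm], r2 = NULL)
    cl2 <- mergeUmiGroups(groupByUmi(rs2), cfg)
    expect_identical(representativeUmi(cl1), representativeUmi(cl2))
    expect_identical(pooledCount(cl1), pooledCount(cl2))
    expect_identical(as.character(consensusR1(cl1)),
                     as.character(consensusR1(cl2)))
})
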