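test_that("run configuration validates its parameter combinations", {
    expect_error(UmiRunConfig(pairedData = FALSE, UMIlocation = "R1andR2",
                              UMIlength = 10, sequenceLength = 50),
                 "pairedData")
    expect_error(UmiRunConfig(UMIlength = 0, sequenceLength = 50),
                 "UMIlength")
    expect_error(UmiRunConfig(UMIlength = 10, sequenceLength = 50,
                              UMIlocation = "R2"), "UMIlocation")
    cfg <- UmiRunConfig(UMIlength = 12, sequenceLength = 50)
    expect_s4_class(cfg, "UmiRunConfig")
})

test_that("UMI extraction splits prefix from insert per library case", {
    ## single-end, k = 2: "ACGT" -> key "AC", insert "GT" with its scores
    cfg <- UmiRunConfig(UMIlength = 2, sequenceLength = 2)
    r1 <- qsds("ACGT", list(c(10L, 20L, 30L, 40L)))
    ex <- extractUmi(r1, config = cfg)
    expect_identical(umiKeys(ex), "AC")
    expect_identical(unname(as.character(ex@r1)), "GT")
    expect_identical(qualsOf(ex@r1)[[1L]], c(30L, 40L))

    ## the worked 12-nt UMI prefix
    cfg12 <- UmiRunConfig(UMIlength = 12, sequenceLength = 4)
    r1 <- qsds("GAGCTTCAACTCACGT", list(rep(30L, 16L)))
    expect_identical(umiKeys(extractUmi(r1, config = cfg12)),
                     "GAGCTTCAACTC")

    ## dual-UMI paired, k = 2: keys concatenate, both mates trimmed
    cfgd <- UmiRunConfig(pairedData = TRUE, UMIlocation = "R1andR2",
                         UMIlength = 2, sequenceLength = 3)
    r1 <- qsds("ACGGG", list(rep(30L, 5L)))
    r2 <- qsds("TTCCC", list(rep(30L, 5L)))
    exd <- extractUmi(r1, r2, cfgd)
    expect_identical(umiKeys(exd), "ACTT")
    expect_identical(unname(as.character(exd@r1)), "GGG")
    expect_identical(unname(as.character(exd@r2)), "CCC")

    ## paired with UMI on R1 only: R2 untouched
    cfgp <- UmiRunConfig(pairedData = TRUE, UMIlocation = "R1",
                         UMIlength = 2, sequenceLength = 3)
    exp2 <- extractUmi(qsds("ACGGG", list(rep(30L, 5L))),
                       qsds("TTCCC", list(rep(30L, 5L))), cfgp)
    expect_identical(unname(as.character(exp2@r2)), "TTCCC")
})

test_that("extraction rejects reads inconsistent with the configuration", {
    cfg <- UmiRunConfig(UMIlength = 4, sequenceLength = 10)
    expect_error(extractUmi(qsds("ACG", list(c(1L, 2L, 3L))), config = cfg),
                 "shorter than UMIlength")
    expect_error(extractUmi(qsds("ACGTACGT", list(rep(30L, 8L))),
                            config = cfg), "sequenceLength")
    cfgp <- UmiRunConfig(pairedData = TRUE, UMIlength = 2,
                         sequenceLength = 2)
    expect_error(extractUmi(qsds("ACGT", list(rep(30L, 4L))), config = cfgp),
                 "no R2")
})

test_that("exact grouping tallies counts and orders deterministically", {
    cfg <- UmiRunConfig(UMIlength = 2, sequenceLength = 2)
    reads <- qsds(c("AAGG", "AACC", "ATCC"),
                  list(rep(30L, 4L), rep(30L, 4L), rep(30L, 4L)))
    g <- groupByUmi(extractUmi(reads, config = cfg))
    expect_identical(umiKeys(g), c("AA", "AT"))
    expect_identical(unname(groupCounts(g)), c(2L, 1L))

    ## conservation on a larger random set, invariant to read order
    set.seed(42)
    n <- 30L
    keys <- sample(c("AA", "AC", "GG", "TT"), n, replace = TRUE)
    seqs <- paste0(keys, "CG")
    reads <- qsds(seqs, lapply(seq_len(n), function(i) rep(30L, 4L)))
    g1 <- groupByUmi(extractUmi(reads, config = cfg))
    expect_identical(sum(groupCounts(g1)), n)
    perm <- sample(n)
    g2 <- groupByUmi(extractUmi(reads[perm], config = cfg))
    expect_identical(umiKeys(g1), umiKeys(g2))
    expect_identical(groupCounts(g1), groupCounts(g2))

    ## empty input
    g0 <- groupByUmi(extractUmi(qsds(character(0), character(0)),
                                config = cfg))
    expect_identical(length(g0), 0L)
})

test_that("cleaning keeps exactly the groups at or above the cutoff", {
    cfg <- UmiRunConfig(UMIlength = 2, sequenceLength = 1)
    counts <- c(U1 = 7L, U2 = 6L, U3 = 5L)
    umis <- c("AA", "CC", "GG")
    reads <- qsds(rep(paste0(umis, "T"), times = counts),
                  lapply(seq_len(sum(counts)), function(i) rep(30L, 3L)))
    g <- groupByUmi(extractUmi(reads, config = cfg))
    expect_identical(unname(groupCounts(cleanGroups(g, 6))), c(7L, 6L))
    expect_identical(length(cleanGroups(g, 1)), 3L)
    expect_identical(length(cleanGroups(g, 0)), 3L)
    expect_identical(length(cleanGroups(g, 100)), 0L)

    ## monotonicity: higher cutoff never keeps more groups or reads
    kept <- vapply(0:8, function(ct) length(cleanGroups(g, ct)), integer(1))
    reads_kept <- vapply(0:8, function(ct)
        sum(groupCounts(cleanGroups(g, ct))), integer(1))
    expect_true(all(diff(kept) <= 0))
    expect_true(all(diff(reads_kept) <= 0))
})
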