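# umidedup

Alignment-free deduplication and error correction of UMI-tagged FASTQ
reads.

## The problem

Library preparation for high-throughput sequencing amplifies every input
molecule by PCR, so the read set contains duplicates and amplification or
sequencing artifacts. When a unique molecular identifier (UMI) — a short
random oligonucleotide, typically 8–16 nt — is ligated to each molecule
before amplification, all duplicates of one molecule share one barcode,
and the duplicates can be collapsed back into a single corrected
representative without aligning anything to a reference. That makes the
approach usable on data that standard mappers handle poorly, such as B-
and T-cell receptor repertoires, and lets the corrected FASTQ flow into
any downstream pipeline.

`umidedup` is for anyone with UMI-tagged FASTQ files (single-end with a
5' UMI on R1, paired-end with a UMI on R1, or paired-end with UMIs on
both mates) who wants one consensus read per original molecule plus a
traceable summary table.

## The method

Three steps, all on raw sequence:

1. **Per-UMI consensus.** Reads are grouped by their exact UMI prefix,
   groups below a minimum read count (`countsCutoff`) are dropped, and
   each group is collapsed column by column. At every position each
   observed base *b* is scored by

   criterion(*b*) = ( freq%(*b*) + meanQ(*b*) ) / 2

   where freq%(*b*) is the percentage of the group's reads showing *b*
   at that position (0–100) and meanQ(*b*) the arithmetic mean of their
   Phred scores (0–41). The base with the maximal criterion is called; a
   criterion tie goes to the base with the higher mean quality, any
   remaining tie to the alphabetically smallest base. The consensus
   quality is the winner's mean quality, rounded.

2. **UMI merging.** Because sequencing errors hit the UMI too, one
   molecule can appear under several near-identical UMIs. Groups are
   merged greedily: the unassigned group with the most reads seeds a
   cluster and absorbs every group within `UMIdistance` (Hamming) of its
   UMI whose step-1 consensus sequence is within `sequenceDistance` of
   the seed's (for paired data, R1 and R2 each). Absorbed groups leave
   the pool; the loop repeats until it is empty.

3. **Final consensus.** Each cluster's consensus is recomputed from all
   pooled raw reads, so absorbed UMIs contribute with their full read
   weight. One read per cluster is written, UMI removed, with the
   identifier `umi=<representative UMI>;reads=<pooled count>`.

## Worked example

Simulate a small library with known ground truth, then run the pipeline:

```r
library(umidedup)

sim <- simulateUmiLibrary(nMolecules = 6, umiLength = 8, insertLength = 20,
                          duplicates = c(5, 9), umiErrorRate = 0.01,
                          insertErrorRate = 0.01, seed = 42,
                          outputDir = "raw")

cfg <- UmiRunConfig(UMIlength = 8, sequenceLength = 20, countsCutoff = 3,
                    UMIdistance = 1, sequenceDistance = 3,
                    inputDir = "raw", outputDir = "corrected")
res <- runUmiPipeline(cfg)
#> [INFO] processing sim_R1.fastq
#> [INFO] 38 reads, 8 UMIs; cleaning dropped 2 UMI groups below cutoff 3
#> [INFO] 6 UMIs merged into 6 clusters
#> [INFO] stats: input_reads=38, reads_after_cleaning=36, umis_start=8,
#>        umis_after_cleaning=6, umis_after_merging=6
```

The 38 raw reads carried 8 distinct UMIs: the 6 true ones plus 2
singleton UMIs created by sequencing errors in the barcode, which the
cleaning cutoff removes. The result is one consensus read per molecule:

```r
res$summary[, c("representative_umi", "n_umis_merged", "pooled_count",
                "consensus_r1", "mean_quality_r1")]
#>   representative_umi n_umis_merged pooled_count         consensus_r1 mean_quality_r1
#> 1           AACTCCGG             1            9 CTAAAGTACAATTAGGATAT              37
#> 2           TCCATATC             1            8 AAAGGTACCGCTGGCATATC              37
#> 3           CCATGTGT             1            5 TCGTGAACCCCCTGCACGCC              37
#> 4           TCGGCCTT             1            5 CTTAGCAACAAGTCGCCTAG              37
#> 5           TCTTGCAC             1            5 CCGAACGTTCTAATAAACGA              37
#> 6           AAGTAGAA             1            4 TCATCCCTACACTGTATATG              37
```

Every consensus insert is identical to the simulated truth despite the
1% per-base error rate:

```r
all(res$summary$consensus_r1 == sim$truth$true_insert[
    match(res$summary$representative_umi, sim$truth$true_umi)])
#> [1] TRUE
```

`corrected/` now holds `sim_R1_corrected.fastq` (6 records, UMI-free)
and `summary_table.csv`, whose columns (absorbed UMIs, pooled counts)
let you trace each output read back to its input groups.

The same run from a shell, via the installed script:

```sh
Rscript $(Rscript -e 'cat(find.package("umidedup"))')/exec/umidedup \
    --UMIlength 8 --sequenceLength 20 --countsCutoff 3 \
    --UMIdistance 1 --sequenceDistance 3 \
    --input-dir raw --output-dir corrected
```

## Scope

Reads of one shared length per run, substitutions only (the columnar
consensus cannot absorb indels), Phred+33 qualities, UMIs at the 5'
start. Pattern- or primer-based UMI extraction, network/directional UMI
clustering, and BAM input/output are out of scope.
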