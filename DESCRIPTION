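Package: umidedup
Title: Alignment-Free UMI Deduplication and Consensus Read Correction
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Deduplicates and error-corrects UMI-tagged FASTQ reads without
    alignment. Reads sharing a unique molecular identifier (UMI) are
    collapsed into a single consensus read by a per-base criterion that
    averages base frequency and mean Phred quality; near-identical UMI
    groups are then merged greedily under Hamming-distance bounds on both
    the UMIs and the consensus sequences, and the merged clusters are
    re-corrected from their pooled raw reads. Supports single-end reads
    with a 5' UMI on R1 and paired-end reads with UMIs on R1 or on both
    mates. Emits corrected FASTQ (UMI removed) plus a summary table, and
    includes a synthetic-library simulator with ground truth for
    validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    tools,
    Biostrings,
    IRanges,
    S4Vectors
Suggests:
    testthat (>= 3.0.0),
    optparse,
    yaml
Config/testthat/edition: 3
RoxygenNote: 7.3.3
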