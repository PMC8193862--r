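---
title: "Consensus-based UMI deduplication: model, parameters and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Consensus-based UMI deduplication: model, parameters and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(umidedup)
```

# The model

A UMI-tagged library is a mixture: each original molecule was tagged
with a random barcode and amplified, so the observed reads are noisy
copies of a much smaller set of true (UMI, insert) pairs. The package
inverts that process with three assumptions:

* **Shared read length.** Every read in a run has the same total
  length, so positions align column-wise without alignment. This is why
  only substitution errors are handled — an indel would shift all
  downstream columns, and the per-position model would average
  unrelated bases. Indel-containing data should be length-filtered
  first.
* **5' UMIs of known, fixed length.** The first `UMIlength` bases of R1
  (and of R2 in the dual-UMI layout) are the barcode; everything after
  is insert. In the dual-UMI case the two barcodes are concatenated
  into a single key of twice the length, treating the pair as one
  molecular identifier; exact grouping and all Hamming distances then
  operate on the concatenation. Matching the two ends independently
  would be an alternative; concatenation was chosen because both ends
  must agree for two reads to come from one fragment anyway.
* **Errors are rare and per-base independent**, in the barcode as in
  the insert, which is what makes a frequency-plus-quality vote a good
  estimator of the true base.

## The consensus criterion

At each column of a UMI group, every observed base $b$ is scored by

$$\mathrm{criterion}(b) \;=\; \frac{\mathrm{freq}_\%(b) + \bar{Q}(b)}{2}$$

with $\mathrm{freq}_\%(b) = 100\,\cdot\,n_b / n$ and $\bar{Q}(b)$ the
arithmetic mean Phred score of the reads showing $b$ there. The scales
deserve a note: frequency as a percentage (0–100) and quality on the
raw Phred scale (0–41) give the two terms comparable magnitude, so
neither silently dominates. A variant normalising both to $[0,1]$ would
reweight quality upward; the chosen scaling keeps frequency slightly
dominant, which is the behaviour you want when a few high-quality reads
disagree with a clear majority. The scaling is isolated in
`consensusBase()`, so the alternative is a one-line change.

Qualities are averaged on the Phred (log) scale, not on the
error-probability scale. Averaging probabilities would let one very low
score dominate the mean; the log-scale mean is the more conservative
summary and matches how "mean quality" is conventionally reported.

Ties resolve in two stages: equal criteria go to the base with the
higher mean quality; a full tie (possible, e.g. two bases seen in equal
numbers at equal quality) falls through to the alphabetically smallest
base, A < C < G < N < T. `N` participates as a fifth symbol and can win
a column only by the same criterion — it is not treated as missing
data. The consensus quality is the winner's mean quality rounded half
up and clipped to $[0, 41]$, because FASTQ needs integer scores.

The UMI itself is corrected implicitly: within a group the UMI is
constant by construction, and after merging the representative UMI of a
cluster — the seed's, i.e. the highest-count group's — stands for all
absorbed variants.

## Cleaning and merging

Cleaning drops UMI groups with fewer than `countsCutoff` reads; the
cutoff is inclusive (a group with exactly `countsCutoff` reads
survives). Its purpose is statistical: a consensus over one or two
reads cannot outvote an error, and most sub-cutoff groups are
barcode-error satellites of real groups.

Merging is greedy and seed-centric. While unassigned groups remain, the
one with the most reads (ties: lexicographically smallest UMI, for
reproducibility) seeds a cluster and absorbs every unassigned group
that passes **both** distance tests against the seed: Hamming distance
between UMIs at most `UMIdistance`, and Hamming distance between step-1
consensus sequences at most `sequenceDistance` (for paired data R1 and
R2 must each pass the same bound — requiring both is stricter than
summing and matches treating the two mates as independent evidence).
Three consequences worth knowing:

* **No chaining.** A group close to an absorbed member but far from the
  seed stays unmerged; clusters are stars around their seeds, not
  connected components. This deliberately differs from network-style
  UMI clustering.
* **Distances are computed on step-1 consensuses**, one per group, not
  between raw reads — both cheaper and more robust, since per-group
  consensus has already removed most sequencing noise.
* **The final consensus pools raw reads.** Recomputing from all member
  reads of the cluster weights each absorbed UMI by its read count. The
  alternative — averaging the per-group consensuses — would give a
  12-read satellite the same vote as a 1,001-read seed.

With `UMIdistance = 0` merging degenerates to exact deduplication:
every cluster is a singleton and the final consensus equals the step-1
consensus (covered by a test).

# Parameters

| Parameter | Units | Default | Why |
|---|---|---|---|
| `UMIlength` | nt | — (required) | Protocol property; 8–16 nt typical. |
| `sequenceLength` | nt | — (required) | Insert length = read length − `UMIlength`; outputs have exactly this length. Used as a hard validation, not a trim. |
| `countsCutoff` | reads | 1 | Protocol-dependent; deep amplicon data supports 6+, shallow data may need 1–3. |
| `UMIdistance` | nt | 1 | One barcode substitution is by far the dominant error mode at per-base rates ≪ 1. |
| `sequenceDistance` | nt | 3 | Generous enough for a few insert errors in a consensus, tight enough to keep distinct molecules apart for inserts ≥ ~20 nt. |
| `pairedData`, `UMIlocation` | — | single-end, R1 | Library layout selectors. |

`sequenceLength` interpretation: the pipeline validates that every
UMI-carrying read splits into `UMIlength + sequenceLength` bases and
that, in the paired-with-UMI-on-R1-only layout, the untouched R2 has
the same total length. A length mismatch is an error by design — silent
trimming would misalign the consensus columns.

# The simulator

`simulateUmiLibrary()` generates the data structure the method assumes:
`nMolecules` random inserts tagged with UMIs drawn by rejection
sampling to keep all true barcodes at pairwise Hamming distance ≥
`minUmiDist` (default 3, i.e. more than twice the default
`UMIdistance`), each emitted `duplicates` times with independent
per-base substitutions at `umiErrorRate` / `insertErrorRate`. Correct
bases get `qualityHigh` (default 37, a clean Illumina call),
substituted bases `qualityLow` (default 14), a two-level contrast that
makes the frequency-versus-quality criterion actually exercisable in
tests. Reads are shuffled so input order carries no signal, and the
whole library is reproducible from `seed`.

The separation enforced between true UMIs is what turns "number of
clusters equals number of molecules" from a likelihood into a theorem:
error-free barcode variants of different molecules can never fall
within `UMIdistance` of each other. Real libraries draw barcodes
uniformly and *can* collide or sit at distance 1; the simulator's
defaults (200 molecules over 12-nt UMIs, 8–30 duplicates, error rates
0.002/0.005) represent a well-behaved deep amplicon experiment.

What the simulator does **not** model — and what passing tests
therefore do not demonstrate about real data: PCR jackpot effects and
per-cycle error propagation (errors in early cycles appear in many
duplicates and can out-vote the truth), position-dependent quality
decay, adapter contamination, indels, and barcode collisions between
molecules. The acceptance checks show the machinery is exact under its
own assumptions, not that those assumptions hold for any given
protocol.

# Numerical and degenerate-input choices

* Phred+33 is the only supported encoding (the de-facto standard for
  current instruments); scores outside $[0, 41]$ are rejected rather
  than clipped on input.
* Rounding of consensus qualities is half-up (`floor(q + 0.5)`), so
  11.5 → 12 deterministically, avoiding banker's-rounding surprises in
  byte-compare tests.
* Group ordering (descending count, lexicographic UMI tie-break) and
  seed selection use radix order on the C locale, making every stage —
  and hence the output files — byte-identical across runs and
  platforms.
* Empty inputs degrade gracefully: an empty group set merges to an
  empty cluster set, the summary is written header-only, and an empty
  FASTQ output file is legal. An empty read *group*, by contrast, is a
  hard error: a consensus over nothing is meaningless.
* A single-read group is its own consensus (unanimity), with its own
  qualities.
* gzip is detected by the `.gz` suffix only; content sniffing was
  rejected as non-deterministic across oddly named files.
* Files are read whole into memory. The intended scale (up to a few
  million desk-scale reads) fits comfortably, and whole-file
  `Biostrings` containers make the column-wise consensus a matrix
  operation instead of a streaming accumulator.

# Problem sizes in the test suite

The oracle-equivalence tests compare the implementation against
brute-force re-implementations on 1,000 random groups (≤ 10 reads × ≤
20 nt) for the consensus and 500 random instances (≤ 10 groups) for the
merge; the parameter-recovery check runs the full pipeline on 200
molecules × 8–30 duplicates × 50 nt inserts across 5 seeds. These sizes
give the randomized properties broad coverage while keeping a full
`testthat` run at a few minutes on one CPU.

# Known limitations

* Substitution-only, fixed-length model; no indels, no variable-length
  reads, no 3' or pattern-embedded UMIs.
* Greedy merging is order-dependent in principle (largest group first);
  a maximum-weight clustering could split ambiguous neighbourhoods
  differently. The greedy rule is the method's definition, not an
  approximation to one.
* Memory scales with input size (whole-file containers).
* The criterion's equal weighting of frequency and quality is a
  modelling choice, not a likelihood; heavily quality-skewed data might
  warrant the normalised variant discussed above.
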