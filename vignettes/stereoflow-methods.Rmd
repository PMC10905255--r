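---
title: "stereoflow: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{stereoflow: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

This vignette explains the computations the package performs, the
parameters that matter, what the synthetic generator does and does not
emulate, and the design choices made where more than one reading was
defensible. It states no empirical result that the test suite or the
acceptance script does not itself compute.

# Spatial restoration

## Model

Each chip spot carries a distinct 25-base coordinate barcode (CID); the
mask is the injective CID → (x, y) table. Sequencers substitute bases at
a small per-base rate, so exact lookup alone loses a material fraction of
reads: with per-base error rate $e$, the probability a 25-mer is read
error-free is $(1-e)^{25}$ and the probability of exactly one error is
$25e(1-e)^{24}$. Single-substitution tolerance therefore recovers most of
what exact matching loses, and the expected mapped fraction is

$$P(\text{mapped}) \approx (1-e)^{25} + 25\,e\,(1-e)^{24},$$

the closed form the recovery tests check at 3σ binomial tolerance.

Matching rules, in order: an exact hit short-circuits (an exact match is
strictly more probable than any distance-1 alternative); otherwise all
single-substitution variants are looked up — exactly one hit is a
*corrected* match, two or more hits map to distinct coordinates (the mask
is injective) and the read is discarded as *ambiguous*, zero hits is
*unmatched*. Distance is capped at one substitution; no indel tolerance,
no quality weighting. A CID containing `N` can never match exactly;
substituting the `N` with A/C/G/T counts as the one allowed substitution,
so a single-`N` CID is still rescuable and a two-`N` CID never is.

## Partitioning

Masks and read sets can be split by CID to bound memory: by the first
$k$ bases (prefix rule, $4^k$ parts) or by the 2-bit big-endian encoding
of the full CID modulo $n$ (any $n$). The base encoding is pinned as
A=0, C=1, G=2, T=3; any fixed bijection works, but one must be pinned for
the modulo rule to be reproducible. The full 25-base encoding
($< 2^{50}$) is exact in double precision. Whether the modulo rule should
hash the full CID or a substring was open; we pin full-CID encoding and
document it here.

A read whose single CID error falls inside the partitioning prefix would
be routed away from the partition holding its true mask entry. The
implementation therefore routes at the *variant* level: each
single-substitution variant is looked up in the partition its own
encoding selects. A variant can only equal a mask CID of its own
partition, so partitioned results — coordinates, match kinds, ambiguity
calls — are identical to unpartitioned matching read for read. This holds
for both rules (for the prefix rule it reduces to querying the home
partition plus the ≤ 3·prefix-length prefix-variant partitions). The
acceptance suite checks byte-identical end-to-end outputs for 1, 4 and
16 partitions.

CIDs containing non-ACGT symbols cannot be encoded; they are routed to
partition 0 (they can never match any mask entry, so placement is
immaterial) and counted.

# Read QC

The pre-alignment checks run in a fixed order with the first failure
reported: (1) MID contains `N`; (2) MID is poly-A; (3) any MID base below
`minMidQuality` (Phred, default 10); (4) a trailing cDNA A-run of at
least `polyaRunMin` bases (default 10) is trimmed, and the read fails if
fewer than `minCdnaLengthAfterTrim` bases (default 25) remain.

Two dialect choices, both deliberate: the MID quality rule is a per-base
minimum rather than a mean (a single bad base is what corrupts a barcode,
and the per-base rule is monotone in the threshold); and "cDNA contains
poly-A" is implemented as trim-then-length-check rather than outright
discard — poly-A tails are expected mRNA biology, and discarding every
tailed read would throw away most of a real library. The exact cutoffs
used by production pipelines are not published; ours are permissive,
logged, and overridable.

# Annotation

CIGARs are parsed into reference align blocks: M/=/X extend the current
block, N (splice gap) and D close it (both advance the reference), I and
S consume read only, H neither. Read length is the sum of M/=/X/I/S
lengths.

For each overlapping gene, per transcript, the exon count is the total
block overlap with that transcript's exons and the intron count the
overlap with the gene span minus those exons (introns of the *same*
transcript, plus span flanks outside it); the transcript maximizing
(exoncnt, then introncnt) represents the gene. Per-block mixing of
transcripts was rejected as biologically incoherent — a read derives from
one isoform. The label follows the 50 % rule: EXONIC when
exoncnt ≥ read-length/2, else INTRONIC when introncnt ≥ read-length/2,
else INTERGENIC. Gene choice: best label first
(EXONIC > INTRONIC > INTERGENIC), then largest overlap with the gene
span, then smallest (start, end, gene_id) — fully deterministic; a
"random" tie-break would make runs irreproducible, and the positional
rule is a complete ordering already.

Strand affects only the antisense flag (alignment strand ≠ chosen gene
strand), never the region label. Antisense reads are tallied alongside
the region counters — the annotation tally's transcriptome row is
exonic + intronic regardless of sense — and are excluded later, at
expression-matrix construction. "Uniquely mapped" is operationalized as
not secondary/supplementary and MAPQ ≥ `minMapq` (default 20, which also
admits the 255 convention some aligners use for unique hits).

# MID correction

Within each (coordinate, gene) group: if fewer than `minMidTypes`
(default 5) distinct MIDs are present the group is returned unchanged.
Otherwise MIDs are sorted by descending count — ties by *descending*
lexicographic MID, which pins a deterministic order — and traversed from
the smallest count upward; each MID is compared against the
higher-ranked MIDs in rank order and merged into the first one within
`tolerance` (default 1) Hamming distance, transferring its current
count. Ranks are fixed by the original sort, so a merged-away MID
(count 0) remains a valid target at its original rank; transfers move
current counts, so group totals are conserved exactly.

One subtlety: the recorded old → new mapping is single-step, and chains
can arise (a merge target can itself merge into a higher-ranked MID
later in the traversal). Because merges proceed from the smallest rank
upward, a MID's count always ends at the root of its chain, so replaying
the mapping to a fixed point over the raw per-read MID list reproduces
the corrected counts exactly — the matrix builder applies mappings this
way, and the suite asserts the replay identity on randomized groups.

The gate interacts with error recovery in a way worth spelling out: a
group whose true molecule count is below `minMidTypes` is never
processed, so an MID error there survives. The recovery experiment in
the acceptance suite therefore constructs groups with a designed
molecule count k = 5 (the smallest count the default gate processes
unconditionally), 5× duplication and 0.5 % per-base MID error, and
requires the corrected unique-MID count to equal k in ≥ 95 % of 1000
groups. The residual failures are intrinsic to distance-1 correction:
reads with two MID errors land outside the tolerance.

# Expression matrix

Only EXONIC/INTRONIC, sense-strand reads contribute. The value at
(x, y, gene) is the number of distinct corrected MIDs. Binning uses
0-based floor division (bin coordinate = ⌊x / binSize⌋), emitting bin
indices with the bin size recorded in the output metadata; count totals
are invariant under binning. The serialized format is a plain gem TSV
(`geneID  x  y  MIDCount` with metadata header lines) — lossless,
diffable, and round-trip tested up to 10⁵ records.

# Tissue segmentation

The grayscale branch works on the expression heatmap (pixel = total MID
count per bin): log1p intensity transform (counts are heavy-tailed; Otsu
on raw counts is dominated by a few bright pixels), Gaussian smoothing
(`sigma`, default 2 bins), min-max rescale, Otsu threshold (or a fixed
one), morphological closing then opening (disc radii 3 and 2 bins),
removal of connected components below `minAreaFrac` (default 0.001 of
the image — the noise filter the method calls for without specifying;
isolated off-tissue bins are single pixels, real tissue sections are
orders of magnitude larger), hole filling, and contour tracing. All
parameters sit in `tissuecutParams()`. Degenerate inputs are defined,
not errors: an all-zero heatmap yields an empty mask; a constant
positive one yields a full-frame mask. Deep-learning segmentation of
microscope images is out of scope (no trained weights, no image
registration).

# Saturation

From (x, y, gene, MID) read tuples under tissue: a preparatory spatial
subsample keeps a fraction (default 5 %) of occupied bin200 bins
(ceiling, so non-empty input never empties); the per-read list is then
shuffled **once** with the stage seed and prefixes of ⌊f·N⌋ reads are
taken at f ∈ {0.05, 0.1, …, 1.0} — prefix sampling keeps the rows
nested, so total reads increase and distinct-tuple counts are
non-decreasing monotonically across rows. Saturation is
1 − unique/total; the median gene count is the median over occupied bins
(empty bins excluded) of distinct genes per bin, at bin1 and bin200.

Under the plain reading of the definitions, bin1 and bin200 saturation
use the same (bin1 x, y, gene, MID) dedup key and coincide; both columns
are reported and the equality is deliberate. A stricter
bin200-resolution key (bin index, gene, MID) is available behind
`bin200Keys = TRUE` for users who want coarse-lattice deduplication; it
can only raise the coarse column.

# Synthetic data

The generator stands in for the chip fab, the sequencer and the aligner.
It emulates: a rectangular lattice with one distinct uniform 25-base CID
per spot (small test chips are resampled to pairwise Hamming
distance ≥ 3 so single-error correction is unambiguous); molecules
placed on a disk/rectangle of "tissue" plus uniform background
(`backgroundRate` molecules per off-tissue spot); shifted-Poisson PCR
duplication (1 + Poisson(mean − 1)); independent per-base substitution
errors on CID, MID and cDNA; and splice-aware alignment records placed
at each molecule's true exonic coordinates over a toy genome/GTF.
Everything is deterministic under the seed, and a truth table links
every read to its molecule and injected error positions.

Default study conditions: a 20 × 20-spot chip, 5 genes, 2000 molecules,
disk tissue of radius one third of the chip width, background 0.05,
CID/cDNA error 1 % per base, MID error 0.5 %, duplication mean 3 — a
deliberately small but structurally complete replica of a run; the
partition-invariance checks use it at seed 42, and the segmentation
check uses a 120 × 120 chip with a radius-40 disk and 20000 molecules so
the heatmap has enough support for morphology at bin 2. Problem sizes
throughout the suite (≤ 10⁴-entry masks, ≤ 10³ queries per mask,
500-read annotation oracles, 10³ correction groups) were chosen so each
property is exercised well past its edge cases while the whole suite
runs in minutes on one core.

What it does **not** emulate — and what passing tests therefore do not
show about real data: platform-specific error profiles (errors here are
i.i.d. substitutions; no indels, no quality-correlated errors, and CID
indel reads that a real run would lose are absent), transcript-level
expression structure (genes are uniform, one isoform each), alignment
error (records are placed at truth, so unique-mapping rates and
multi-mapper behaviour are untested), doublet/diffusion artefacts, and
tissue morphologies more complex than a convex blob. The pipeline's
accuracy claims on real libraries rest on the correctness of each
stage's contract, not on these simulations.

# Numerical and degenerate-input choices

- Coordinates are 0-based, x = column, y = row; intervals half-open.
- The exact/corrected/ambiguous classification is testable against an
  exhaustive Hamming scan for every mask the suite uses; the index
  answers queries identically to that scan by construction (variant
  lookup), not approximately.
- Empty inputs are values, not errors, wherever a downstream stage can
  proceed: empty masks reject all queries, empty read streams produce
  zero counters, empty matrices rasterize to zero images, zero-read
  funnels report 0 % without division errors. Saturation on an empty
  tuple list *is* an error (no meaningful curve exists).
- `floor(f · N)` prefixes can be empty for tiny N at small f; rows then
  report zero totals with NA statistics rather than fabricating values.
- The gem TSV and mask TSV are versioned by their header lines and
  rejected on mismatch. A hierarchical-container serialization of the
  same records was considered and dropped: the information content is
  identical and the TSV keeps fixtures diffable.

# Limitations

- No multi-mapper rescue, UTR sub-labels, or GFF attribute dialects
  beyond `gene_id`/`transcript_id`.
- MID correction is count-greedy with Hamming tolerance; directional
  network methods and quality-weighted merging are out of scope.
- The CLI is a thin convenience wrapper; the R API is the interface.
- Chips are rectangular lattices; vendor binary mask formats are not
  parsed (the TSV mask format here is this package's own).
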