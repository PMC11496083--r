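---
title: "Quantifying CD45/PTPRC splice isoform features in single cells: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying CD45/PTPRC splice isoform features in single cells: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cd45iso)
```

## The problem

CD45, the product of *PTPRC*, is alternatively spliced at exons 4, 5 and 6
(protein segments A, B, C). Lymphocyte subsets differ in which of these
exons they retain: human naive T cells express CD45RA, memory and effector
cells CD45RO (all three exons skipped), and the pattern is routinely used
as a surface phenotype. Droplet scRNA-seq quantifies *PTPRC* as a single
gene and discards the splicing signal, although in 5' libraries the reads
covering the alternative exons are present in the BAM. This package
recovers four per-cell *features* from those reads:

* **RA / RB / RC** — evidence that exon 4 / 5 / 6 is present: any read
  overlapping the exon.
* **RO** — evidence that all three are absent: a read spanning the
  exon 3 → exon 7 junction, which only exists in the fully skipped
  transcript.

These are feature-level calls, not full-isoform reconstructions: a read
overlapping exon 4 supports RA whether the molecule was RABC or RA-only.

## The discriminating reference

The central device is a reference in which *mapping location implies
feature overlap*. For a feature (an exon, or a junction between two exons)
we enumerate every chain of exons that transcript-building rules allow to
precede or follow it. The rules are an adjacency list over exon
identifiers — for CD45: exon 3 may be followed by exon 4, 5, 6 or 7, exon 4
by 5, 6 or 7, and so on, with the constitutive backbone chained linearly.
For each (upstream chain, downstream chain) pair one reference sequence is
assembled:

* upstream flank — the **last** `R − k` bases of the concatenated upstream
  chain;
* the feature exon in full (for junctions the two flanks abut directly);
* downstream flank — the **first** `R − k` bases of the concatenated
  downstream chain;

where `R` is the read length in bases and `k` the guaranteed overlap.
Because each flank is shorter than a read by `k` bases, *every* window of
length `R` fully inside the sequence overlaps the feature by at least `k`
bases (for junctions: at least `k` bases on each side of the splice
point). This containment guarantee is the property the whole method rests
on; the test suite and the acceptance script verify it by exhaustive
window enumeration over randomized gene models rather than by argument.

Chain enumeration stops once the accumulated sequence reaches the flank
length, or at the gene end — chains ending early simply yield shorter
flanks, which only strengthens the guarantee. Distinct chains whose
truncated flanks coincide are deduplicated (an aligner cannot distinguish
them), as are identical full reference sequences; flank truncation keeps
the exon-proximal side so junction-spanning context nearest the feature is
preserved.

## Classification: production route and oracle

Reads are assigned by **k-mer containment**: for each reference, the
fraction of the read's k-mers (k = 21 by default) present in that
reference is computed on both strands, and references reaching
`min_kmer_frac` on their better strand are hits. Hits collapse to the
feature level before any weighting, so the multiplicity of flank
combinations — an artifact of reference construction — never dilutes a
read's contribution.

An independent **genomic oracle** classifies the same reads from alignment
geometry alone: aligned blocks (CIGAR `M`/`=`/`X` runs) must overlap a
feature exon by ≥ `k` bases, or an `N` gap must bridge exactly the
junction's intron with ≥ `k` aligned bases on both sides. The two routes
share no code or data structures, which is what makes their agreement
informative.

**When do the routes agree exactly?** Full containment of an error-free
read in a flanked reference is equivalent to a ≥ `k`-base feature overlap
— *provided the overlap is long enough to be visible to k-mers*. With the
weakest guarantee `k = 1`, a read ending one base into exon 4 is
sequence-identical to a read ending one base into exon 5 whenever the two
exons start with the same base (probability 1/4 per boundary); the k-mer
route then correctly reports both features while the oracle, which knows
the alignment, reports one. This is genuine sequence-level ambiguity, not
a defect of either route. Exact dual-route agreement therefore holds when
the guaranteed overlap equals the k-mer size, and the validation runs use
`min_overlap = 21` with `min_kmer_frac = 1`. For real (noisy) data the
defaults relax to `min_overlap = 1` — the weakest reading of "a fully
mapped read touches the feature" — and `min_kmer_frac = 0.7`, which
tolerates roughly one substitution per 21 bp.

## Counting

Reads are grouped by `(cell barcode, UMI)`; corrected tags (`CB`/`UB`) are
preferred with raw tags (`CR`/`UR`) as fallback, and untagged records are
dropped with a logged count. A molecule's feature set is the **union** of
its reads' feature sets, and each molecule with a non-empty set
contributes total weight 1 split equally: `1/|F|` per feature. Union-then-
split was chosen over majority voting because it is deterministic, order-
independent, and mirrors the expected-weight behaviour of EM-free
pseudo-alignment aggregation; fractional weights are kept in the output
rather than rounded, so weight is conserved exactly (the matrix total
equals the number of assigned molecules — asserted in the tests).

Columns are fixed either by a user-supplied whitelist (all listed
barcodes appear, even all-zero) or, without one, by keeping the top
`N = 3000` barcodes by assigned weight, `N` chosen to match common
practice of forcing a cell count when no external cell calling is
available. Matrices are written in the 10x MatrixMarket layout with
real-valued entries, 1-based indices and column-major triplet order, so
reruns are byte-identical.

Per-cell normalization is `log2(1 + s · c / T)` with scale `s = 10^4`
(the dominant single-cell convention) and `T` the cell's total count in
this matrix; log base 2 is used throughout, and all-zero cells map to
zero rather than to `-Inf`.

## Mixed read lengths

Libraries occasionally mix two R2 lengths. Because the flank length is a
function of `R`, the pipeline partitions reads at a threshold (default
100 bp, with `length ≤ 100` in the short group), builds a reference per
group using that group's modal read length (ties broken towards the longer
length), quantifies each group separately, and adds the two matrices
element-wise over the barcode union. With a single read length this
reduces to one pass.

## Subsampling and the saturation model

Depth dependence is studied by qname-level subsampling on a fraction grid
of 5% to 100% in steps of 5 (20 points). Each read name is retained when a
deterministic 32-bit hash of `(seed, qname)` falls below the fraction —
the samtools `--subsample` contract: records of one qname share fate, and
subsets are nested across fractions at a fixed seed (so detection
estimators are provably monotone in depth on error-free data). The default
seed is 42. The hash is FNV-1a with a murmur-style finalizer; without the
finalizer, consecutively numbered read names receive correlated hashes and
subsampling would be biased for simulated data.

For each fraction the *full* quantification is rerun and two estimators
are computed: the fraction of cells with a positive count for a feature,
and the mean (zeros included) log2-normalized count. The depth covariate
`X` is the mean number of uniquely mapped reads per cell, recomputed from
the subsample (`NH == 1`, falling back to `mapq == 255` when the NH tag is
absent), with every whitelisted cell in the denominator. The points are
fitted with

$$Y = \frac{aX}{b+X},$$

`a` the plateau of the estimator and `b` the depth at which `Y = a/2`.
The fit is unweighted nonlinear least squares via Levenberg–Marquardt with
the analytic Jacobian ($\partial Y/\partial a = X/(b+X)$,
$\partial Y/\partial b = -aX/(b+X)^2$), initialized at `a₀ = max(Y)` and
`b₀ = X` of the point whose `Y` is nearest `a₀/2`. Convergence accepts the
standard tolerance conditions *and* the zero-gradient condition, which is
the one reached on noise-free data where the residual vanishes; the
generic `stats::nls` solver serves as an independent cross-check in the
tests. Success additionally requires `a, b > 0`; non-convergence is
flagged, with parameters still returned.

## The simulator: what it does and does not emulate

`make_toy_model()` embeds `n ≥ 7` exons (default 9) of random length
120–200 bp, separated by introns of 80–300 bp, in a random plus-strand
genome — large enough that every exon exceeds any flank, small enough that
exhaustive window scans stay instant. `simulate_reads()` draws reads from
the *spliced transcript* of each molecule's isoform and lifts them to
genomic coordinates with exact `N`-gapped CIGARs, the way real cDNA reads
arise; junction reads are therefore consistent by construction. Barcodes
are 16-mers and UMIs 12-mers, matching 10x tag shapes; substitution errors
are optional. An `informative_only` mode restricts read starts to
positions overlapping at least one feature of the molecule's isoform,
which makes every molecule recoverable and is how truth-recovery tests
avoid conflating sampling loss with classification error.

The simulator deliberately does **not** emulate: barcode or UMI sequencing
errors (a Cell Ranger BAM has already corrected them), ambient RNA,
doublets, PCR duplicates with errors, coverage bias along the transcript,
intronic or antisense reads, or minus-strand genes (gene models on either
strand are supported elsewhere; the simulator emits sense reads, and
antisense handling in the classifier is exercised by reverse-complement
unit tests). Passing tests on simulated data therefore demonstrate the
*logic* of the method — reference construction, classification, counting,
depth modelling — not robustness to every artifact of real libraries.

## Numerical and edge-case decisions

* Coordinates are 1-based inclusive everywhere a user sees them (GTF,
  region strings, SAM positions), the R/Bioconductor convention; feature
  intervals inside reference sequences are half-open 0-based and
  documented as such.
* Exons are merged by exact `(start, end)`; overlapping-but-unequal
  variants stay separate and must be disambiguated in the rules file —
  deterministic, no heuristic merging.
* Read-length inference takes the modal length, ties towards the longer
  read (a longer R only lengthens flanks, which weakens nothing).
* Duplicate-flagged records are retained (UMI deduplication supersedes
  them); secondary and supplementary alignments are dropped.
* `quantify()` with neither whitelist nor forced-cells keeps all observed
  barcodes — the mode used internally when length-split groups are merged
  before final column selection.
* Empty locus: an all-zero matrix with the whitelist's columns and a
  warning, not an error.
* Zero-width junction intervals sit at the flank boundary; "overlap" for a
  junction means straddling the point with ≥ `k` bases on each side.
* The locus region may be padded (default 0); the exact extent of a locus
  differs between genome builds, so padding is a parameter rather than a
  constant.

## Problem sizes used for verification

The shipped validation runs at sizes chosen to finish in seconds to a few
minutes while still exercising every code path: 50 randomized gene models
(7–14 exons; read length 50–150; `k` 1–10) for the exhaustive containment
scan (~10^5 windows); >10,000 simulated reads for dual-route agreement;
50 cells × 4 isoforms for end-to-end truth recovery; 100 noisy replicates
on the 20-point grid for fit recovery (σ = 0.01 Gaussian noise on the
estimator). `scripts/acceptance.R` recomputes all of these from scratch at
a caller-supplied seed.

## Known limitations

* 3' chemistry data carry little signal for the 5'-proximal alternative
  exons; the method runs but detects few feature reads per cell.
* Feature-level calls cannot distinguish co-occurring isoforms within a
  molecule beyond the read's span (no RAB vs RA×RB resolution), and no EM
  is attempted for multi-feature molecules — weight is split equally.
* Reads overlapping a feature by fewer bases than the k-mer size are
  sequence-ambiguous at exon boundaries that share prefixes; with the
  default `min_overlap = 1` such molecules may legitimately split weight
  across two features.
* The k-mer classifier assumes the discriminating reference is the only
  relevant sequence space; reads from paralogous loci that happen to be
  extracted would need the aligner-based upstream filter (the locus
  region) to have done its job.
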