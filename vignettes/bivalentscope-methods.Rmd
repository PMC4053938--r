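---
title: "Methods: metagene profiling and bimodal decomposition of 5hmC/Tet1/PRC2 co-occupancy"
author: "bivalentscope"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: metagene profiling and bimodal decomposition}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(bivalentscope)
```

# Scientific setting

5-hydroxymethylcytosine (5hmC) is the oxidation product of 5mC produced by
the TET enzymes. In embryonic stem cells, Tet1 is recruited to chromatin
at H3K27me3-positive regions, and on *bivalent* promoters — promoters
carrying both H3K4me3 and H3K27me3 — its occupancy is bimodal: a narrow
pool at the transcription start site (TSS) and a broad pool shifted
several hundred bp downstream that co-localizes with PRC2 (Suz12) and
with 5hmC itself. This package implements the downstream quantitative
analyses needed to establish and measure that structure from coverage
tracks, peak sets, gene models and expression tables, plus a seeded
synthetic-data generator so that every stage is testable without
sequencing data.

# Coordinate conventions

All file interfaces use the BED family conventions (0-based, half-open):
`length = end - start`, and touching records such as `[100,200)` and
`[200,300)` do not overlap. Internally the package stores intervals as
Bioconductor `GRanges` (1-based, closed) because GenomicRanges/IRanges
supply the field-standard containers and interval arithmetic; conversion
happens exactly once, at read/write time, and all half-open boundary
semantics are preserved at the interfaces (this is asserted by tests).
The TSS of a `-` strand gene is the last covered base of its span, so
reflecting the genome (coordinates and strands together) leaves every
TSS, promoter window and profile matrix invariant — a property the test
suite checks explicitly.

Promoter windows are strand-aware reflections: for a `+` gene the window
covers `upstream` bp before the TSS and `downstream` bp from the TSS base
on; for a `-` gene it is the exact mirror image. We chose strict
reflection symmetry (rather than any off-by-one variant) because it makes
strand a pure relabelling, which is the invariant the profile engine
relies on.

# Profile matrices

`build_tss_matrix()` averages per-bp signal into fixed-width bins across
`[-flank, +flank)` around each TSS, reversing minus-strand rows so the
axis is always 5'→3'. Row signal is the **mean per-bp** value in the bin
(not the sum) so that bins of different widths — and the mixed fixed-bp /
scaled bins of the gene-body mode — stay comparable. Defaults are a
±5 kb window with 50 bp bins (200 bins) for clustering and decomposition,
chosen so a few-hundred-bp shift between binding modes spans many bins;
±2 kb with 25 bp bins is used where only the promoter-proximal shape
matters. `build_scaled_body_matrix()` maps each gene body onto 100 equal
fractions (fractional-overlap weighting, so genes shorter than 100 bp are
still usable and flagged) with 2 kb fixed flanks, the common metagene
layout. Bins that fall off the chromosome contribute zero and flag the
row as clipped.

`compare_profiles()` tests a control-vs-condition difference of
metaprofiles over the same genes. Because the design is paired per gene,
the label-swap null is implemented as a sign-flip of per-gene row
differences; the two-sided p-value uses the `(b + 1)/(n + 1)` estimator,
which never returns zero and is slightly conservative. Benjamini–Hochberg
adjustment is applied across the bins of one comparison.

# Classification schemes

* **Expression tiers**: RPKM `< 0.1` (none), `[0.1, 5)` (low), `>= 5`
  (mid/high); intervals left-closed so boundary values fall upward.
* **Tissue-specific genes**: RPKM at least 10 in the target tissue and
  below 1 in every other sample. **Housekeeping genes**: RPKM above 10 in
  all samples.
* **CpG classes**: over 500-bp windows sliding in 5-bp steps across the
  promoter sequence (TSS ± 1 kb), the CpG observed/expected ratio
  `#CG × L / (#C × #G)` and GC fraction are computed; HCP if any window
  exceeds ratio 0.75 with GC > 0.55, LCP if no window reaches ratio 0.48,
  ICP otherwise. These are the standard published thresholds for this
  three-way scheme; the 5-bp step is a speed/precision compromise that
  tests show does not change calls on generated promoters.
* **Chromatin classes**: presence/absence of ≥1 bp overlap between each
  mark's peaks and the TSS ± 1 kb window gives K4 / K27 / K4-K27
  (bivalent) / none. No peak-score cutoff is applied: the upstream peak
  caller is trusted, and presence/absence is the only rule that is
  portable across callers.
* **Enhancers** are assumed pre-filtered to H3K4me1-positive distal
  elements; the package only splits them into active (H3K27ac-overlapping)
  vs poised.

# Co-occupancy statistics

`element_density()` reports the fraction of merged element bp covered by
at least one mark interval — a covered-bp (binary) definition, matching
the "% of segment length" notion of density; it is invariant to splitting
marks into adjacent pieces. `enrichment_test()` compares two disjoint
element classes by randomly reassigning the pooled elements between the
classes (sizes preserved). When the number of distinct reassignments is
small the test enumerates all of them and the p-value is exact; otherwise
it samples `n_perm` reassignments with the `(b + 1)/(n + 1)` estimator.
The test statistic is the difference of covered-bp densities.
`overlap_fraction()` counts each query interval once if it overlaps any
target interval by ≥1 bp. `signal_correlation()` reduces each track to
per-region means (binary occupancy for peak sets) and reports the Pearson
matrix; zero-variance inputs yield `NA` with a warning rather than a
fabricated value.

# Profile clustering

Per-gene profiles are clustered with Lloyd iterations under the distance
`d(a, b) = 1 - cor(a, b)`. Each row is centred and scaled to unit norm
once, after which `1 - cor` to a centroid equals `1 -` cosine similarity,
and the mean of member rows maximizes the summed cosine — i.e. the
procedure is spherical k-means on centred rows, whose objective is
provably non-increasing per iteration (the test suite asserts this on the
recorded objective trace). Consequences of the Pearson distance:

* rows with zero variance have no defined correlation and are excluded up
  front with a warning rather than assigned arbitrarily;
* the result is invariant to per-row affine rescaling, so no further
  standardization is applied;
* an emptied cluster is re-seeded from the point farthest from its
  current centroid.

Initial centroids are `k` distinct rows drawn under the seed; runs are
fully reproducible. Reported centroids are per-bin means of the member
rows on the original scale (interpretable as profiles), while the
internal iteration uses the standardized rows. Stability is assessed by
re-running with consecutive seeds and scoring every pair of runs with the
adjusted Rand index (ARI; chance-corrected and invariant to the arbitrary
k-means labelling — raw agreement would not be). The ARI itself is
computed by `mclust::adjustedRandIndex` and is cross-checked in the tests
against the closed-form contingency-table formula. The reference analysis
for this design uses 100 realizations and k = 2; both are defaults.

# Two-Gaussian decomposition

The aggregate profile is modelled as
`f(x) = A [ w e^{-(x-\mu_1)^2/2\sigma_1^2} + (1-w) e^{-(x-\mu_2)^2/2\sigma_2^2} ]`
with six free parameters, fitted by least squares. Numerical choices:

* **Initialization** is a variable-projection grid: candidate centres are
  the two highest local maxima (at least ~3 bins apart), the axis
  quartiles and the profile's weighted mean; candidate widths span
  0.005–0.25 of the axis span. For every centre pair the two amplitudes
  are solved in closed form by linear least squares; the best width combo
  per centre pair seeds a bounded Levenberg–Marquardt refinement
  (`minpack.lm::nls.lm`) and the lowest-RSS solution wins. Refining from
  every centre pair (a few dozen cheap starts) is what makes recovery
  robust when the two components overlap heavily or differ greatly in
  mass.
* **Bounds**: widths are bounded below at half the bin width (prevents
  collapse onto a single bin); the weight is constrained to
  `[0.001, 0.999]`; centres may wander one axis-span beyond the data.
* **Identifiability**: the model is symmetric under component swap with
  `w <-> 1 - w`, so components are reordered post hoc to `mu1 <= mu2`.
* **Degenerate inputs**: fewer than 12 bins (twice the parameter count),
  an identically-zero profile, or a profile with no positive signal are
  errors. Small negative values — metaprofile means are noisy estimates —
  are tolerated with a warning; they must not be clipped to zero by the
  caller, since zero-truncation of symmetric noise creates a positive
  background pedestal that a baseline-free six-parameter model can only
  absorb by distorting the broad component.

The fit is invariant to uniform rescaling of the profile (up to `A`) and
equivariant under axis shifts; both properties are asserted to tight
tolerances in the tests.

# The synthetic-data generator

`sim_config()` defines the package's reference study conditions; the
defaults are fixed once and everything downstream (tests, the acceptance
script) runs against them.

* **Genome and genes**: one synthetic chromosome, 600 genes in 25 kb
  slots (genes never overlap and ±5 kb TSS windows stay inside their
  slot), lengths uniform in 2–8 kb, 2–8 exons, strands Bernoulli(1/2).
* **Classes**: 30% bivalent, 40% K4-only, 70/30 of which are HCP/ICP, 30%
  silent (60/40 LCP/ICP) — bivalent promoters are CpG-rich in ESCs, which
  the promoter-sequence Markov chains reproduce (HCP: GC 0.62 with CpG
  transition 0.45; ICP: 0.50/0.15; LCP: 0.40/0.02, tuned so ≥95% of
  generated promoters classify into their target class).
* **Tet1 truth**: bivalent promoters get the six-parameter profile with
  centres −39 and +455 bp, widths 80 and 400 bp, upstream weight 0.45 and
  amplitude 10 — centres match the fitted values this analysis design
  reports on real bivalent promoters; the widths are chosen to make the
  narrow/broad contrast realistic since no widths are published. K4-only
  promoters get a single TSS-centred Gaussian (σ = 120 bp, amplitude 12).
* **Other marks**: H3K4me3 on all expressed promoters (σ = 300 bp);
  H3K27me3 as a broad block from −0.5 to +2.5 kb on bivalent promoters;
  5hmC with a PRC2-dependent component coincident with the downstream
  Tet1 component plus a gene-body component whose density follows the
  rise-and-fall `exp(-(log10 RPKM - 1)^2 / (2·0.8^2))`, peaking at
  log10 RPKM = 1 and vanishing for silent and very highly expressed
  genes. A knockdown 5hmC track retains 15% of the PRC2-dependent
  component, emulating Suz12 depletion.
* **Expression**: per-tier log10-normal RPKM (silent −3, low 0.5,
  mid/high 1.5; SD 0.4), four samples (ESC, MEF, brain, liver) drawn
  i.i.d. per gene; 15% of K4-only genes are designated housekeeping
  (RPKM guaranteed > 10 everywhere) and 10% liver-specific (≥ 10 in
  liver, < 1 elsewhere).
* **Noise**: Poisson-like — SD `noise_sd · sqrt(v · ref)` at model value
  `v` (10% of the mark's peak amplitude at the peak), applied only on the
  signal support and floored at zero. Enrichment tracks are sparse, so
  aggregate metaprofiles carry no background pedestal; this matters
  because the six-parameter model has no baseline term (see above).
* **Peaks**: a thresholding stand-in for a peak caller — runs above 25%
  of the mark's peak amplitude, at least 50 bp wide.

Signal is laid down on a 25-bp integer grid and rounded to 4 decimals, so
regeneration under one seed is byte-identical across platforms (R's
default Mersenne-Twister RNG; the test suite checks manifest checksums).

**What the generator does not emulate** — and hence what passing tests do
*not* show about real data: read-level sampling noise and mappability
artifacts, correlated expression across tissues (samples are i.i.d., so
many broadly expressed genes legitimately satisfy the housekeeping rule
beyond the designated set), chromatin domains beyond promoter-proximal
blocks, inter-gene signal spill-over, and peak-caller-specific behaviour.
Tests against it validate the machinery (coordinate arithmetic,
estimators, optimizers, determinism), not biological discovery.

# Pipeline

`run_pipeline()` composes eight analyses (expression-ordered heatmaps and
tier metaprofiles, element-class densities with pairwise enrichment
tests, the mark correlation matrix, H3K27me3-ordered profiles,
peak-overlap fractions, profile clustering with stability, the bimodal
decomposition on H3K27me3-positive promoters, and the knockdown
differential). Inputs are validated per requested analysis before any
computation starts; every analysis writes TSV/JSON outputs that are pure
functions of inputs and configuration, and a manifest records parameters,
seeds and the multiple-testing adjustment (BH within each analysis's
p-value family). Two runs with one configuration are byte-identical.

# Problem sizes and defaults

The package's reference conditions are 600 genes, ±5 kb / 50 bp profile
matrices, k = 2 clustering with 100 stability realizations, 999–1000
permutations for significance tests, and 100 replicates for Monte-Carlo
recovery checks — sizes at which every end-to-end analysis completes in
seconds to a couple of minutes on a single CPU while keeping Monte-Carlo
standard errors small relative to the tolerances being asserted.

# Known limitations

* The bedGraph reader rejects overlapping runs rather than summing them;
  tracks must be pre-normalized (this keeps the total-signal invariant
  trivial and surfaces malformed inputs early).
* The covered-bp density treats marks as binary; a signal-weighted
  density is not currently exposed.
* The enrichment test requires disjoint element universes; overlapping
  class definitions must be resolved upstream.
* `fit_two_gaussians()` fits exactly two components with no baseline
  term; profiles with a substantial uniform background should be
  background-subtracted first.
* Model selection over k (clustering) or over the number of Gaussian
  components is out of scope; k = 2 and two components are fixed by the
  analysis design.
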