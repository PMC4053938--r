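# bivalentscope

Downstream analysis of **5-hydroxymethylcytosine (5hmC), Tet1 and Polycomb
(PRC2) co-occupancy** around gene promoters, for epigenomics analysts
working with coverage tracks (bedGraph), peak calls (BED), gene models
(BED12) and RNA-seq expression tables (RPKM).

In embryonic stem cells, many developmental promoters are *bivalent*: they
carry both the active H3K4me3 and the repressive H3K27me3 mark. Tet1 — the
enzyme that oxidizes 5mC to 5hmC — binds these promoters in a
characteristically **bimodal** pattern: a narrow component at the
transcription start site (TSS) and a broad component shifted several
hundred bp downstream, coincident with PRC2 (Suz12/Ezh2) and with 5hmC
itself. This package provides the quantitative machinery to detect and
measure that structure:

- **Metagene profiling** — TSS-anchored and scaled gene-body profile
  matrices from coverage tracks, metaprofiles, expression- or mark-ordered
  heatmap matrices, gene-body densities
  (`build_tss_matrix()`, `build_scaled_body_matrix()`, `mean_profile()`,
  `genebody_density()`, `order_rows()`).
- **Promoter classification** — CpG content (LCP/ICP/HCP via the CpG
  observed/expected ratio), chromatin state (K4 / K27 / bivalent K4-K27 /
  none), expression tiers, tissue-specific and housekeeping genes
  (`cpg_class()`, `chromatin_class()`, `expression_tiers()`, ...).
- **Co-occupancy statistics** — per-element-class signal densities with
  seeded permutation enrichment tests, peak co-binding fractions, mark
  correlation matrices (`element_density()`, `enrichment_test()`,
  `overlap_fraction()`, `signal_correlation()`).
- **Profile decomposition** — k-means over per-gene binding profiles with
  `1 - Pearson r` as the distance, with stability over repeated seeded
  realizations scored by the adjusted Rand index; and a six-parameter
  least-squares decomposition of an aggregate profile into two
  non-normalized Gaussians (`cluster_profiles()`, `cluster_stability()`,
  `fit_two_gaussians()`).
- **Differential profiles** — paired sign-flip permutation test for
  control-vs-knockdown metaprofile differences (`compare_profiles()`).
- **Synthetic data** — a fully seeded generator that emits complete
  fixture bundles (annotation, promoter FASTA, tracks, peaks, expression,
  ground truth) with the statistical structure the analysis assumes
  (`sim_config()`, `emit_fixture()`), and `run_pipeline()` to compose
  everything into deterministic end-to-end runs.

## The core model

The aggregate Tet1 profile on H3K27me3-positive promoters is modelled as a
superposition of two non-normalized Gaussians with six free parameters —
two centres, two widths, one relative weight, one overall amplitude:

```
f(x) = A * [ w * exp(-(x - mu1)^2 / (2 sigma1^2))
           + (1 - w) * exp(-(x - mu2)^2 / (2 sigma2^2)) ]
```

fitted by bounded Levenberg–Marquardt least squares from a
variable-projection start grid (for fixed centres and widths, the two
amplitudes are a linear least-squares problem). Components are reported
with `mu1 <= mu2`. Per-gene profiles are clustered by Lloyd iterations
with distance `d(a, b) = 1 - cor(a, b)`, equivalent (after per-row
centring and norming) to spherical k-means, so the objective is provably
non-increasing and runs are deterministic given a seed.

## Worked example

Everything below runs offline on a seeded synthetic dataset whose planted
structure mirrors the biology described above:

```r
library(bivalentscope)

cfg <- sim_config(seed = 7, n_genes = 300)
ann <- generate_annotation(cfg)
dat <- generate_tracks(ann, cfg)

m <- build_tss_matrix(dat$tracks$tet1, ann$genes,
                      flank = 5000, bin_width = 50)
m
#> profile_matrix: 300 genes x 200 bins, anchor=tss, flank=5000 bp

cluster_profiles(m, k = 2, seed = 1)
#> profile_clusters: k=2, n=200 genes, 2 iterations (seed 1)
#>   cluster 1: 100 genes, within-cluster mean r = 0.993
#>   cluster 2: 100 genes, within-cluster mean r = 0.997

biv <- dat$truth$gene_id[dat$truth$class == "bivalent"]
fit_two_gaussians(mean_profile(m, biv))
#> Two-Gaussian decomposition (non-normalized components)
#>   component 1: centre -38.7 bp, width (sigma) 81.3 bp, weight 0.450
#>   component 2: centre +457.2 bp, width (sigma) 397.5 bp, weight 0.550
#>   amplitude 9.992, RSS 0.1971, converged: TRUE

ov <- overlap_fraction(dat$peaks$k27, dat$peaks$tet1, "H3K27me3", "Tet1")
sprintf("%.1f%% of %s peaks are also bound by %s",
        100 * ov$fraction, ov$label_A, ov$label_B)
#> "100.0% of H3K27me3 peaks are also bound by Tet1"
```

The 100 silent genes carry no Tet1 signal and are excluded from clustering
(zero variance); the remaining 200 split perfectly into the TSS-centred
(K4-only) and downstream-shifted (bivalent) occupancy shapes, and the
bivalent metaprofile decomposes into a narrow TSS component near −39 bp
and a broad downstream component near +455 bp — the planted generating
parameters. A model object supports `coef()`, `summary()`, `predict()`,
`fitted()`, `residuals()` and `plot()`.

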