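Package: bivalentscope
Title: Metagene Profiling and Bimodal Decomposition of 5hmC/Tet1/PRC2
    Co-Occupancy
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Downstream analysis of 5-hydroxymethylcytosine (5hmC), Tet1 and
    Polycomb (PRC2) occupancy around gene promoters in embryonic stem cells
    and differentiated tissues. Builds TSS-anchored and scaled gene-body
    profile matrices from coverage tracks, classifies promoters by CpG
    content, chromatin state (H3K4me3/H3K27me3 bivalency) and expression
    tier, computes element-class signal densities with permutation
    enrichment tests and peak co-binding fractions, clusters per-gene
    binding profiles by correlation-distance k-means with multi-seed
    stability assessment, and decomposes aggregate binding profiles into a
    six-parameter superposition of two non-normalized Gaussians. A seeded
    synthetic-data generator emits complete fixture bundles (gene models,
    coverage tracks, peak sets, promoter sequences, expression tables) with
    ground-truth labels so every stage is testable without sequencing data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    GenomicRanges,
    IRanges,
    S4Vectors,
    GenomeInfoDb,
    Biostrings,
    minpack.lm,
    mclust,
    jsonlite,
    stats,
    utils,
    graphics,
    tools,
    methods
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
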