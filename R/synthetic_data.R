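## Seeded generator for a complete fixture: gene models on a synthetic
## chromosome, promoter sequences hitting target CpG classes, coverage
## tracks for Tet1 / H3K4me3 / H3K27me3 / 5hmC (plus a PRC2-knockdown 5hmC
## variant), thresholded peak sets, an expression table with
## housekeeping / tissue-specific structure, and a ground-truth table.
##
## The generative structure mirrors what the analysis assumes: bivalent
## promoters carry a bimodal Tet1 profile (narrow TSS component plus a
## broad downstream component co-located with PRC2-dependent 5hmC and a
## broad H3K27me3 domain), K4-only promoters carry a single TSS-centred
## component, and gene-body 5hmC density rises with expression up to
## log10 RPKM = 1 and falls again at high expression.

#' Simulation configuration
#'
#' Defaults define the package's reference study conditions; see the
#' methods vignette for the rationale of each value.
#'
#' @param seed Integer seed driving every random choice.
#' @param n_genes Number of genes (>= 10).
#' @param chrom Chromosome name of the synthetic genome.
#' @param slot bp of chromosome allotted per gene (genes never overlap and
#'   their +/- 5 kb windows stay inside their slot).
#' @param gene_length_range Min/max gene length in bp.
#' @param class_fractions Named fractions (`bivalent`, `k4_only`,
#'   `silent`); must sum to 1.
#' @param bivalent_truth Six-parameter truth of the bivalent Tet1 profile
#'   (`mu1`, `sigma1`, `mu2`, `sigma2`, `w`, `A`; bp / signal units).
#' @param k4_truth Single-Gaussian truth of the K4-only Tet1 profile.
#' @param k4_amp,k27_amp H3K4me3 / H3K27me3 amplitudes.
#' @param k27_extent H3K27me3 domain relative to the TSS (bp, c(from, to)).
#' @param hmc_prom_amp Amplitude of the PRC2-dependent promoter 5hmC
#'   component (centred with the downstream Tet1 component).
#' @param hmc_body_max Peak gene-body 5hmC density at log10 RPKM = 1.
#' @param kd_factor Residual fraction of the PRC2-dependent 5hmC component
#'   in the knockdown track.
#' @param noise_sd Noise SD as a fraction of each mark's peak amplitude.
#' @param step Grid step in bp at which signal is laid down.
#' @param peak_threshold Peak-calling stand-in: fraction of the mark's peak
#'   amplitude a run must exceed.
#' @param min_peak_width Minimum peak width in bp.
#' @param expr_log10_mean,expr_log10_sd Per-tier log10 RPKM location/scale
#'   (`none`, `low`, `mid_high`).
#' @param hk_fraction,liver_fraction Fractions of K4-only genes designated
#'   housekeeping / liver-specific.
#' @param samples Sample labels of the expression table (first = the
#'   profiled cell type).
#' @return A `sim_config` list.
#' @export
sim_config <- function(seed = 1L,
                       n_genes = 600L,
                       chrom = "chrS",
                       slot = 25000L,
                       gene_length_range = c(2000L, 8000L),
                       class_fractions = c(bivalent = 0.3, k4_only = 0.4,
                                           silent = 0.3),
                       bivalent_truth = c(mu1 = -39, sigma1 = 80,
                                          mu2 = 455, sigma2 = 400,
                                          w = 0.45, A = 10),
                       k4_truth = c(mu = 0, sigma = 120, A = 12),
                       k4_amp = 8, k27_amp = 6,
                       k27_extent = c(-500, 2500),
                       hmc_prom_amp = 5, hmc_body_max = 3,
                       kd_factor = 0.15,
                       noise_sd = 0.1,
                       step = 25L,
                       peak_threshold = 0.25,
                       min_peak_width = 50L,
                       expr_log10_mean = c(none = -3, low = 0.5,
                                           mid_high = 1.5),
                       expr_log10_sd = 0.4,
                       hk_fraction = 0.15, liver_fraction = 0.1,
                       samples = c("ESC", "MEF", "brain", "liver")) {
  stopifnot(n_genes >= 10L,
            abs(sum(class_fractions) - 1) < 1e-9,
            all(gene_length_range > 0), step >= 1L,
            noise_sd >= 0, length(samples) >= 2L)
  cfg <- as.list(environment())
  cfg$chrom_length <- as.integer(n_genes) * as.integer(slot)
  if (cfg$gene_length_range[2L] + 2L * 5000L + 2000L > slot)
    stop("genes do not fit in chrom_length: increase slot", call. = FALSE)
  class(cfg) <- "sim_config"
  cfg
}

# first-order Markov chains tuned so that generated promoters classify as
# their target CpG class (see methods vignette): columns A, C, G, T
.cpg_chain_params <- list(
  HCP = list(gc = 0.62, pcg = 0.45),
  ICP = list(gc = 0.50, pcg = 0.15),
  LCP = list(gc = 0.40, pcg = 0.02))

.cpg_transition <- function(gc, pcg) {
  p <- c(A = (1 - gc) / 2, C = gc / 2, G = gc / 2, T = (1 - gc) / 2)
  g2 <- (p["G"] - p["C"] * pcg) / (1 - p["C"])   # keep the G marginal
  Tm <- matrix(0, 4, 4, dimnames = list(names(p), names(p)))
  for (s in names(p)) {
    pg <- if (s == "C") pcg else g2
    rest <- p[c("A", "C", "T")] / sum(p[c("A", "C", "T")])
    Tm[s, ] <- c(rest["A"] * (1 - pg), rest["C"] * (1 - pg), pg,
                 rest["T"] * (1 - pg))
  }
  Tm
}

# vectorized Markov sampling: n sequences of length len in parallel
.markov_seqs <- function(n, len, Tm) {
  bases <- c("A", "C", "G", "T")
  cum <- t(apply(Tm, 1L, cumsum))
  state <- sample.int(4L, n, replace = TRUE)
  out <- matrix(0L, n, len)
  out[, 1L] <- state
  for (j in seq_len(len - 1L)) {
    u <- stats::runif(n)
    state <- 1L + (u > cum[state, 1L]) + (u > cum[state, 2L]) +
      (u > cum[state, 3L])
    out[, j + 1L] <- state
  }
  apply(out, 1L, function(r) paste(bases[r], collapse = ""))
}

#' Generate the synthetic annotation
#'
#' Non-overlapping genes with mixed strands and 2-8 exons each, a
#' genome-size table, promoter sequences (TSS +/- 1 kb) drawn from
#' CpG-class-specific Markov chains, and the truth table skeleton.
#'
#' @param config A [sim_config()].
#' @return List with `genes` (gene models, as from [read_gene_models()]),
#'   `seqlengths`, `promoter_seqs` (named character), and `truth`
#'   (data.frame with `gene_id`, `class`, `cpg_class`, `strand`).
#' @export
generate_annotation <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  n <- config$n_genes
  ids <- sprintf("g%04d", seq_len(n))
  classes <- sample(rep(names(config$class_fractions),
                        times = round(config$class_fractions * n),
                        length.out = n))
  strands <- sample(c("+", "-"), n, replace = TRUE)
  glen <- sample(seq(config$gene_length_range[1L],
                     config$gene_length_range[2L]), n, replace = TRUE)
  margin <- 6000L
  slot_start <- (seq_len(n) - 1L) * config$slot
  s0 <- slot_start + margin                      # BED start, 0-based
  e0 <- s0 + glen
  # exons: 2-8 blocks; first starts at gene start, last ends at gene end
  exon_rows <- vapply(seq_len(n), function(i) {
    k <- sample(2:8, 1L)
    inner <- sort(sample(seq_len(glen[i] - 2L), 2L * (k - 1L)))
    bounds <- c(0L, inner, glen[i])
    starts <- bounds[seq(1L, 2L * k, by = 2L)]
    ends <- bounds[seq(2L, 2L * k, by = 2L)]
    paste(k, paste0(paste(ends - starts, collapse = ","), ","),
          paste0(paste(starts, collapse = ","), ","), sep = "|")
  }, "")
  cpg <- character(n)
  cpg[classes == "bivalent"] <- "HCP"
  cpg[classes == "k4_only"] <- sample(c("HCP", "ICP"),
                                      sum(classes == "k4_only"),
                                      replace = TRUE, prob = c(0.7, 0.3))
  cpg[classes == "silent"] <- sample(c("LCP", "ICP"),
                                     sum(classes == "silent"),
                                     replace = TRUE, prob = c(0.6, 0.4))
  prom_seqs <- character(n)
  for (cl in names(.cpg_chain_params)) {
    idx <- which(cpg == cl)
    if (!length(idx)) next
    pars <- .cpg_chain_params[[cl]]
    Tm <- .cpg_transition(pars$gc, pars$pcg)
    prom_seqs[idx] <- .markov_seqs(length(idx), 2000L, Tm)
  }
  names(prom_seqs) <- ids
  ex <- strsplit(exon_rows, "|", fixed = TRUE)
  bed12 <- paste(config$chrom, s0, e0, ids, 0, strands, s0, e0, "0",
                 vapply(ex, `[[`, "", 1L), vapply(ex, `[[`, "", 2L),
                 vapply(ex, `[[`, "", 3L), sep = "\t")
  tmp <- tempfile(fileext = ".bed12")
  writeLines(bed12, tmp)
  genes <- read_gene_models(tmp)
  unlink(tmp)
  seqlengths <- stats::setNames(config$chrom_length, config$chrom)
  truth <- data.frame(gene_id = ids, class = classes, cpg_class = cpg,
                      strand = strands, stringsAsFactors = FALSE)
  list(genes = genes, seqlengths = seqlengths,
       promoter_seqs = prom_seqs, truth = truth)
}

# model signal (no noise) for one mark at offsets o (bp relative to TSS,
# 5'->3'), given gene class
.mark_model <- function(mark, o, class, cfg, body_dens = 0, gene_len = 0) {
  bt <- cfg$bivalent_truth
  kt <- cfg$k4_truth
  v <- numeric(length(o))
  if (mark %in% c("tet1")) {
    if (class == "bivalent")
      v <- bimodal_model(o, bt[["mu1"]], bt[["sigma1"]], bt[["mu2"]],
                         bt[["sigma2"]], bt[["w"]], bt[["A"]])
    else if (class == "k4_only")
      v <- kt[["A"]] * exp(-(o - kt[["mu"]])^2 / (2 * kt[["sigma"]]^2))
  } else if (mark == "k4") {
    if (class != "silent")
      v <- cfg$k4_amp * exp(-o^2 / (2 * 300^2))
  } else if (mark == "k27") {
    if (class == "bivalent")
      v <- cfg$k27_amp * (o >= cfg$k27_extent[1L] & o <= cfg$k27_extent[2L])
  } else if (mark %in% c("hmc", "hmc_kd")) {
    if (class == "bivalent") {
      amp <- cfg$hmc_prom_amp * if (mark == "hmc_kd") cfg$kd_factor else 1
      v <- amp * exp(-(o - bt[["mu2"]])^2 / (2 * bt[["sigma2"]]^2))
    }
    v <- v + body_dens * (o >= 0 & o < gene_len)
  }
  v
}

.mark_ref_amp <- function(mark, cfg) {
  switch(mark,
         tet1 = max(cfg$bivalent_truth[["A"]], cfg$k4_truth[["A"]]),
         k4 = cfg$k4_amp,
         k27 = cfg$k27_amp,
         hmc = max(cfg$hmc_prom_amp, cfg$hmc_body_max),
         hmc_kd = max(cfg$hmc_prom_amp, cfg$hmc_body_max))
}

#' Generate coverage tracks, peak sets, expression and ground truth
#'
#' @param annotation Output of [generate_annotation()].
#' @param config The same [sim_config()].
#' @return List with `tracks` (named `signal_track`s: `tet1`, `k4`
#'   (H3K4me3), `k27` (H3K27me3), `hmc` (5hmC), `hmc_kd` (5hmC under PRC2
#'   knockdown)), `peaks` (named `GRanges`), `expression` (gene x sample
#'   RPKM matrix) and `truth` (data.frame incl. planted profile
#'   parameters, expression tier and housekeeping/liver-specific flags).
#' @export
generate_tracks <- function(annotation, config) {
  stopifnot(inherits(config, "sim_config"))
  cfg <- config
  genes <- annotation$genes
  truth <- annotation$truth
  n <- length(genes)
  set.seed(cfg$seed + 1L)

  ## expression table -------------------------------------------------------
  tier <- c(bivalent = "low", k4_only = "mid_high", silent = "none")[
    truth$class]
  k4_idx <- which(truth$class == "k4_only")
  n_hk <- round(cfg$hk_fraction * length(k4_idx))
  n_liv <- round(cfg$liver_fraction * length(k4_idx))
  special <- sample(k4_idx, n_hk + n_liv)
  hk_idx <- special[seq_len(n_hk)]
  liv_idx <- special[n_hk + seq_len(n_liv)]
  expr <- matrix(0, n, length(cfg$samples),
                 dimnames = list(truth$gene_id, cfg$samples))
  for (s in seq_along(cfg$samples)) {
    mu <- cfg$expr_log10_mean[tier]
    expr[, s] <- 10^stats::rnorm(n, mu, cfg$expr_log10_sd)
  }
  # designated housekeeping: comfortably above 10 everywhere; designated
  # liver-specific: >= 10 in liver, < 1 elsewhere
  expr[hk_idx, ] <- 10^matrix(stats::runif(n_hk * length(cfg$samples),
                                           1.1, 2), n_hk)
  liver <- cfg$samples == "liver"
  expr[liv_idx, liver] <- 10^stats::runif(n_liv, 1.1, 2)
  expr[liv_idx, !liver] <- 10^matrix(
    stats::runif(n_liv * sum(!liver), -2, -0.1), n_liv)
  truth$expression_tier <- unname(tier)
  truth$housekeeping <- seq_len(n) %in% hk_idx
  truth$liver_specific <- seq_len(n) %in% liv_idx

  ## gene-body 5hmC density: rise-and-fall, peaked at log10 RPKM = 1 --------
  l10 <- log10(expr[, 1L] + 1e-6)
  body_dens <- cfg$hmc_body_max * exp(-(l10 - 1)^2 / (2 * 0.8^2))
  body_dens[tier == "none"] <- 0

  ## tracks on a `step`-bp grid ---------------------------------------------
  tss <- gene_tss(genes)
  minus <- truth$strand == "-"
  glen <- GenomicRanges::width(genes)
  flank <- 5000L
  marks <- c("tet1", "k4", "k27", "hmc", "hmc_kd")
  tracks <- list()
  peaks <- list()
  for (mark in marks) {
    ref <- .mark_ref_amp(mark, cfg)
    all_s <- vector("list", n)
    all_v <- vector("list", n)
    for (i in seq_len(n)) {
      # grid spans TSS window plus the gene body, in genomic coordinates
      lo <- min(tss[i] - flank, GenomicRanges::start(genes)[i])
      hi <- max(tss[i] + flank, GenomicRanges::end(genes)[i])
      gs <- seq(lo, hi - cfg$step + 1L, by = cfg$step)
      centre <- gs + (cfg$step - 1) / 2
      o <- if (minus[i]) tss[i] - centre else centre - tss[i]
      v <- .mark_model(mark, o, truth$class[i], cfg,
                       body_dens = body_dens[i], gene_len = glen[i])
      if (cfg$noise_sd > 0) {
        # Poisson-like noise: variance proportional to signal, zero off the
        # signal support (enrichment tracks are sparse), so aggregate
        # metaprofiles carry no background pedestal
        on <- v > 0.02 * ref
        v[on] <- v[on] + stats::rnorm(sum(on), 0,
                                      cfg$noise_sd * sqrt(v[on] * ref))
        v[!on] <- 0
      }
      v <- round(pmax(v, 0), 4L)
      keep <- v > 0
      all_s[[i]] <- gs[keep]
      all_v[[i]] <- v[keep]
    }
    s <- unlist(all_s)
    v <- unlist(all_v)
    gr <- GenomicRanges::GRanges(cfg$chrom,
                                 IRanges::IRanges(s, s + cfg$step - 1L),
                                 score = v)
    tr <- signal_track(gr, seqlengths = annotation$seqlengths)
    tracks[[mark]] <- tr
    peaks[[mark]] <- call_peaks(tr, threshold = cfg$peak_threshold * ref,
                                min_width = cfg$min_peak_width)
  }

  bt <- cfg$bivalent_truth
  kt <- cfg$k4_truth
  biv <- truth$class == "bivalent"
  truth$tet1_mu1 <- ifelse(biv, bt[["mu1"]],
                           ifelse(truth$class == "k4_only", kt[["mu"]], NA))
  truth$tet1_sigma1 <- ifelse(biv, bt[["sigma1"]],
                              ifelse(truth$class == "k4_only",
                                     kt[["sigma"]], NA))
  truth$tet1_mu2 <- ifelse(biv, bt[["mu2"]], NA)
  truth$tet1_sigma2 <- ifelse(biv, bt[["sigma2"]], NA)
  truth$tet1_w <- ifelse(biv, bt[["w"]], NA)
  truth$tet1_A <- ifelse(biv, bt[["A"]],
                         ifelse(truth$class == "k4_only", kt[["A"]], NA))

  list(tracks = tracks, peaks = peaks, expression = expr, truth = truth)
}

#' Threshold-based peak calling stand-in
#'
#' Contiguous runs with signal strictly above `threshold` and width at
#' least `min_width` bp become peaks.
#'
#' @param track A `signal_track`.
#' @param threshold Signal cutoff.
#' @param min_width Minimum peak width in bp.
#' @return A sorted `GRanges` of peaks.
#' @export
call_peaks <- function(track, threshold, min_width = 50L) {
  out <- list()
  for (ch in names(track$cov)) {
    v <- IRanges::slice(track$cov[[ch]], lower = threshold,
                        includeLower = FALSE)
    r <- IRanges::IRanges(start = IRanges::start(v), end = IRanges::end(v))
    r <- r[IRanges::width(r) >= min_width]
    if (length(r)) out[[ch]] <- GenomicRanges::GRanges(ch, r)
  }
  if (!length(out)) return(GenomicRanges::GRanges())
  sort(do.call(c, unname(out)), ignore.strand = TRUE)
}

#' Write a full fixture bundle to disk
#'
#' Emits `genes.bed12`, `genome.sizes`, `promoters.fa`,
#' `tracks/<mark>.bedGraph`, `peaks/<mark>.bed`, `expression.tsv`,
#' `truth.tsv` and a `manifest.json` echoing the configuration with an md5
#' checksum per file; the bundle re-parses losslessly through the package
#' readers and is byte-identical across regenerations with one config.
#'
#' @param config A [sim_config()].
#' @param out_dir Output directory (created if missing).
#' @return The manifest, invisibly.
#' @export
emit_fixture <- function(config, out_dir) {
  ann <- generate_annotation(config)
  dat <- generate_tracks(ann, config)
  dir.create(file.path(out_dir, "tracks"), recursive = TRUE,
             showWarnings = FALSE)
  dir.create(file.path(out_dir, "peaks"), showWarnings = FALSE)
  paths <- c(genes = "genes.bed12", sizes = "genome.sizes",
             fasta = "promoters.fa", expression = "expression.tsv",
             truth = "truth.tsv")
  write_gene_models(ann$genes, file.path(out_dir, paths["genes"]))
  write_genome_sizes(ann$seqlengths, file.path(out_dir, paths["sizes"]))
  write_sequences(ann$promoter_seqs, file.path(out_dir, paths["fasta"]))
  write_expression(dat$expression, file.path(out_dir, paths["expression"]))
  utils::write.table(dat$truth, file.path(out_dir, paths["truth"]),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  for (mark in names(dat$tracks)) {
    p <- file.path("tracks", paste0(mark, ".bedGraph"))
    write_signal(dat$tracks[[mark]], file.path(out_dir, p))
    paths[paste0("track_", mark)] <- p
    p <- file.path("peaks", paste0(mark, ".bed"))
    write_intervals(dat$peaks[[mark]], file.path(out_dir, p))
    paths[paste0("peaks_", mark)] <- p
  }
  cfg <- unclass(config)
  manifest <- list(
    seed = config$seed,
    config = cfg[order(names(cfg))],
    files = as.list(paths),
    checksums = as.list(tools::md5sum(file.path(out_dir, paths))))
  names(manifest$checksums) <- paths
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(manifest)
}
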