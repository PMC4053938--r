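## Orchestration: compose the stages into the eight named analyses with
## pre-flight input validation, seeded determinism, a manifest, and
## Benjamini-Hochberg adjustment across each analysis's p-value family.

.analysis_inputs <- list(
  expression_heatmaps = c("hmc_track", "genes", "expression"),
  element_densities = c("hmc_peaks", "genes", "k4_peaks", "k27_peaks"),
  mark_correlation = c("genes"),
  k27_ordered_profiles = c("hmc_track", "k27_track", "genes"),
  peak_overlap = c("k27_peaks", "tet1_peaks"),
  profile_clustering = c("tet1_track", "genes"),
  bimodal_decomposition = c("tet1_track", "k27_track", "genes"),
  differential_profiles = c("hmc_track", "hmc_kd_track", "k27_track",
                            "genes"))

#' Pipeline run configuration
#'
#' @param inputs Named list of file paths: `genes` (BED12), `sizes`
#'   (genome sizes), `expression` (TSV), `promoters_fasta` (FASTA),
#'   `<mark>_track` (bedGraph) and `<mark>_peaks` (BED) for marks among
#'   `hmc`, `hmc_kd`, `tet1`, `k4`, `k27`.
#' @param analyses Character vector of analyses to run (default: all
#'   whose inputs are present): `expression_heatmaps`,
#'   `element_densities`, `mark_correlation`, `k27_ordered_profiles`,
#'   `peak_overlap`, `profile_clustering`, `bimodal_decomposition`,
#'   `differential_profiles`.
#' @param flank,bin_width TSS window geometry (bp).
#' @param k,n_realizations Clustering parameters.
#' @param n_perm Permutations for the significance tests.
#' @param seed Master seed.
#' @param expression_sample Sample column used for tiers and orderings.
#' @return A `run_config` list.
#' @export
run_config <- function(inputs, analyses = NULL, flank = 5000L,
                       bin_width = 50L, k = 2L, n_realizations = 100L,
                       n_perm = 1000L, seed = 1L,
                       expression_sample = NULL) {
  if (is.null(analyses))
    analyses <- names(Filter(function(req) all(req %in% names(inputs)),
                             .analysis_inputs))
  structure(list(inputs = inputs, analyses = analyses, flank = flank,
                 bin_width = bin_width, k = k,
                 n_realizations = n_realizations, n_perm = n_perm,
                 seed = seed, expression_sample = expression_sample),
            class = "run_config")
}

.log_line <- function(con, ...) {
  msg <- paste0(...)
  writeLines(msg, con)
  message(msg)
}

#' Run the configured analyses
#'
#' Every requested analysis is validated against its required inputs
#' before any computation starts; outputs (TSV matrices, JSON reports, a
#' log and a manifest echoing parameters, seeds and the multiple-testing
#' adjustment) are pure functions of inputs and configuration, so reruns
#' are byte-identical.
#'
#' @param config A [run_config()].
#' @param out_dir Output directory.
#' @return Named list of in-memory results, invisibly.
#' @export
run_pipeline <- function(config, out_dir) {
  stopifnot(inherits(config, "run_config"))
  unknown <- setdiff(config$analyses, names(.analysis_inputs))
  if (length(unknown)) stop("unknown analyses: ",
                            paste(unknown, collapse = ", "), call. = FALSE)
  for (a in config$analyses) {
    miss <- setdiff(.analysis_inputs[[a]], names(config$inputs))
    if (length(miss))
      stop("analysis '", a, "' is missing input(s): ",
           paste(miss, collapse = ", "), call. = FALSE)
  }
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  log_con <- file(file.path(out_dir, "run.log"), "w")
  on.exit(close(log_con))
  .log_line(log_con, "seed: ", config$seed)

  inp <- config$inputs
  sizes <- if ("sizes" %in% names(inp)) read_genome_sizes(inp$sizes)
           else NULL
  genes <- read_gene_models(inp$genes)
  expr <- if ("expression" %in% names(inp)) read_expression(inp$expression)
          else NULL
  sample1 <- config$expression_sample
  if (is.null(sample1) && !is.null(expr)) sample1 <- colnames(expr)[1L]
  tracks <- list()
  peaks <- list()
  for (nm in names(inp)) {
    if (grepl("_track$", nm))
      tracks[[sub("_track$", "", nm)]] <- read_signal(inp[[nm]],
                                                      seqlengths = sizes)
    if (grepl("_peaks$", nm))
      peaks[[sub("_peaks$", "", nm)]] <- read_intervals(inp[[nm]])
  }
  results <- list()

  tsv <- function(df, name) {
    utils::write.table(df, file.path(out_dir, name), sep = "\t",
                       quote = FALSE, row.names = FALSE)
  }
  json <- function(x, name) {
    jsonlite::write_json(x, file.path(out_dir, name), auto_unbox = TRUE,
                         pretty = TRUE, digits = NA)
  }

  for (a in config$analyses) {
    .log_line(log_con, "analysis: ", a)
    res <- switch(a,
      expression_heatmaps = {
        m <- build_scaled_body_matrix(tracks$hmc, genes)
        key <- expr[, sample1]
        names(key) <- rownames(expr)
        m <- order_rows(m, key)
        write_profile_matrix(m, file.path(out_dir,
                                          "expression_heatmap.tsv"))
        tiers <- expression_tiers(expr, sample1)
        metas <- lapply(levels(tiers), function(tl) {
          ids <- names(tiers)[tiers == tl]
          if (length(base::intersect(ids, rownames(m$values))) == 0L)
            return(NULL)
          mp <- mean_profile(m, ids)
          write_meta_profile(mp, file.path(
            out_dir, paste0("metaprofile_tier_", tl, ".tsv")))
          mp
        })
        names(metas) <- levels(tiers)
        dens <- genebody_density(tracks$hmc, genes)
        tsv(data.frame(gene_id = names(dens),
                       rpkm = expr[names(dens), sample1],
                       hmc_body_density = unname(dens)),
            "genebody_density.tsv")
        list(matrix = m, tier_profiles = metas, density = dens)
      },
      element_densities = {
        prom <- promoter_window(genes, 1000L, 1000L, sizes)
        cls <- chromatin_class(genes, peaks$k4, peaks$k27)
        fams <- list()
        rows <- list()
        for (cl in levels(cls)) {
          el <- prom[cls == cl]
          if (length(el) == 0L) next
          d <- element_density(peaks$hmc, el)
          rows[[cl]] <- data.frame(class = cl, n = length(el),
                                   total_bp = d$total_bp,
                                   covered_bp = d$covered_bp,
                                   density = d$density)
        }
        pres <- names(rows)
        pr <- list()
        if (length(pres) >= 2L) {
          combs <- utils::combn(pres, 2L)
          for (j in seq_len(ncol(combs))) {
            a1 <- combs[1L, j]; a2 <- combs[2L, j]
            t <- enrichment_test(peaks$hmc, prom[cls == a1],
                                 prom[cls == a2],
                                 n_perm = config$n_perm,
                                 seed = config$seed + j)
            pr[[j]] <- data.frame(class_A = a1, class_B = a2,
                                  delta = t$delta, p = t$p,
                                  method = t$method)
          }
        }
        dens_df <- do.call(rbind, rows)
        pairs_df <- if (length(pr)) do.call(rbind, pr) else NULL
        if (!is.null(pairs_df))
          pairs_df$p_adj <- stats::p.adjust(pairs_df$p, "BH")
        tsv(dens_df, "element_density.tsv")
        if (!is.null(pairs_df)) tsv(pairs_df, "element_density_tests.tsv")
        list(densities = dens_df, tests = pairs_df)
      },
      mark_correlation = {
        prom <- promoter_window(genes, 1000L, 1000L, sizes)
        marks <- c(tracks, peaks[setdiff(names(peaks), names(tracks))])
        cm <- signal_correlation(marks, prom)
        tsv(data.frame(mark = rownames(cm), cm, check.names = FALSE),
            "mark_correlation.tsv")
        cm
      },
      k27_ordered_profiles = {
        m <- build_tss_matrix(tracks$hmc, genes, config$flank,
                              config$bin_width)
        prom <- promoter_window(genes, 1000L, 1000L, sizes)
        k27_prom <- vapply(seq_along(prom), function(i)
          mean(track_values(tracks$k27,
                            as.character(GenomicRanges::seqnames(prom))[i],
                            GenomicRanges::start(prom)[i],
                            GenomicRanges::end(prom)[i])), 0)
        names(k27_prom) <- S4Vectors::mcols(genes)$gene_id
        m <- order_rows(m, k27_prom)
        write_profile_matrix(m, file.path(out_dir,
                                          "k27_ordered_heatmap.tsv"))
        pos <- names(k27_prom)[k27_prom > stats::median(k27_prom)]
        neg <- setdiff(names(k27_prom), pos)
        mp_pos <- mean_profile(m, pos)
        mp_neg <- mean_profile(m, neg)
        write_meta_profile(mp_pos, file.path(out_dir,
                                             "metaprofile_k27pos.tsv"))
        write_meta_profile(mp_neg, file.path(out_dir,
                                             "metaprofile_k27neg.tsv"))
        list(matrix = m, k27_level = k27_prom, k27_pos = mp_pos,
             k27_neg = mp_neg)
      },
      peak_overlap = {
        combos <- expand.grid(A = names(peaks), B = names(peaks),
                              stringsAsFactors = FALSE)
        combos <- combos[combos$A != combos$B, ]
        ov <- lapply(seq_len(nrow(combos)), function(j) {
          o <- overlap_fraction(peaks[[combos$A[j]]],
                                peaks[[combos$B[j]]],
                                combos$A[j], combos$B[j])
          data.frame(A = o$label_A, B = o$label_B, n_A = o$n_A,
                     n_A_hit = o$n_A_hit, fraction = o$fraction)
        })
        df <- do.call(rbind, ov)
        tsv(df, "peak_overlap.tsv")
        df
      },
      profile_clustering = {
        m <- build_tss_matrix(tracks$tet1, genes, config$flank,
                              config$bin_width)
        cl <- suppressWarnings(
          cluster_profiles(m, config$k, seed = config$seed))
        stab <- suppressWarnings(
          cluster_stability(m, config$k, config$n_realizations,
                            base_seed = config$seed))
        tsv(data.frame(gene_id = names(cl$assignment),
                       cluster = unname(cl$assignment)),
            "cluster_assignment.tsv")
        tsv(data.frame(axis = cl$axis, t(cl$centroids)),
            "cluster_centroids.tsv")
        json(list(k = cl$k, within_cor = cl$within_cor,
                  n_realizations = stab$n_realizations,
                  mean_ari = stab$mean_ari, seed = config$seed),
             "cluster_stability.json")
        list(clusters = cl, stability = stab)
      },
      bimodal_decomposition = {
        m <- build_tss_matrix(tracks$tet1, genes, 5000L, config$bin_width)
        prom <- promoter_window(genes, 1000L, 1000L, sizes)
        k27_prom <- GenomicRanges::countOverlaps(
          prom, peaks$k27, ignore.strand = TRUE) > 0L
        ids <- S4Vectors::mcols(genes)$gene_id[k27_prom]
        mp <- mean_profile(m, ids)
        write_meta_profile(mp, file.path(out_dir,
                                         "metaprofile_k27pos_tet1.tsv"))
        fit <- fit_two_gaussians(mp)
        json(c(coef(fit), rss = fit$rss, converged = fit$converged,
               n_genes = mp$n_genes), "bimodal_fit.json")
        fit
      },
      differential_profiles = {
        mA <- build_tss_matrix(tracks$hmc, genes, config$flank,
                               config$bin_width)
        mB <- build_tss_matrix(tracks$hmc_kd, genes, config$flank,
                               config$bin_width)
        prom <- promoter_window(genes, 1000L, 1000L, sizes)
        k27_prom <- GenomicRanges::countOverlaps(
          prom, peaks$k27, ignore.strand = TRUE) > 0L
        ids <- S4Vectors::mcols(genes)$gene_id[k27_prom]
        d <- compare_profiles(mA, mB, subset = ids,
                              n_perm = config$n_perm,
                              seed = config$seed)
        tsv(d, "differential_metaprofile.tsv")
        d
      })
    results[[a]] <- res
  }
  manifest <- list(
    analyses = config$analyses,
    parameters = list(flank = config$flank, bin_width = config$bin_width,
                      k = config$k,
                      n_realizations = config$n_realizations,
                      n_perm = config$n_perm, seed = config$seed,
                      expression_sample = sample1),
    multiple_testing = "Benjamini-Hochberg within each analysis family",
    significance = "seeded label-permutation tests",
    inputs = config$inputs)
  json(manifest, "manifest.json")
  .log_line(log_con, "done: ", length(results), " analyses")
  invisible(results)
}
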