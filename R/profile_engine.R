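## Profile matrices: genes x position-bin signal around an anchor, plus the
## column-average metaprofile.  Row signal is mean per-bp so bins of unequal
## width (fixed-bp flanks vs scaled body bins) stay comparable.

new_profile_matrix <- function(values, axis, anchor, flank, bin_width,
                               clipped = rep(FALSE, nrow(values))) {
  stopifnot(ncol(values) == length(axis), all(diff(axis) > 0))
  structure(list(values = values, axis = axis, anchor = anchor,
                 flank = flank, bin_width = bin_width, clipped = clipped),
            class = "profile_matrix")
}

#' @export
print.profile_matrix <- function(x, ...) {
  cat(sprintf("profile_matrix: %d genes x %d bins, anchor=%s, flank=%d bp\n",
              nrow(x$values), ncol(x$values), x$anchor, x$flank))
  invisible(x)
}

#' @export
dim.profile_matrix <- function(x) dim(x$values)

# per-bp window of a track, oriented 5'->3' for the gene
.oriented_window <- function(track, chrom, tss, flank, minus) {
  if (minus) v <- rev(track_values(track, chrom, tss - flank + 1L,
                                   tss + flank))
  else v <- track_values(track, chrom, tss - flank, tss + flank - 1L)
  v
}

#' TSS-anchored profile matrix
#'
#' Row `g`, bin `j` holds the mean per-bp signal of gene `g` in the `j`-th
#' `bin_width`-bp window of `[-flank, +flank)` around its TSS.  Minus-strand
#' rows are reversed so the axis always runs 5' to 3'; the axis records bin
#' centres in bp relative to the TSS.  Bins extending off the chromosome
#' contribute 0 and the row is flagged in `$clipped`.
#'
#' @param track A `signal_track`.
#' @param genes Gene models (`GRanges` with `gene_id` and `tss`).
#' @param flank Half-window in bp; must be divisible by `bin_width`.
#' @param bin_width Bin width in bp.
#' @return A `profile_matrix` (anchor `"tss"`).
#' @export
build_tss_matrix <- function(track, genes, flank = 5000L, bin_width = 50L) {
  if (length(genes) == 0L) stop("empty gene list", call. = FALSE)
  stopifnot(flank %% bin_width == 0L)
  nb <- 2L * flank %/% bin_width
  tss <- gene_tss(genes)
  chrom <- as.character(GenomicRanges::seqnames(genes))
  minus <- as.character(GenomicRanges::strand(genes)) == "-"
  vals <- matrix(0, length(genes), nb)
  clipped <- logical(length(genes))
  for (i in seq_along(genes)) {
    L <- track$seqlengths[chrom[i]]
    if (!is.na(L) &&
        (tss[i] - flank < 0L || tss[i] + flank > L)) clipped[i] <- TRUE
    v <- .oriented_window(track, chrom[i], tss[i], flank, minus[i])
    vals[i, ] <- colMeans(matrix(v, nrow = bin_width))
  }
  rownames(vals) <- S4Vectors::mcols(genes)$gene_id
  axis <- seq(-flank + bin_width / 2, flank - bin_width / 2, by = bin_width)
  new_profile_matrix(vals, axis, "tss", flank, bin_width, clipped)
}

# mean of per-bp vector x over n equal fractional bins (fractional-overlap
# weighting for bins not aligned to bp boundaries)
.frac_bin_means <- function(x, n) {
  L <- length(x)
  cs <- c(0, cumsum(x))
  integral <- function(t) {          # integral of piecewise-constant x on [0,t)
    k <- floor(t)
    v <- cs[k + 1L]
    fr <- t - k
    v + ifelse(fr > 0 & k < L, x[pmin(k + 1L, L)] * fr, 0)
  }
  edges <- seq(0, L, length.out = n + 1L)
  diff(integral(edges)) / (L / n)
}

#' Scaled gene-body profile matrix
#'
#' Each gene body (TSS to TES) is rescaled to `n_body_bins` equal fractions
#' (fractional-overlap weighting, so genes shorter than `n_body_bins` bp are
#' still usable and flagged); flanks are fixed-bp bins of `flank_bin_width`.
#' The axis places upstream flank bin centres at negative bp, body bins at
#' permille of gene length in (0, 1000), and downstream flank centres beyond
#' 1000.
#'
#' @param track A `signal_track`.
#' @param genes Gene models.
#' @param flank Fixed flank in bp on each side.
#' @param n_body_bins Number of scaled bins across the gene body.
#' @param flank_bin_width Bin width of the fixed flanks (divides `flank`).
#' @return A `profile_matrix` (anchor `"scaled-body"`).
#' @export
build_scaled_body_matrix <- function(track, genes, flank = 2000L,
                                     n_body_bins = 100L,
                                     flank_bin_width = 50L) {
  if (length(genes) == 0L) stop("empty gene list", call. = FALSE)
  stopifnot(flank %% flank_bin_width == 0L)
  nf <- flank %/% flank_bin_width
  nb <- 2L * nf + n_body_bins
  chrom <- as.character(GenomicRanges::seqnames(genes))
  minus <- as.character(GenomicRanges::strand(genes)) == "-"
  s <- GenomicRanges::start(genes)
  e <- GenomicRanges::end(genes)
  vals <- matrix(0, length(genes), nb)
  clipped <- logical(length(genes))
  for (i in seq_along(genes)) {
    v <- track_values(track, chrom[i], s[i] - flank, e[i] + flank)
    if (minus[i]) v <- rev(v)
    gl <- e[i] - s[i] + 1L
    clipped[i] <- gl < n_body_bins
    up <- v[seq_len(flank)]
    body <- v[flank + seq_len(gl)]
    down <- v[flank + gl + seq_len(flank)]
    vals[i, ] <- c(colMeans(matrix(up, nrow = flank_bin_width)),
                   .frac_bin_means(body, n_body_bins),
                   colMeans(matrix(down, nrow = flank_bin_width)))
  }
  rownames(vals) <- S4Vectors::mcols(genes)$gene_id
  axis <- c(seq(-flank + flank_bin_width / 2, -flank_bin_width / 2,
                by = flank_bin_width),
            (seq_len(n_body_bins) - 0.5) / n_body_bins * 1000,
            1000 + seq(flank_bin_width / 2, flank - flank_bin_width / 2,
                       by = flank_bin_width))
  new_profile_matrix(vals, axis, "scaled-body", flank, flank_bin_width,
                     clipped)
}

#' Metaprofile: per-bin mean over a gene subset
#'
#' @param matrix A `profile_matrix`.
#' @param subset Character vector of gene ids, or `NULL` for all rows.
#' @return A `meta_profile`: list with `axis`, `mean` and `n_genes`.
#' @export
mean_profile <- function(matrix, subset = NULL) {
  rows <- rownames(matrix$values)
  if (!is.null(subset)) {
    rows <- base::intersect(rows, subset)
    if (length(rows) == 0L)
      stop("subset shares no genes with the matrix", call. = FALSE)
  }
  m <- matrix$values[rows, , drop = FALSE]
  structure(list(axis = matrix$axis, mean = colMeans(m),
                 n_genes = length(rows), anchor = matrix$anchor,
                 bin_width = matrix$bin_width),
            class = "meta_profile")
}

#' @export
print.meta_profile <- function(x, ...) {
  cat(sprintf("meta_profile: %d bins (%s anchor), n_genes=%d, peak=%.4g at %g\n",
              length(x$axis), x$anchor, x$n_genes, max(x$mean),
              x$axis[which.max(x$mean)]))
  invisible(x)
}

#' @export
plot.meta_profile <- function(x, ...) {
  graphics::plot(x$axis, x$mean, type = "l",
                 xlab = "position relative to anchor (bp)",
                 ylab = "mean signal", ...)
  invisible(x)
}

#' Gene-body signal density
#'
#' Total signal over the gene span (TSS to TES) divided by gene length in bp.
#'
#' @param track A `signal_track`.
#' @param genes Gene models.
#' @return Named numeric vector, signal per bp, one value per gene.
#' @export
genebody_density <- function(track, genes) {
  chrom <- as.character(GenomicRanges::seqnames(genes))
  out <- vapply(seq_along(genes), function(i) {
    v <- track_values(track, chrom[i], GenomicRanges::start(genes)[i],
                      GenomicRanges::end(genes)[i])
    sum(v) / length(v)
  }, 0)
  names(out) <- S4Vectors::mcols(genes)$gene_id
  out
}

#' Reorder profile-matrix rows by a per-gene key
#'
#' Stable sort; genes missing from `key` get 0 (with a warning); ties are
#' broken by gene id so that orderings are reproducible.
#'
#' @param matrix A `profile_matrix`.
#' @param key Named numeric vector (gene id -> ordering value).
#' @param descending Sort high to low?
#' @return The reordered `profile_matrix`.
#' @export
order_rows <- function(matrix, key, descending = TRUE) {
  ids <- rownames(matrix$values)
  k <- key[ids]
  if (anyNA(k)) {
    warning(sum(is.na(k)), " genes missing from ordering key; using 0",
            call. = FALSE)
    k[is.na(k)] <- 0
  }
  o <- order(if (descending) -k else k, ids)
  matrix$values <- matrix$values[o, , drop = FALSE]
  matrix$clipped <- matrix$clipped[o]
  matrix
}

#' Differential metaprofile between two conditions
#'
#' Both matrices must share axis and gene universe (the same genes measured
#' under two conditions).  The per-bin difference of metaprofiles is tested
#' by a paired label-swap permutation: for each gene the condition labels of
#' its two rows are exchanged at random (equivalently the per-gene row
#' difference is sign-flipped), and the two-sided p-value per bin is
#' `(b + 1) / (n_perm + 1)` where `b` counts permuted mean differences at
#' least as extreme as the observed one.
#'
#' @param matrixA,matrixB `profile_matrix` objects on identical axes.
#' @param subset Optional gene-id subset.
#' @param n_perm Number of label-swap permutations.
#' @param seed Integer seed.
#' @return A data.frame with `axis`, `meanA`, `meanB`, `diff`, `p` and
#'   BH-adjusted `p_adj`.
#' @export
compare_profiles <- function(matrixA, matrixB, subset = NULL,
                             n_perm = 1000L, seed = 1L) {
  if (length(matrixA$axis) != length(matrixB$axis) ||
      any(matrixA$axis != matrixB$axis))
    stop("profile matrices have different axes", call. = FALSE)
  ids <- rownames(matrixA$values)
  if (!setequal(ids, rownames(matrixB$values)))
    stop("profile matrices have different gene universes", call. = FALSE)
  if (!is.null(subset)) ids <- base::intersect(ids, subset)
  if (length(ids) == 0L) stop("empty gene subset", call. = FALSE)
  A <- matrixA$values[ids, , drop = FALSE]
  B <- matrixB$values[ids, , drop = FALSE]
  D <- A - B
  n <- nrow(D)
  d_obs <- colMeans(D)
  set.seed(seed)
  signs <- matrix(sample(c(-1, 1), n_perm * n, replace = TRUE), n_perm, n)
  perm <- (signs %*% D) / n
  b <- colSums(abs(perm) >= matrix(abs(d_obs), n_perm, ncol(D),
                                   byrow = TRUE))
  p <- (b + 1) / (n_perm + 1)
  data.frame(axis = matrixA$axis, meanA = colMeans(A), meanB = colMeans(B),
             diff = d_obs, p = p, p_adj = stats::p.adjust(p, "BH"))
}

#' Write / read a profile matrix as TSV
#'
#' The first row stores the axis (column names `bin_<centre>`), the first
#' column the gene ids.
#' @param matrix A `profile_matrix`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_profile_matrix <- function(matrix, path) {
  df <- data.frame(gene_id = rownames(matrix$values),
                   matrix$values, check.names = FALSE)
  colnames(df)[-1L] <- paste0("bin_", matrix$axis)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_profile_matrix
#' @param anchor,flank,bin_width Metadata not stored in the TSV.
#' @export
read_profile_matrix <- function(path, anchor = "tss", flank = NA_integer_,
                                bin_width = NA_integer_) {
  df <- utils::read.table(path, sep = "\t", header = TRUE,
                          check.names = FALSE)
  vals <- as.matrix(df[, -1L, drop = FALSE])
  rownames(vals) <- df[[1L]]
  axis <- as.numeric(sub("^bin_", "", colnames(vals)))
  colnames(vals) <- NULL
  if (is.na(bin_width) && length(axis) > 1L) bin_width <- diff(axis)[1L]
  if (is.na(flank)) flank <- -axis[1L] + bin_width / 2
  new_profile_matrix(vals, axis, anchor, as.integer(round(flank)),
                     bin_width)
}

#' @rdname write_profile_matrix
#' @param profile A `meta_profile`.
#' @export
write_meta_profile <- function(profile, path) {
  utils::write.table(
    data.frame(axis = profile$axis, mean = profile$mean,
               n_genes = profile$n_genes),
    path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
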