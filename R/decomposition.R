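## The two bespoke numeric procedures: k-means over per-gene binding
## profiles with 1 - Pearson correlation as the distance, with multi-seed
## stability scored by the adjusted Rand index; and least-squares
## decomposition of an aggregate binding profile into a superposition of two
## non-normalized Gaussians (six parameters: two means, two widths, one
## relative weight, one overall amplitude).

# center each row and scale to unit L2 norm; rows must have nonzero variance
.row_standardize <- function(X) {
  Xc <- X - rowMeans(X)
  nr <- sqrt(rowSums(Xc^2))
  Xc / nr
}

#' Correlation-distance k-means over binding profiles
#'
#' Lloyd iterations with distance `d(a, b) = 1 - cor(a, b)` (Pearson).
#' Internally every row is centred and scaled to unit norm, under which the
#' procedure is spherical k-means: the per-cluster mean direction minimizes
#' the summed correlation distance, so the objective is non-increasing at
#' every iteration and the run is deterministic given the seed.  Rows with
#' zero variance have no defined correlation and are excluded up front with
#' a warning; an emptied cluster is re-seeded from the point farthest from
#' its centroid.
#'
#' @param matrix A `profile_matrix`.
#' @param k Number of clusters (>= 1).
#' @param seed Integer seed (initial centroids are `k` distinct rows).
#' @param max_iter Iteration cap.
#' @return A `profile_clusters` object: `assignment` (named integer),
#'   `centroids` (k x bins matrix of per-bin means of member rows, on the
#'   matrix axis), `within_cor` (mean correlation of members to their
#'   centroid), `objective_trace`, `iterations`, `seed`, `axis`, `excluded`.
#' @export
cluster_profiles <- function(matrix, k = 2L, seed = 1L, max_iter = 300L) {
  X <- matrix$values
  sds <- apply(X, 1L, stats::sd)
  excluded <- rownames(X)[sds == 0 | is.na(sds)]
  if (length(excluded)) {
    warning(length(excluded),
            " zero-variance rows excluded from clustering", call. = FALSE)
    X <- X[sds > 0 & !is.na(sds), , drop = FALSE]
  }
  if (nrow(X) < k)
    stop("fewer rows with nonzero variance (", nrow(X), ") than k = ", k,
         call. = FALSE)
  Z <- .row_standardize(X)
  n <- nrow(Z)
  set.seed(seed)
  centers <- Z[sample.int(n, k), , drop = FALSE]
  assign_old <- rep(0L, n)
  trace <- numeric(0)
  for (it in seq_len(max_iter)) {
    # cosine similarity of unit rows to (renormalized) centroid directions
    cn <- centers / sqrt(rowSums(centers^2))
    sim <- Z %*% t(cn)                     # n x k, equals Pearson r
    assign <- max.col(sim, ties.method = "first")
    for (j in seq_len(k)) {
      if (!any(assign == j)) {             # re-seed from the farthest point
        worst <- which.min(sim[cbind(seq_len(n), assign)])
        assign[worst] <- j
      }
    }
    trace <- c(trace, sum(1 - sim[cbind(seq_len(n), assign)]))
    if (identical(assign, assign_old)) break
    assign_old <- assign
    centers <- do.call(rbind, lapply(seq_len(k), function(j)
      colMeans(Z[assign == j, , drop = FALSE])))
  }
  names(assign) <- rownames(X)
  centroids <- do.call(rbind, lapply(seq_len(k), function(j)
    colMeans(X[assign == j, , drop = FALSE])))
  cz <- .row_standardize(centroids)
  within <- vapply(seq_len(k), function(j)
    mean(Z[assign == j, , drop = FALSE] %*% cz[j, ]), 0)
  structure(list(k = k, assignment = assign, centroids = centroids,
                 within_cor = within, objective_trace = trace,
                 iterations = it, seed = seed, axis = matrix$axis,
                 excluded = excluded),
            class = "profile_clusters")
}

#' @export
print.profile_clusters <- function(x, ...) {
  cat(sprintf("profile_clusters: k=%d, n=%d genes, %d iterations (seed %d)\n",
              x$k, length(x$assignment), x$iterations, x$seed))
  tab <- table(x$assignment)
  for (j in seq_len(x$k))
    cat(sprintf("  cluster %d: %d genes, within-cluster mean r = %.3f\n",
                j, tab[[as.character(j)]], x$within_cor[j]))
  invisible(x)
}

#' Clustering stability over repeated seeded realizations
#'
#' Runs [cluster_profiles()] `n_realizations` times with consecutive seeds
#' and scores every pair of runs with the adjusted Rand index (ARI), which
#' is invariant to the arbitrary k-means labelling.
#'
#' @param matrix A `profile_matrix`.
#' @param k Number of clusters.
#' @param n_realizations Number of runs (>= 2; the original analysis of
#'   this design used 100).
#' @param base_seed Seeds are `base_seed, base_seed + 1, ...`.
#' @return List with `n_realizations`, `ari` (pairwise agreement matrix,
#'   unit diagonal), `mean_ari` (mean over distinct pairs) and
#'   `assignments` (genes x realizations matrix).
#' @export
cluster_stability <- function(matrix, k = 2L, n_realizations = 100L,
                              base_seed = 1L) {
  stopifnot(n_realizations >= 2L)
  runs <- lapply(seq_len(n_realizations) - 1L, function(i)
    suppressWarnings(cluster_profiles(matrix, k, seed = base_seed + i)))
  A <- do.call(cbind, lapply(runs, `[[`, "assignment"))
  m <- diag(1, n_realizations)
  for (i in seq_len(n_realizations - 1L))
    for (j in (i + 1L):n_realizations)
      m[i, j] <- m[j, i] <- mclust::adjustedRandIndex(A[, i], A[, j])
  list(n_realizations = n_realizations, ari = m,
       mean_ari = mean(m[upper.tri(m)]), assignments = A)
}

## ---------------------------------------------------------------------------
## Two-Gaussian decomposition
## ---------------------------------------------------------------------------

#' Evaluate the six-parameter two-Gaussian model
#'
#' `A * (w * exp(-(x - mu1)^2 / (2 sigma1^2)) +
#'   (1 - w) * exp(-(x - mu2)^2 / (2 sigma2^2)))`
#'
#' @param x Positions (bp relative to the anchor).
#' @param mu1,sigma1 Centre and width of the first component.
#' @param mu2,sigma2 Centre and width of the second component.
#' @param w Relative weight of the first component, in (0, 1).
#' @param A Overall amplitude (> 0).
#' @return Model values at `x`.
#' @export
bimodal_model <- function(x, mu1, sigma1, mu2, sigma2, w, A) {
  A * (w * exp(-(x - mu1)^2 / (2 * sigma1^2)) +
         (1 - w) * exp(-(x - mu2)^2 / (2 * sigma2^2)))
}

# candidate means: the two highest local maxima at least ~3 bins apart,
# else quartiles
.profile_peaks <- function(x, y) {
  n <- length(y)
  loc <- which(diff(sign(diff(y))) < 0) + 1L
  loc <- loc[order(y[loc], decreasing = TRUE)]
  sep <- 3 * (max(x) - min(x)) / max(length(x) - 1, 1)
  picks <- numeric(0)
  for (i in loc) {
    if (all(abs(x[i] - picks) > sep)) picks <- c(picks, x[i])
    if (length(picks) == 2L) break
  }
  if (length(picks) < 2L)
    picks <- c(picks, stats::quantile(x, c(0.25, 0.75),
                                      names = FALSE))[1:2]
  sort(picks)
}

#' Fit a superposition of two non-normalized Gaussians to a metaprofile
#'
#' Least-squares minimization of the residual sum of squares between the
#' profile and [bimodal_model()].  Starting points come from a
#' variable-projection grid: over candidate centre pairs (local maxima,
#' axis quartiles, the profile's weighted mean) and candidate widths
#' (0.01x to 0.2x the axis span), the two component amplitudes are solved
#' in closed form by linear least squares; the best grid points seed a
#' bounded Levenberg-Marquardt refinement ([minpack.lm::nlsLM]) and the
#' lowest-RSS solution wins.  Widths are bounded below at half the bin
#' width to prevent collapse onto a single bin; components are reordered
#' afterwards so `mu1 <= mu2` (the model is symmetric under component swap
#' with `w <-> 1 - w`).
#'
#' @param profile A `meta_profile`, or a list/data.frame with `axis` and
#'   `mean` (at least 12 bins, not identically zero; small negative values
#'   from noise are tolerated with a warning).
#' @return A `bimodal_fit` object with components `mu1`, `sigma1`, `mu2`,
#'   `sigma2`, `w`, `A`, `rss`, `converged`, `profile` (the data), and
#'   `n_starts_ok`.  Methods: `print`, `coef`, `summary`, `predict`,
#'   `fitted`, `residuals`, `plot`.
#' @export
fit_two_gaussians <- function(profile) {
  x <- profile$axis
  y <- profile$mean
  if (length(x) < 12L) stop("need at least 12 bins to fit 6 parameters",
                            call. = FALSE)
  if (all(y == 0)) stop("profile is identically zero", call. = FALSE)
  if (max(y) <= 0) stop("profile has no positive signal", call. = FALSE)
  if (any(y < 0))
    warning("profile has negative values (noise); fitting anyway",
            call. = FALSE)
  span <- max(x) - min(x)
  bw <- if (length(x) > 1L) min(diff(x)) else 1
  peaks <- .profile_peaks(x, y)
  wmean <- sum(x * y) / sum(y)
  cand_mu <- sort(unique(round(c(
    peaks, stats::quantile(x, c(0.25, 0.75), names = FALSE), wmean))))
  cand_sig <- pmax(c(0.005, 0.015, 0.04, 0.1, 0.25) * span, bw / 2)

  # variable projection: for fixed centres/widths the two amplitudes are a
  # linear least-squares problem (clamped at 0); keep the best width combo
  # per centre pair so the seed list stays diverse in (mu1, mu2)
  grid <- list()
  for (m1 in cand_mu) for (m2 in cand_mu) {
    if (m2 < m1) next
    pair_best <- NULL
    for (s1 in cand_sig) for (s2 in cand_sig) {
      g1 <- exp(-(x - m1)^2 / (2 * s1^2))
      g2 <- exp(-(x - m2)^2 / (2 * s2^2))
      a <- tryCatch(stats::coef(stats::lm.fit(cbind(g1, g2), y)),
                    error = function(e) c(NA, NA))
      if (anyNA(a)) next
      a <- pmax(a, 1e-9 * max(y))
      rss <- sum((y - a[1L] * g1 - a[2L] * g2)^2)
      if (is.null(pair_best) || rss < pair_best[7L])
        pair_best <- c(m1, s1, m2, s2, a[1L], a[2L], rss)
    }
    if (!is.null(pair_best)) grid[[length(grid) + 1L]] <- pair_best
  }
  gm <- do.call(rbind, grid)
  gm <- gm[order(gm[, 7L]), , drop = FALSE]
  n_seed <- nrow(gm)          # refine from every centre pair (few dozen)

  lower <- c(mu1 = min(x) - span, sigma1 = bw / 2,
             mu2 = min(x) - span, sigma2 = bw / 2, w = 1e-3, A = 1e-12)
  upper <- c(mu1 = max(x) + span, sigma1 = 5 * span,
             mu2 = max(x) + span, sigma2 = 5 * span, w = 1 - 1e-3, A = Inf)
  resid_fn <- function(p)
    y - bimodal_model(x, p[1L], p[2L], p[3L], p[4L], p[5L], p[6L])
  best <- NULL
  n_ok <- 0L
  for (i in seq_len(n_seed)) {
    a1 <- gm[i, 5L]; a2 <- gm[i, 6L]
    A0 <- a1 + a2
    p0 <- c(mu1 = gm[i, 1L], sigma1 = gm[i, 2L], mu2 = gm[i, 3L],
            sigma2 = gm[i, 4L],
            w = min(max(a1 / A0, 2e-3), 1 - 2e-3), A = A0)
    fit <- tryCatch(
      minpack.lm::nls.lm(
        par = p0, lower = unname(lower), upper = unname(upper),
        fn = resid_fn,
        control = minpack.lm::nls.lm.control(maxiter = 500,
                                             ftol = 1e-12, ptol = 1e-12)),
      error = function(e) NULL)
    if (is.null(fit)) next
    n_ok <- n_ok + 1L
    rss <- sum(fit$fvec^2)
    if (is.null(best) || rss < best$rss)
      best <- list(rss = rss, fit = fit,
                   converged = fit$info %in% 1:3)
  }
  if (is.null(best))
    stop("two-Gaussian fit failed from every starting point", call. = FALSE)
  p <- as.list(best$fit$par)
  if (p$mu1 > p$mu2)       # component swap symmetry
    p <- list(mu1 = p$mu2, sigma1 = p$sigma2, mu2 = p$mu1,
              sigma2 = p$sigma1, w = 1 - p$w, A = p$A)
  structure(list(mu1 = p$mu1, sigma1 = p$sigma1, mu2 = p$mu2,
                 sigma2 = p$sigma2, w = p$w, A = p$A, rss = best$rss,
                 converged = isTRUE(best$converged),
                 n_starts_ok = n_ok,
                 profile = list(axis = x, mean = y)),
            class = "bimodal_fit")
}

#' Evaluate a fitted two-Gaussian model at positions
#' @param fit A `bimodal_fit`.
#' @param x Positions in bp.
#' @return Model values.
#' @export
evaluate_bimodal <- function(fit, x) {
  bimodal_model(x, fit$mu1, fit$sigma1, fit$mu2, fit$sigma2, fit$w, fit$A)
}

#' @export
coef.bimodal_fit <- function(object, ...) {
  c(mu1 = object$mu1, sigma1 = object$sigma1, mu2 = object$mu2,
    sigma2 = object$sigma2, w = object$w, A = object$A)
}

#' @export
print.bimodal_fit <- function(x, ...) {
  cat("Two-Gaussian decomposition (non-normalized components)\n")
  cat(sprintf("  component 1: centre %+.1f bp, width (sigma) %.1f bp, weight %.3f\n",
              x$mu1, x$sigma1, x$w))
  cat(sprintf("  component 2: centre %+.1f bp, width (sigma) %.1f bp, weight %.3f\n",
              x$mu2, x$sigma2, 1 - x$w))
  cat(sprintf("  amplitude %.4g, RSS %.4g, converged: %s\n",
              x$A, x$rss, x$converged))
  invisible(x)
}

#' @export
summary.bimodal_fit <- function(object, ...) {
  tss_y <- evaluate_bimodal(object, 0)
  out <- list(coef = coef.bimodal_fit(object), rss = object$rss,
              converged = object$converged,
              n_bins = length(object$profile$axis),
              r_squared = 1 - object$rss /
                sum((object$profile$mean - mean(object$profile$mean))^2),
              value_at_anchor = tss_y)
  class(out) <- "summary.bimodal_fit"
  out
}

#' @export
print.summary.bimodal_fit <- function(x, ...) {
  cat("Two-Gaussian decomposition\n\nCoefficients:\n")
  print(round(x$coef, 4))
  cat(sprintf("\nRSS: %.4g   R-squared: %.4f   bins: %d   converged: %s\n",
              x$rss, x$r_squared, x$n_bins, x$converged))
  invisible(x)
}

#' @export
predict.bimodal_fit <- function(object, newdata = NULL, ...) {
  x <- if (is.null(newdata)) object$profile$axis
       else if (is.list(newdata)) newdata$axis else newdata
  evaluate_bimodal(object, x)
}

#' @export
fitted.bimodal_fit <- function(object, ...) {
  evaluate_bimodal(object, object$profile$axis)
}

#' @export
residuals.bimodal_fit <- function(object, ...) {
  object$profile$mean - fitted.bimodal_fit(object)
}

#' @export
plot.bimodal_fit <- function(x, ...) {
  ax <- x$profile$axis
  graphics::plot(ax, x$profile$mean, type = "p", pch = 16, cex = 0.5,
                 xlab = "position relative to anchor (bp)",
                 ylab = "signal", ...)
  xs <- seq(min(ax), max(ax), length.out = 400)
  graphics::lines(xs, evaluate_bimodal(x, xs), col = "red")
  graphics::lines(xs, x$A * x$w * exp(-(xs - x$mu1)^2 / (2 * x$sigma1^2)),
                  col = "blue", lty = 2)
  graphics::lines(xs, x$A * (1 - x$w) *
                        exp(-(xs - x$mu2)^2 / (2 * x$sigma2^2)),
                  col = "darkgreen", lty = 2)
  invisible(x)
}
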