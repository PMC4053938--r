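# Correlation-distance k-means + stability, and the two-Gaussian fit.

pm_from <- function(vals, axis = NULL) {
  if (is.null(axis)) axis <- seq(-ncol(vals) / 2 + 0.5, by = 1,
                                 length.out = ncol(vals))
  rownames(vals) <- sprintf("g%04d", seq_len(nrow(vals)))
  bivalentscope:::new_profile_matrix(vals, axis, "tss",
                                     as.integer(ncol(vals) / 2), 1L)
}

planted_profiles <- function(n_per = 50L, noise = 0.05, seed = 1L) {
  set.seed(seed)
  x <- seq(-100, 100, by = 2)
  s1 <- exp(-x^2 / (2 * 15^2))
  s2 <- exp(-(x - 40)^2 / (2 * 40^2))
  vals <- rbind(
    t(replicate(n_per, s1 + rnorm(length(x), 0, noise))),
    t(replicate(n_per, s2 + rnorm(length(x), 0, noise))))
  list(matrix = pm_from(pmax(vals, 0), x),
       truth = rep(1:2, each = n_per))
}

test_that("degenerate clustering: identical rows collapse perfectly", {
  row <- sin(seq(0, 3, length.out = 30)) + 1
  m <- pm_from(matrix(rep(row, 10), 10, byrow = TRUE))
  cl <- cluster_profiles(m, k = 1L, seed = 5L)
  expect_equal(unname(cl$assignment), rep(1L, 10))
  expect_equal(cl$within_cor, 1, tolerance = 1e-12)
})

test_that("planted two-shape partition is recovered exactly", {
  pp <- planted_profiles()
  cl <- cluster_profiles(pp$matrix, k = 2L, seed = 3L)
  expect_equal(oracle_ari(cl$assignment, pp$truth), 1)
})

test_that("k-means objective is non-increasing and seeded-deterministic", {
  set.seed(77)
  m <- pm_from(matrix(rexp(80 * 40), 80, 40))
  for (s in 1:5) {
    cl <- cluster_profiles(m, k = 3L, seed = s)
    expect_true(all(diff(cl$objective_trace) <= 1e-9))
  }
  a <- cluster_profiles(m, k = 3L, seed = 11L)
  b <- cluster_profiles(m, k = 3L, seed = 11L)
  expect_identical(a$assignment, b$assignment)
  expect_equal(a$centroids, b$centroids)
})

test_that("zero-variance rows are excluded, small inputs rejected", {
  vals <- rbind(matrix(rexp(5 * 20), 5, 20), matrix(1, 3, 20))
  m <- pm_from(vals)
  expect_warning(cl <- cluster_profiles(m, k = 2L, seed = 1L),
                 "zero-variance")
  expect_length(cl$assignment, 5L)
  expect_length(cl$excluded, 3L)
  flat <- pm_from(matrix(1, 4, 20))
  expect_error(suppressWarnings(cluster_profiles(flat, k = 2L)),
               "fewer rows")
})

test_that("stability is 1 for separated shapes, low for pure noise, and
           the ARI agrees with the closed-form hand computation", {
  pp <- planted_profiles()
  st <- cluster_stability(pp$matrix, k = 2L, n_realizations = 10L,
                          base_seed = 5L)
  expect_equal(st$mean_ari, 1, tolerance = 1e-12)
  expect_equal(diag(st$ari), rep(1, 10L))

  set.seed(99)
  noise <- pm_from(matrix(rnorm(120 * 30), 120, 30))
  stn <- cluster_stability(noise, k = 2L, n_realizations = 10L,
                           base_seed = 2L)
  expect_lt(stn$mean_ari, 0.2)

  # hand-checkable partitions of 6 items
  p1 <- c(1, 1, 1, 2, 2, 2)
  p2 <- c(1, 1, 2, 2, 2, 2)
  expect_equal(mclust::adjustedRandIndex(p1, p2), oracle_ari(p1, p2),
               tolerance = 1e-12)
  expect_equal(oracle_ari(p1, p1), 1)
})

test_that("noise-free two-Gaussian profiles are recovered exactly", {
  x <- seq(-4975, 4975, by = 50)
  truth <- c(mu1 = -40, sigma1 = 80, mu2 = 450, sigma2 = 400, w = 0.4,
             A = 1)
  y <- bimodal_model(x, truth["mu1"], truth["sigma1"], truth["mu2"],
                     truth["sigma2"], truth["w"], truth["A"])
  fit <- fit_two_gaussians(list(axis = x, mean = y))
  expect_true(fit$converged)
  expect_lt(abs(fit$mu1 - truth[["mu1"]]), 1)
  expect_lt(abs(fit$mu2 - truth[["mu2"]]), 1)
  expect_true(all(abs(coef(fit) - truth) / abs(truth) < 1e-3))
})

test_that("single-component data does not fabricate a second mode", {
  x <- seq(-1975, 1975, by = 50)
  y <- 3 * exp(-x^2 / (2 * 300^2))
  fit <- fit_two_gaussians(list(axis = x, mean = y))
  single_rss <- sum((y - fit$A * exp(-(x - fit$mu1)^2 /
                                       (2 * fit$sigma1^2)))^2)
  expect_lte(fit$rss, single_rss + 1e-9)
  # either the second weight vanishes or the components coincide
  # the weight bound w <= 1 - 1e-3 leaves a vanishing second component
  expect_true(1 - fit$w < 0.05 || abs(fit$mu2 - fit$mu1) < fit$sigma1 / 2)
  expect_lt(max(abs(fitted(fit) - y)), 2e-3 * max(y))
})

test_that("means are recovered within half a bin under 10% noise", {
  x <- seq(-4975, 4975, by = 50)
  clean <- bimodal_model(x, -39, 80, 455, 400, 0.45, 10)
  peak <- max(clean)
  err1 <- err2 <- numeric(20)
  for (r in 1:20) {
    set.seed(400 + r)
    y <- clean + rnorm(length(x), 0, 0.1 * peak)
    f <- suppressWarnings(fit_two_gaussians(list(axis = x, mean = y)))
    err1[r] <- abs(f$mu1 + 39)
    err2[r] <- abs(f$mu2 - 455)
  }
  expect_lt(mean(err1), 30)
  expect_lt(mean(err2), 30)
})

test_that("fit is scale-invariant and shift-equivariant; model evaluates
           to hand arithmetic", {
  x <- seq(-2975, 2975, by = 50)
  y <- bimodal_model(x, -30, 100, 500, 350, 0.5, 2) +
    0.02 * cos(x / 300)^2           # mild deterministic perturbation
  y <- pmax(y, 0)
  f1 <- fit_two_gaussians(list(axis = x, mean = y))
  f5 <- fit_two_gaussians(list(axis = x, mean = 5 * y))
  expect_equal(f5$mu1, f1$mu1, tolerance = 1e-4)
  expect_equal(f5$sigma2, f1$sigma2, tolerance = 1e-4)
  expect_equal(f5$w, f1$w, tolerance = 1e-4)
  expect_equal(f5$A / f1$A, 5, tolerance = 1e-4)

  fs <- fit_two_gaussians(list(axis = x + 700, mean = y))
  expect_equal(fs$mu1 - f1$mu1, 700, tolerance = 1e-3)
  expect_equal(fs$mu2 - f1$mu2, 700, tolerance = 1e-3)

  # hand evaluation: A(w e^{-(x-mu1)^2/2s1^2} + (1-w) e^{-(x-mu2)^2/2s2^2})
  hand <- 2 * (0.3 * exp(-(120 - 50)^2 / (2 * 80^2)) +
                 0.7 * exp(-(120 - 400)^2 / (2 * 300^2)))
  expect_equal(bimodal_model(120, 50, 80, 400, 300, 0.3, 2), hand,
               tolerance = 1e-12)
  fit <- structure(list(mu1 = 50, sigma1 = 80, mu2 = 400, sigma2 = 300,
                        w = 0.3, A = 2), class = "bimodal_fit")
  expect_equal(evaluate_bimodal(fit, 120), hand, tolerance = 1e-12)
  expect_equal(evaluate_bimodal(fit, c(-1e7, 1e7)), c(0, 0))
  # peak value with w = 1 at x = mu1 equals A
  expect_equal(bimodal_model(50, 50, 80, 400, 300, 1, 2), 2)
})

test_that("degenerate profiles are rejected", {
  x <- seq(-500, 500, by = 100)
  expect_error(fit_two_gaussians(list(axis = x, mean = rep(0, 11))),
               "12 bins")
  x2 <- seq(-575, 575, by = 50)
  expect_error(fit_two_gaussians(list(axis = x2,
                                      mean = rep(0, length(x2)))),
               "identically zero")
  expect_error(fit_two_gaussians(list(axis = x2,
                                      mean = rep(-1, length(x2)))),
               "no positive signal")
  ysmall <- pmax(bimodal_model(x2, 0, 100, 400, 200, 0.5, 1), 0)
  ysmall[1L] <- -0.01
  expect_warning(fit_two_gaussians(list(axis = x2, mean = ysmall)),
                 "negative values")
})
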