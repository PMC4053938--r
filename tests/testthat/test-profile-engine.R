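# TSS-anchored and scaled-body profile matrices, metaprofiles, orderings
# and the paired differential test.

test_that("TSS matrices place signal in the correct strand-aware bin", {
  gm <- toy_genes(data.frame(chrom = "chr1", s0 = c(10000L, 30000L),
                             e0 = c(14000L, 34000L), id = c("gp", "gm"),
                             strand = c("+", "-")))
  zero <- toy_track(data.frame(chrom = "chr1", s0 = 0L, e0 = 1L,
                               value = 0))
  m0 <- suppressWarnings(build_tss_matrix(zero, gm, 1000L, 50L))
  expect_true(all(m0$values == 0))
  expect_equal(dim(m0), c(2L, 40L))
  expect_equal(m0$axis, -m0$axis[length(m0$axis):1])  # symmetric about 0

  # unit signal on [tss, tss+1) of the plus gene -> first bin right of 0
  tr <- toy_track(data.frame(chrom = "chr1", s0 = 10000L, e0 = 10001L,
                             value = 1))
  m <- build_tss_matrix(tr, gm, 1000L, 50L)
  hit <- which(m$values["gp", ] != 0)
  expect_equal(hit, 21L)
  expect_equal(m$axis[hit], 25)
  expect_equal(unname(m$values["gp", hit]), 1 / 50)           # mean per-bp

  # minus gene: signal 200 bp downstream of its TSS (tss0 = 33999, so at
  # 0-based 33799) must land at +200 on the shared axis
  trm <- toy_track(data.frame(chrom = "chr1", s0 = 33799L, e0 = 33800L,
                              value = 1))
  mm <- build_tss_matrix(trm, gm, 1000L, 50L)
  hit <- which(mm$values["gm", ] != 0)
  expect_equal(mm$axis[hit], 225)                      # bin covering +200
})

test_that("bin conservation holds at bin_width 1", {
  gm <- toy_genes(data.frame(chrom = "chr1", s0 = 10000L, e0 = 14000L,
                             id = "g", strand = "+"))
  set.seed(42)
  runs <- data.frame(chrom = "chr1", s0 = seq(9000L, 11980L, by = 20L),
                     value = round(runif(150), 3))
  runs$e0 <- runs$s0 + 20L
  tr <- toy_track(runs, seqlengths = c(chr1 = 20000L))
  m <- build_tss_matrix(tr, gm, 500L, 1L)
  expect_equal(sum(m$values),
               sum(track_values(tr, "chr1", 10001L - 500L, 10001L + 499L)),
               tolerance = 1e-12)
})

test_that("mirroring the genome leaves profile matrices unchanged", {
  fx <- small_fixture()
  L <- fx$cfg$chrom_length
  # mirrored track: position p -> L + 1 - p
  gr <- GenomicRanges::GRanges()
  tr <- fx$dat$tracks$tet1
  r <- tr$cov[[1L]]
  e <- cumsum(S4Vectors::runLength(r))
  s <- e - S4Vectors::runLength(r) + 1L
  v <- S4Vectors::runValue(r)
  keep <- v != 0
  mirror_runs <- GenomicRanges::GRanges(
    names(tr$cov)[1L],
    IRanges::IRanges(L + 1L - e[keep], L + 1L - s[keep]),
    score = v[keep])
  mtr <- signal_track(mirror_runs, seqlengths = fx$ann$seqlengths)
  g <- fx$ann$genes
  flip <- c("+" = "-", "-" = "+")
  rows <- sprintf("%s\t%d\t%d\t%s\t0\t%s\t%d\t%d\t0\t1\t%d,\t0,",
                  as.character(GenomicRanges::seqnames(g)),
                  L - GenomicRanges::end(g),
                  L - GenomicRanges::start(g) + 1L,
                  S4Vectors::mcols(g)$gene_id,
                  flip[as.character(GenomicRanges::strand(g))],
                  L - GenomicRanges::end(g),
                  L - GenomicRanges::start(g) + 1L,
                  GenomicRanges::width(g))
  mg <- read_gene_models(write_lines_tmp(rows, ".bed12"))
  m1 <- build_tss_matrix(tr, g, 2000L, 50L)
  m2 <- build_tss_matrix(mtr, mg, 2000L, 50L)
  expect_equal(m2$values[rownames(m1$values), ], m1$values,
               tolerance = 1e-12)
})

test_that("scaled-body matrices are invariant to gene length under uniform
           coverage and map localized signal to the right body bins", {
  gm <- toy_genes(data.frame(chrom = "chr1",
                             s0 = c(10000L, 40000L, 60000L),
                             e0 = c(14000L, 47777L, 60037L),
                             id = c("a", "b", "short"),
                             strand = c("+", "-", "+")))
  uni <- toy_track(data.frame(chrom = "chr1", s0 = 0L, e0 = 100000L,
                              value = 2.5))
  m <- build_scaled_body_matrix(uni, gm, flank = 2000L, n_body_bins = 100L)
  body <- 41:140
  expect_true(all(abs(m$values[, body] - 2.5) < 1e-9))
  expect_true(m$clipped[3L])                       # 37 bp < 100 bins

  # signal over the 5' half of gene "a" only
  half <- toy_track(data.frame(chrom = "chr1", s0 = 10000L, e0 = 12000L,
                               value = 4))
  mh <- build_scaled_body_matrix(half, gm[1L], flank = 2000L,
                                 n_body_bins = 100L)
  expect_true(all(abs(mh$values[1L, 41:90] - 4) < 1e-9))
  expect_true(all(mh$values[1L, 91:140] == 0))

  m0 <- build_scaled_body_matrix(
    toy_track(data.frame(chrom = "chr1", s0 = 0L, e0 = 1L, value = 0)),
    gm, flank = 2000L, n_body_bins = 100L)
  expect_true(all(m0$values == 0))
})

test_that("metaprofiles equal brute-force column means", {
  fx <- small_fixture()
  m <- build_tss_matrix(fx$dat$tracks$hmc, fx$ann$genes, 2000L, 50L)
  one <- mean_profile(m, rownames(m$values)[5L])
  expect_equal(one$mean, unname(m$values[5L, ]))
  two <- mean_profile(m, rownames(m$values)[1:2])
  expect_equal(two$mean, unname(colMeans(m$values[1:2, ])))
  all_mp <- mean_profile(m)
  brute <- apply(m$values, 2L, function(col) sum(col) / length(col))
  expect_equal(all_mp$mean, brute, tolerance = 1e-9)
  expect_error(mean_profile(m, "not-a-gene"), "no genes")
})

test_that("gene-body density matches hand-computed signal per bp", {
  gm <- toy_genes(data.frame(chrom = "chr1", s0 = 1000L, e0 = 2000L,
                             id = "g", strand = "+"))
  uni <- toy_track(data.frame(chrom = "chr1", s0 = 0L, e0 = 5000L,
                              value = 3.5))
  expect_equal(unname(genebody_density(uni, gm)), 3.5)
  runs <- data.frame(chrom = "chr1", s0 = c(1100L, 1500L, 1900L),
                     e0 = c(1200L, 1600L, 2100L), value = c(2, 5, 1))
  tr <- toy_track(runs, seqlengths = c(chr1 = 5000L))
  # only [1900,2000) of the last run is inside the gene
  expect_equal(unname(genebody_density(tr, gm)),
               (2 * 100 + 5 * 100 + 1 * 100) / 1000)
  zero <- toy_track(data.frame(chrom = "chr1", s0 = 0L, e0 = 1L,
                               value = 0))
  expect_equal(unname(suppressWarnings(genebody_density(zero, gm))), 0)
})

test_that("row ordering is stable, keyed and tie-broken by gene id", {
  fx <- small_fixture()
  m <- build_tss_matrix(fx$dat$tracks$hmc, fx$ann$genes[1:5], 1000L, 50L)
  key <- c(3, 1, 4, 1, 5)
  names(key) <- rownames(m$values)
  up <- order_rows(m, key, descending = FALSE)
  expect_equal(rownames(up$values),
               names(key)[order(key, names(key))])
  down <- order_rows(m, key, descending = TRUE)
  expect_equal(rownames(down$values),
               names(key)[order(-key, names(key))])
  # ties (genes 2 and 4) stay in gene-id order either way
  tied <- rownames(up$values)[1:2]
  expect_equal(tied, sort(names(key)[key == 1]))
  again <- order_rows(up, key, descending = FALSE)
  expect_equal(again$values, up$values)             # idempotent
  expect_warning(order_rows(m, key[-1L]), "missing")
})

test_that("paired differential test finds planted effects and not nulls", {
  mk <- function(vals, axis) {
    rownames(vals) <- sprintf("g%03d", seq_len(nrow(vals)))
    bivalentscope:::new_profile_matrix(vals, axis, "tss", 1000L, 50L)
  }
  axis <- seq(-975, 975, by = 50)
  set.seed(1)
  base <- matrix(rexp(200 * 40), 200, 40)
  A <- mk(base, axis)
  B_same <- mk(base, axis)
  d0 <- compare_profiles(A, B_same, n_perm = 200L, seed = 3L)
  expect_true(all(d0$diff == 0))
  expect_true(all(d0$p == 1))

  B_shift <- mk(base + 0.7, axis)
  ds <- compare_profiles(A, B_shift, n_perm = 200L, seed = 3L)
  expect_equal(ds$diff, rep(-0.7, 40), tolerance = 1e-12)

  # planted 2x reduction in the central 10 bins
  set.seed(2)
  B2 <- base + matrix(rnorm(200 * 40, 0, 0.05), 200, 40)
  centre <- 16:25
  B2[, centre] <- B2[, centre] / 2
  dp <- compare_profiles(A, mk(pmax(B2, 0), axis), n_perm = 999L,
                         seed = 4L)
  expect_true(all(dp$p[centre] < 0.01))
  expect_true(mean(dp$p[-centre] < 0.05) < 0.25)

  bad_axis <- mk(base, axis + 5)
  expect_error(compare_profiles(A, bad_axis), "axes")
})

test_that("differential p-values match exhaustive sign-flip enumeration", {
  axis <- seq(-175, 175, by = 50)
  set.seed(7)
  n <- 10L
  base <- matrix(rexp(n * 8), n, 8)
  eff <- base
  eff[, 4:5] <- eff[, 4:5] * 0.5
  mk <- function(vals) {
    rownames(vals) <- sprintf("g%02d", seq_len(n))
    bivalentscope:::new_profile_matrix(vals, axis, "tss", 200L, 50L)
  }
  D <- base - eff
  d_obs <- colMeans(D)
  # exhaustive enumeration over all 2^10 sign assignments
  signs <- as.matrix(expand.grid(rep(list(c(-1, 1)), n)))
  perm <- (signs %*% D) / n
  p_exact <- vapply(seq_len(8L), function(j)
    mean(abs(perm[, j]) >= abs(d_obs[j])), 0)
  res <- compare_profiles(mk(base), mk(eff), n_perm = 4000L, seed = 9L)
  expect_true(all(abs(res$p - p_exact) <
                    4 * sqrt(p_exact * (1 - p_exact) / 4000) + 2e-3))
})
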