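# Shared fixture builders and independent oracles.  Everything is generated
# in code; the default synthetic bundle is cached per test run.

.fixture_cache <- new.env(parent = emptyenv())

# default study-condition fixture (generated once per session)
default_fixture <- function() {
  if (is.null(.fixture_cache$default)) {
    cfg <- sim_config()
    ann <- generate_annotation(cfg)
    dat <- generate_tracks(ann, cfg)
    .fixture_cache$default <- list(cfg = cfg, ann = ann, dat = dat)
  }
  .fixture_cache$default
}

# small fixture for cheaper end-to-end tests
small_fixture <- function() {
  if (is.null(.fixture_cache$small)) {
    cfg <- sim_config(seed = 11L, n_genes = 120L)
    ann <- generate_annotation(cfg)
    dat <- generate_tracks(ann, cfg)
    .fixture_cache$small <- list(cfg = cfg, ann = ann, dat = dat)
  }
  .fixture_cache$small
}

write_lines_tmp <- function(lines, ext = ".txt") {
  f <- tempfile(fileext = ext)
  writeLines(lines, f)
  f
}

# toy gene models from a compact table: data.frame(chrom,s0,e0,id,strand)
toy_genes <- function(df) {
  rows <- sprintf("%s\t%d\t%d\t%s\t0\t%s\t%d\t%d\t0\t1\t%d,\t0,",
                  df$chrom, df$s0, df$e0, df$id, df$strand, df$s0, df$e0,
                  df$e0 - df$s0)
  read_gene_models(write_lines_tmp(rows, ".bed12"))
}

# toy track from runs: data.frame(chrom,s0,e0,value)
toy_track <- function(df, seqlengths = NULL) {
  rows <- sprintf("%s\t%d\t%d\t%s", df$chrom, df$s0, df$e0,
                  format(df$value, scientific = FALSE))
  read_signal(write_lines_tmp(rows, ".bedGraph"), seqlengths = seqlengths)
}

grange <- function(chrom, s0, e0) {
  GenomicRanges::GRanges(chrom, IRanges::IRanges(s0 + 1L, e0))
}

# random disjoint intervals on [0, span) (0-based half-open)
random_disjoint_intervals <- function(n, span = 10000L, max_w = 200L) {
  starts <- sort(sample.int(span - max_w, n))
  widths <- sample.int(max_w, n, replace = TRUE)
  ends <- pmin(starts + widths, c(starts[-1L], span))
  keep <- ends > starts
  grange("chrT", starts[keep], ends[keep])
}

# random (possibly overlapping) intervals
random_intervals <- function(n, span = 10000L, max_w = 300L) {
  starts <- sample.int(span - max_w, n, replace = TRUE)
  widths <- sample.int(max_w, n, replace = TRUE)
  grange("chrT", starts, starts + widths)
}

## ---- oracles --------------------------------------------------------------

# per-bp bitmap oracle for covered-fraction density
oracle_density_bitmap <- function(marks, elements, span = 20000L) {
  mark_bp <- logical(span)
  for (i in seq_along(marks))
    mark_bp[GenomicRanges::start(marks)[i]:GenomicRanges::end(marks)[i]] <-
      TRUE
  el_bp <- logical(span)
  for (i in seq_along(elements))
    el_bp[GenomicRanges::start(elements)[i]:GenomicRanges::end(elements)[i]] <-
      TRUE
  sum(mark_bp & el_bp) / sum(el_bp)
}

# O(n^2) all-pairs overlap oracle (1-based closed interval intersect)
oracle_overlap_fraction <- function(A, B) {
  hits <- 0L
  for (i in seq_along(A)) {
    ov <- FALSE
    for (j in seq_along(B)) {
      if (as.character(GenomicRanges::seqnames(A))[i] ==
            as.character(GenomicRanges::seqnames(B))[j] &&
          GenomicRanges::start(A)[i] <= GenomicRanges::end(B)[j] &&
          GenomicRanges::start(B)[j] <= GenomicRanges::end(A)[i])
        ov <- TRUE
    }
    hits <- hits + ov
  }
  hits / length(A)
}

# exhaustive reassignment oracle for the enrichment test (small pools)
oracle_enrichment_exact <- function(marks, elementsA, elementsB,
                                    span = 20000L) {
  pool <- c(elementsA, elementsB)
  nA <- length(elementsA)
  n <- length(pool)
  dens <- function(idx) oracle_density_bitmap(marks, pool[idx], span)
  d_obs <- dens(seq_len(nA)) - dens(setdiff(seq_len(n), seq_len(nA)))
  splits <- utils::combn(n, nA)
  deltas <- apply(splits, 2L, function(idx)
    dens(idx) - dens(setdiff(seq_len(n), idx)))
  mean(abs(deltas) >= abs(d_obs) - 1e-12)
}

# closed-form adjusted Rand index from the contingency table
oracle_ari <- function(a, b) {
  tab <- table(a, b)
  n <- sum(tab)
  sum_ij <- sum(choose(tab, 2))
  sum_a <- sum(choose(rowSums(tab), 2))
  sum_b <- sum(choose(colSums(tab), 2))
  expected <- sum_a * sum_b / choose(n, 2)
  (sum_ij - expected) / ((sum_a + sum_b) / 2 - expected)
}

# textbook Pearson correlation
oracle_pearson <- function(x, y) {
  sum((x - mean(x)) * (y - mean(y))) /
    sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
}
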