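## Element-class signal densities, permutation enrichment tests, peak
## co-binding fractions and mark correlation matrices.

.merged_bp <- function(gr) {
  sum(as.numeric(GenomicRanges::width(
    GenomicRanges::reduce(gr, ignore.strand = TRUE))))
}

.covered_bp <- function(marks, elements) {
  sum(as.numeric(GenomicRanges::width(GenomicRanges::intersect(
    GenomicRanges::reduce(marks, ignore.strand = TRUE),
    GenomicRanges::reduce(elements, ignore.strand = TRUE),
    ignore.strand = TRUE))))
}

#' Fraction of element bp covered by marks
#'
#' Elements are merged (overlaps collapsed) before the total is taken;
#' density is the fraction of merged element bp covered by at least one
#' mark interval, so splitting a mark into adjacent pieces changes nothing.
#'
#' @param marks Mark intervals (`GRanges`), e.g. 5hmC peaks.
#' @param elements Element intervals (`GRanges`), e.g. promoters; non-empty.
#' @return List with `total_bp`, `covered_bp` and `density` in `[0, 1]`.
#' @export
element_density <- function(marks, elements) {
  if (length(elements) == 0L) stop("empty element set", call. = FALSE)
  total <- .merged_bp(elements)
  covered <- .covered_bp(marks, elements)
  list(total_bp = total, covered_bp = covered, density = covered / total)
}

#' Permutation test for a density difference between element classes
#'
#' Tests whether `elementsA` carries a different mark density than
#' `elementsB`.  The null is built by randomly reassigning the pooled
#' element intervals to the two classes, preserving class sizes; the
#' two-sided p-value is `(b + 1) / (n_perm + 1)` with `b` the number of
#' permuted |density differences| at least as large as the observed one.
#' When the number of distinct reassignments is at most `n_perm` (and
#' always when `exact = TRUE`), all reassignments are enumerated instead
#' and the p-value is the exact fraction.
#'
#' @param marks Mark intervals.
#' @param elementsA,elementsB Disjoint element sets (an overlap between the
#'   two universes is an error).
#' @param n_perm Number of random reassignments (>= 100).
#' @param seed Integer seed.
#' @param exact Force exhaustive enumeration of reassignments.
#' @return List with `density_A`, `density_B`, `delta`, `p`, `method`
#'   (`"permutation"` or `"exact"`) and `n_perm`.
#' @export
enrichment_test <- function(marks, elementsA, elementsB, n_perm = 1000L,
                            seed = 1L, exact = FALSE) {
  if (!exact && n_perm < 100L) stop("n_perm must be >= 100", call. = FALSE)
  if (length(elementsA) == 0L || length(elementsB) == 0L)
    stop("empty element set", call. = FALSE)
  if (any(GenomicRanges::countOverlaps(elementsA, elementsB,
                                       ignore.strand = TRUE) > 0L))
    stop("element universes A and B overlap; classes must be disjoint",
         call. = FALSE)
  nA <- length(elementsA)
  pool <- c(GenomicRanges::granges(elementsA),
            GenomicRanges::granges(elementsB))
  n <- length(pool)
  # per-element covered bp; additive only if pool elements are disjoint
  marks_red <- GenomicRanges::reduce(marks, ignore.strand = TRUE)
  ov <- GenomicRanges::findOverlaps(pool, marks_red, ignore.strand = TRUE)
  w_ov <- GenomicRanges::width(GenomicRanges::pintersect(
    pool[S4Vectors::queryHits(ov)], marks_red[S4Vectors::subjectHits(ov)],
    ignore.strand = TRUE))
  cov_i <- numeric(n)
  if (length(ov)) {
    agg <- tapply(w_ov, S4Vectors::queryHits(ov), sum)
    cov_i[as.integer(names(agg))] <- as.numeric(agg)
  }
  len_i <- as.numeric(GenomicRanges::width(pool))
  disjoint <- all(GenomicRanges::countOverlaps(pool, pool,
                                               ignore.strand = TRUE) == 1L)
  dens_set <- function(idx) {
    if (disjoint) sum(cov_i[idx]) / sum(len_i[idx])
    else element_density(marks_red, pool[idx])$density
  }
  d_obs <- dens_set(seq_len(nA)) - dens_set((nA + 1L):n)
  n_comb <- choose(n, nA)
  if (exact && n_comb > 1e5)
    stop("too many reassignments (", n_comb, ") for exact enumeration",
         call. = FALSE)
  if (exact || n_comb <= n_perm) {
    splits <- utils::combn(n, nA)
    deltas <- apply(splits, 2L, function(idx)
      dens_set(idx) - dens_set(setdiff(seq_len(n), idx)))
    p <- mean(abs(deltas) >= abs(d_obs) - 1e-12)
    method <- "exact"
    n_used <- ncol(splits)
  } else {
    set.seed(seed)
    deltas <- vapply(seq_len(n_perm), function(j) {
      idx <- sample.int(n, nA)
      dens_set(idx) - dens_set(setdiff(seq_len(n), idx))
    }, 0)
    p <- (sum(abs(deltas) >= abs(d_obs) - 1e-12) + 1) / (n_perm + 1)
    method <- "permutation"
    n_used <- n_perm
  }
  list(density_A = dens_set(seq_len(nA)),
       density_B = dens_set((nA + 1L):n),
       delta = d_obs, p = p, method = method, n_perm = n_used)
}

#' Co-binding fraction of two peak sets
#'
#' Fraction of `A` intervals overlapping (>= 1 bp, half-open boundary
#' semantics: touching intervals do not overlap) at least one `B` interval.
#' Each `A` interval counts once however many `B` peaks it hits.
#'
#' @param A,B Peak sets (`GRanges`); `A` non-empty.
#' @param label_A,label_B Labels echoed in the report.
#' @return List with `label_A`, `label_B`, `n_A`, `n_A_hit`, `fraction`.
#' @export
overlap_fraction <- function(A, B, label_A = "A", label_B = "B") {
  if (length(A) == 0L) stop("empty peak set A", call. = FALSE)
  hit <- GenomicRanges::countOverlaps(A, B, ignore.strand = TRUE) > 0L
  list(label_A = label_A, label_B = label_B,
       n_A = length(A), n_A_hit = sum(hit),
       fraction = sum(hit) / length(A))
}

#' Pairwise correlation of marks over regions
#'
#' Each input (a `signal_track` or a peak `GRanges`) is reduced to one value
#' per region — the mean per-bp signal for tracks, binary occupancy for peak
#' sets — and the Pearson correlation is computed for every pair.  A
#' zero-variance vector yields `NA` correlations with a warning.
#'
#' @param inputs Named list of `signal_track` and/or `GRanges` objects.
#' @param regions Regions (`GRanges`, non-empty) over which to correlate.
#' @return Symmetric correlation matrix with unit diagonal.
#' @export
signal_correlation <- function(inputs, regions) {
  if (length(inputs) < 2L) stop("need at least 2 inputs", call. = FALSE)
  if (length(regions) == 0L) stop("empty region set", call. = FALSE)
  chrom <- as.character(GenomicRanges::seqnames(regions))
  vecs <- vapply(inputs, function(x) {
    if (inherits(x, "signal_track")) {
      vapply(seq_along(regions), function(i)
        mean(track_values(x, chrom[i], GenomicRanges::start(regions)[i],
                          GenomicRanges::end(regions)[i])), 0)
    } else {
      as.numeric(GenomicRanges::countOverlaps(regions, x,
                                              ignore.strand = TRUE) > 0L)
    }
  }, numeric(length(regions)))
  sds <- apply(vecs, 2L, stats::sd)
  if (any(sds == 0))
    warning("zero-variance input(s): ",
            paste(colnames(vecs)[sds == 0], collapse = ", "),
            "; correlations reported as NA", call. = FALSE)
  cm <- suppressWarnings(stats::cor(vecs))
  diag(cm) <- 1
  cm
}
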