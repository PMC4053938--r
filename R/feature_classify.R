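## Promoter / gene classification schemes used to stratify every profile and
## density analysis: expression tiers, tissue-specific vs housekeeping genes,
## CpG-content promoter classes (LCP/ICP/HCP), chromatin state around the TSS
## (K4 / K27 / K4-K27 bivalent / none) and active-vs-poised enhancers.

#' Expression tiers from RPKM
#'
#' Genes are split into three tiers: `none` (RPKM below `low_cut`), `low`
#' (at least `low_cut` but below `high_cut`) and `mid_high` (at least
#' `high_cut`).  Intervals are left-closed, so a gene at exactly `low_cut`
#' is `low`.
#'
#' @param expr Expression matrix from [read_expression()].
#' @param sample Sample (column) label.
#' @param low_cut,high_cut Tier cut points in RPKM (defaults 0.1 and 5).
#' @return Named factor with levels `none`, `low`, `mid_high`.
#' @export
expression_tiers <- function(expr, sample, low_cut = 0.1, high_cut = 5) {
  stopifnot(low_cut >= 0, low_cut < high_cut)
  if (!sample %in% colnames(expr))
    stop("sample '", sample, "' not in expression table", call. = FALSE)
  r <- expr[, sample]
  tier <- ifelse(r < low_cut, "none", ifelse(r < high_cut, "low",
                                             "mid_high"))
  factor(stats::setNames(tier, rownames(expr)),
         levels = c("none", "low", "mid_high"))
}

#' Tissue-specific genes
#'
#' A gene is specific to the target tissue when its RPKM is at least
#' `on_cut` there and below `off_cut` in every other listed sample.
#'
#' @param expr Expression matrix.
#' @param target Target sample label.
#' @param others Character vector of the remaining sample labels.
#' @param on_cut Minimum RPKM in the target (default 10).
#' @param off_cut Exclusive RPKM ceiling elsewhere (default 1).
#' @return Character vector of gene ids.
#' @export
tissue_specific_genes <- function(expr, target, others,
                                  on_cut = 10, off_cut = 1) {
  if (target %in% others) stop("target must not be among others",
                               call. = FALSE)
  miss <- setdiff(c(target, others), colnames(expr))
  if (length(miss)) stop("missing sample(s): ", paste(miss, collapse = ", "),
                         call. = FALSE)
  on <- expr[, target] >= on_cut
  off <- rowSums(expr[, others, drop = FALSE] >= off_cut) == 0L
  rownames(expr)[on & off]
}

#' Housekeeping genes
#'
#' Genes with RPKM strictly above `cut` in every listed sample.
#'
#' @param expr Expression matrix.
#' @param samples Sample labels (at least 2).
#' @param cut RPKM threshold (default 10).
#' @return Character vector of gene ids.
#' @export
housekeeping_genes <- function(expr, samples = colnames(expr), cut = 10) {
  if (length(samples) < 2L) stop("need at least 2 samples", call. = FALSE)
  miss <- setdiff(samples, colnames(expr))
  if (length(miss)) stop("missing sample(s): ", paste(miss, collapse = ", "),
                         call. = FALSE)
  keep <- rowSums(expr[, samples, drop = FALSE] > cut) == length(samples)
  rownames(expr)[keep]
}

# CpG observed/expected ratio and GC fraction for every sliding window.
# Returns a matrix with columns ratio, gc; one row per window position.
.cpg_windows <- function(seq, window = 500L, step = 5L) {
  b <- strsplit(seq, "", fixed = TRUE)[[1L]]
  n <- length(b)
  isC <- as.integer(b == "C")
  isG <- as.integer(b == "G")
  isCG <- as.integer(b[-n] == "C" & b[-1L] == "G")
  w <- min(window, n)
  csC <- c(0L, cumsum(isC))
  csG <- c(0L, cumsum(isG))
  csCG <- c(0L, cumsum(isCG))
  starts <- seq(1L, n - w + 1L, by = step)
  nC <- csC[starts + w] - csC[starts]
  nG <- csG[starts + w] - csG[starts]
  # dinucleotides fully inside the window: starts .. start + w - 2
  nCG <- csCG[pmin(starts + w - 1L, n - 1L + 1L)] - csCG[starts]
  ratio <- ifelse(nC * nG > 0, nCG * w / (nC * nG), 0)
  cbind(ratio = ratio, gc = (nC + nG) / w)
}

#' CpG-content promoter class (LCP / ICP / HCP)
#'
#' Scans the promoter sequence with 500-bp sliding windows (5-bp step;
#' sequences shorter than 500 bp are taken as a single window) and computes
#' per window the CpG observed/expected ratio
#' `#CG x window_length / (#C x #G)` and the GC fraction.  The promoter is
#' `HCP` if any window has ratio > 0.75 and GC > 0.55, `LCP` if no window
#' reaches ratio 0.48, and `ICP` otherwise.
#'
#' @param seq Promoter nucleotide sequence over A/C/G/T/N, length >= 200.
#' @param window,step Sliding-window size and step in bp.
#' @return One of `"LCP"`, `"ICP"`, `"HCP"`.
#' @export
cpg_class <- function(seq, window = 500L, step = 5L) {
  seq <- toupper(seq)
  if (nchar(seq) < 200L) stop("promoter sequence shorter than 200 bp",
                              call. = FALSE)
  nN <- nchar(gsub("[^N]", "", seq))
  if (nN > nchar(seq) / 2) stop("more than 50% N in promoter sequence",
                                call. = FALSE)
  w <- .cpg_windows(seq, window, step)
  if (any(w[, "ratio"] > 0.75 & w[, "gc"] > 0.55)) "HCP"
  else if (all(w[, "ratio"] < 0.48)) "LCP"
  else "ICP"
}

#' Chromatin class of promoters (K4 / K27 / bivalent / none)
#'
#' A promoter window (TSS +/- `window` bp) carries a mark when it overlaps
#' at least one peak of that mark by >= 1 bp.  Promoters with both H3K4me3
#' and H3K27me3 are bivalent (`K4/K27`).
#'
#' @param genes Gene models.
#' @param k4_peaks,k27_peaks Peak sets (`GRanges`) for H3K4me3 and H3K27me3.
#' @param window Half-width of the promoter window in bp (default 1 kb).
#' @return Named factor with levels `K4`, `K27`, `K4/K27`, `none`.
#' @export
chromatin_class <- function(genes, k4_peaks, k27_peaks, window = 1000L) {
  prom <- promoter_window(genes, window, window)
  k4 <- GenomicRanges::countOverlaps(prom, k4_peaks,
                                     ignore.strand = TRUE) > 0L
  k27 <- GenomicRanges::countOverlaps(prom, k27_peaks,
                                      ignore.strand = TRUE) > 0L
  cls <- ifelse(k4 & k27, "K4/K27", ifelse(k4, "K4",
                                           ifelse(k27, "K27", "none")))
  factor(stats::setNames(cls, S4Vectors::mcols(genes)$gene_id),
         levels = c("K4", "K27", "K4/K27", "none"))
}

#' Active vs poised enhancer class
#'
#' Enhancer inputs are assumed pre-filtered to H3K4me1-positive distal
#' elements; this only splits them: `active` when overlapping an H3K27ac
#' peak, `poised` otherwise (typically H3K27me3-marked).
#'
#' @param enhancers Enhancer intervals (`GRanges`, non-empty).
#' @param k27ac_peaks H3K27ac peak set.
#' @return Factor (levels `active`, `poised`), one per enhancer.
#' @export
enhancer_class <- function(enhancers, k27ac_peaks) {
  if (length(enhancers) == 0L) stop("empty enhancer set", call. = FALSE)
  ac <- GenomicRanges::countOverlaps(enhancers, k27ac_peaks,
                                     ignore.strand = TRUE) > 0L
  factor(ifelse(ac, "active", "poised"), levels = c("active", "poised"))
}

#' Full promoter classification table
#'
#' Convenience wrapper combining CpG class, chromatin class and expression
#' tier into one data.frame, one row per gene.
#'
#' @param genes Gene models.
#' @param promoter_seqs Named character vector of promoter sequences
#'   (names = gene ids).
#' @param k4_peaks,k27_peaks Peak sets for H3K4me3/H3K27me3.
#' @param expr Expression matrix.
#' @param sample Expression sample used for tiering.
#' @return data.frame with columns `gene_id`, `cpg_class`,
#'   `chromatin_class`, `expression_tier`.
#' @export
classify_promoters <- function(genes, promoter_seqs, k4_peaks, k27_peaks,
                               expr, sample) {
  ids <- S4Vectors::mcols(genes)$gene_id
  cpg <- vapply(promoter_seqs[ids], cpg_class, "")
  chrom <- chromatin_class(genes, k4_peaks, k27_peaks)
  tier <- expression_tiers(expr, sample)
  data.frame(gene_id = ids,
             cpg_class = factor(cpg, levels = c("LCP", "ICP", "HCP")),
             chromatin_class = chrom[ids],
             expression_tier = tier[ids],
             row.names = NULL)
}
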