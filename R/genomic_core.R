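#' @importFrom GenomicRanges GRanges GRangesList seqnames start end strand
#'   width mcols reduce coverage findOverlaps countOverlaps intersect
#' @importFrom IRanges IRanges Views viewMeans slice RleList
#' @importFrom S4Vectors Rle runValue runLength mcols<-
#' @importFrom GenomeInfoDb seqlengths seqlengths<- seqlevels seqlevels<-
#' @importFrom methods is
NULL

## ---------------------------------------------------------------------------
## Internal coordinate convention: GRanges, 1-based closed.  All BED/bedGraph
## I/O converts at the boundary (BED start + 1 on read, start - 1 on write),
## so half-open semantics hold at every file interface: length = end - start
## and touching records ([100,200) vs [200,300)) do not overlap.
## ---------------------------------------------------------------------------

stop_parse <- function(path, line, msg) {
  stop(sprintf("%s: line %d: %s", path, line, msg), call. = FALSE)
}

.read_tab_lines <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  x <- readLines(path)
  x[nzchar(x) & !startsWith(x, "#") & !startsWith(x, "track")]
}

.as_coord <- function(s) suppressWarnings(as.integer(s))

#' Read a BED3-BED6 file into a sorted peak set
#'
#' Coordinates are converted from BED's 0-based half-open convention to the
#' 1-based closed convention of [GenomicRanges::GRanges]; widths and overlap
#' semantics are unchanged.  Records are returned sorted by (chrom, start).
#' BED strand "." maps to unstranded (`*`).
#'
#' @param path Path to a BED file with 3 to 6 tab-separated columns.
#' @param source Optional label stored in `metadata(x)$source`.
#' @return A `GRanges` sorted by (chrom, start); column 4 (name) and 5
#'   (score) are kept as metadata columns when present.
#' @export
read_intervals <- function(path, source = basename(path)) {
  lines <- .read_tab_lines(path)
  if (length(lines) == 0L) {
    gr <- GenomicRanges::GRanges()
  } else {
    f <- strsplit(lines, "\t", fixed = TRUE)
    nf <- lengths(f)
    bad <- which(nf < 3L)
    if (length(bad)) stop_parse(path, bad[1L], "fewer than 3 BED columns")
    chrom <- vapply(f, `[[`, "", 1L)
    s0 <- .as_coord(vapply(f, `[[`, "", 2L))
    e0 <- .as_coord(vapply(f, `[[`, "", 3L))
    bad <- which(is.na(s0) | is.na(e0))
    if (length(bad)) stop_parse(path, bad[1L], "non-integer coordinates")
    bad <- which(s0 >= e0 | s0 < 0L)
    if (length(bad)) stop_parse(path, bad[1L], "requires 0 <= start < end")
    strand <- rep("*", length(f))
    has6 <- nf >= 6L
    strand[has6] <- vapply(f[has6], `[[`, "", 6L)
    strand[!strand %in% c("+", "-")] <- "*"
    gr <- GenomicRanges::GRanges(chrom, IRanges::IRanges(s0 + 1L, e0),
                                 strand = strand)
    if (any(nf >= 4L)) {
      nm <- rep(NA_character_, length(f))
      nm[nf >= 4L] <- vapply(f[nf >= 4L], `[[`, "", 4L)
      S4Vectors::mcols(gr)$name <- nm
    }
    if (any(nf >= 5L)) {
      sc <- rep(NA_character_, length(f))
      sc[nf >= 5L] <- vapply(f[nf >= 5L], `[[`, "", 5L)
      S4Vectors::mcols(gr)$score <- suppressWarnings(as.numeric(sc))
    }
    gr <- gr[order(as.character(GenomicRanges::seqnames(gr)),
                   GenomicRanges::start(gr), GenomicRanges::end(gr))]
  }
  S4Vectors::metadata(gr)$source <- source
  gr
}

#' Write intervals to BED
#'
#' Inverse of [read_intervals()]: emits 0-based half-open coordinates.
#' @param x A `GRanges`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_intervals <- function(x, path) {
  n <- length(x)
  name <- if (!is.null(S4Vectors::mcols(x)$name)) S4Vectors::mcols(x)$name
          else rep(".", n)
  score <- if (!is.null(S4Vectors::mcols(x)$score)) S4Vectors::mcols(x)$score
           else rep(0, n)
  strand <- as.character(GenomicRanges::strand(x))
  strand[strand == "*"] <- "."
  keep_extra <- any(name != ".") || any(strand != ".") || any(score != 0)
  df <- data.frame(chrom = as.character(GenomicRanges::seqnames(x)),
                   start = GenomicRanges::start(x) - 1L,
                   end = GenomicRanges::end(x))
  if (keep_extra) {
    df$name <- ifelse(is.na(name), ".", name)
    df$score <- ifelse(is.na(score), 0, score)
    df$strand <- strand
  }
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read gene models from a BED12 file
#'
#' Exons are reconstructed from blockStarts/blockSizes; the transcription
#' start site is strand-aware (chromStart for `+`, the last covered base for
#' `-`).  Block arithmetic inconsistent with chromStart/chromEnd is a parse
#' error.
#'
#' @param path Path to a 12-column BED file.
#' @return A `GRanges` of gene spans with metadata columns `gene_id`
#'   (character), `tss` (1-based position of the TSS base) and `exons`
#'   (a `GRangesList`, one sorted disjoint set per gene).
#' @export
read_gene_models <- function(path) {
  lines <- .read_tab_lines(path)
  if (length(lines) == 0L) stop("no records in ", path, call. = FALSE)
  f <- strsplit(lines, "\t", fixed = TRUE)
  bad <- which(lengths(f) < 12L)
  if (length(bad)) stop_parse(path, bad[1L], "fewer than 12 BED12 columns")
  chrom <- vapply(f, `[[`, "", 1L)
  s0 <- .as_coord(vapply(f, `[[`, "", 2L))
  e0 <- .as_coord(vapply(f, `[[`, "", 3L))
  gene_id <- vapply(f, `[[`, "", 4L)
  strand <- vapply(f, `[[`, "", 6L)
  n_blocks <- .as_coord(vapply(f, `[[`, "", 10L))
  bad <- which(is.na(s0) | is.na(e0) | s0 >= e0)
  if (length(bad)) stop_parse(path, bad[1L], "invalid chromStart/chromEnd")
  bad <- which(!strand %in% c("+", "-"))
  if (length(bad)) stop_parse(path, bad[1L], "strand must be + or -")
  exons <- vector("list", length(f))
  for (i in seq_along(f)) {
    sizes <- .as_coord(strsplit(f[[i]][11L], ",", fixed = TRUE)[[1L]])
    starts <- .as_coord(strsplit(f[[i]][12L], ",", fixed = TRUE)[[1L]])
    if (length(sizes) != n_blocks[i] || length(starts) != n_blocks[i] ||
        anyNA(sizes) || anyNA(starts))
      stop_parse(path, i, "blockSizes/blockStarts inconsistent with blockCount")
    ex_s0 <- s0[i] + starts
    ex_e0 <- ex_s0 + sizes
    if (starts[1L] != 0L || ex_e0[n_blocks[i]] != e0[i] ||
        any(ex_e0 > e0[i]) ||
        (n_blocks[i] > 1L && any(ex_s0[-1L] < ex_e0[-n_blocks[i]])))
      stop_parse(path, i, "block arithmetic inconsistent with chromStart/End")
    exons[[i]] <- GenomicRanges::GRanges(chrom[i],
                                         IRanges::IRanges(ex_s0 + 1L, ex_e0),
                                         strand = strand[i])
  }
  if (anyDuplicated(gene_id))
    stop("duplicate gene_id in ", path, ": ",
         gene_id[anyDuplicated(gene_id)], call. = FALSE)
  gr <- GenomicRanges::GRanges(chrom, IRanges::IRanges(s0 + 1L, e0),
                               strand = strand)
  names(gr) <- gene_id
  S4Vectors::mcols(gr)$gene_id <- gene_id
  S4Vectors::mcols(gr)$tss <- ifelse(strand == "+", s0 + 1L, e0)
  S4Vectors::mcols(gr)$exons <- GenomicRanges::GRangesList(exons)
  gr
}

#' Write gene models to BED12
#' @param genes A `GRanges` as returned by [read_gene_models()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_gene_models <- function(genes, path) {
  rows <- character(length(genes))
  for (i in seq_along(genes)) {
    g <- genes[i]
    ex <- S4Vectors::mcols(genes)$exons[[i]]
    s0 <- GenomicRanges::start(g) - 1L
    e0 <- GenomicRanges::end(g)
    sizes <- paste0(paste(GenomicRanges::width(ex), collapse = ","), ",")
    starts <- paste0(paste(GenomicRanges::start(ex) - 1L - s0,
                           collapse = ","), ",")
    rows[i] <- paste(as.character(GenomicRanges::seqnames(g)), s0, e0,
                     S4Vectors::mcols(genes)$gene_id[i], 0,
                     as.character(GenomicRanges::strand(g)), s0, e0, "0",
                     length(ex), sizes, starts, sep = "\t")
  }
  writeLines(rows, path)
  invisible(path)
}

#' Strand-aware TSS positions
#' @param genes Gene models (`GRanges` with `tss` metadata, or any stranded
#'   `GRanges`, in which case the TSS is derived from the span).
#' @return Integer vector of 1-based TSS base positions, named by gene.
#' @export
gene_tss <- function(genes) {
  tss <- S4Vectors::mcols(genes)$tss
  if (is.null(tss)) {
    plus <- as.character(GenomicRanges::strand(genes)) == "+"
    tss <- ifelse(plus, GenomicRanges::start(genes),
                  GenomicRanges::end(genes))
  }
  names(tss) <- names(genes)
  tss
}

## ---------------------------------------------------------------------------
## SignalTrack: non-negative per-bp coverage, zero by default everywhere.
## ---------------------------------------------------------------------------

#' Construct a signal track from runs of coverage
#'
#' @param gr `GRanges` with a numeric `score` column (run values); runs must
#'   not overlap and scores must be non-negative.
#' @param seqlengths Named integer vector of chromosome lengths; defaults to
#'   the furthest covered base per chromosome.
#' @return An object of class `signal_track` wrapping an [IRanges::RleList]
#'   of per-bp values plus the genome-size table.
#' @export
signal_track <- function(gr, seqlengths = NULL) {
  score <- S4Vectors::mcols(gr)$score
  if (is.null(score)) stop("signal runs need a 'score' column", call. = FALSE)
  if (any(score < 0)) stop("negative signal value", call. = FALSE)
  if (length(gr) &&
      any(GenomicRanges::countOverlaps(gr, gr,
                                       ignore.strand = TRUE) > 1L))
    stop("overlapping signal runs; normalize the track upstream",
         call. = FALSE)
  if (is.null(seqlengths)) {
    if (length(gr)) {
      seqlengths <- tapply(GenomicRanges::end(gr),
                           as.character(GenomicRanges::seqnames(gr)), max)
      seqlengths <- stats::setNames(as.integer(seqlengths), names(seqlengths))
    } else seqlengths <- integer(0)
  }
  cov <- lapply(names(seqlengths), function(ch) {
    L <- seqlengths[[ch]]
    sel <- as.character(GenomicRanges::seqnames(gr)) == ch
    if (!any(sel)) return(S4Vectors::Rle(0, L))
    g <- gr[sel]
    o <- order(GenomicRanges::start(g))
    s <- GenomicRanges::start(g)[o]
    e <- pmin(GenomicRanges::end(g)[o], L)
    v <- S4Vectors::mcols(g)$score[o]
    keep <- s <= L
    s <- s[keep]; e <- e[keep]; v <- v[keep]
    # interleave zero gaps with runs; runs are disjoint and sorted
    gap_before <- s - c(1L, e[-length(e)] + 1L)
    vals <- as.vector(rbind(0, v))
    lens <- as.vector(rbind(gap_before, e - s + 1L))
    tail_gap <- L - e[length(e)]
    if (tail_gap > 0L) { vals <- c(vals, 0); lens <- c(lens, tail_gap) }
    nz <- lens > 0L
    S4Vectors::Rle(vals[nz], lens[nz])
  })
  names(cov) <- names(seqlengths)
  structure(list(cov = IRanges::RleList(cov, compress = FALSE),
                 seqlengths = seqlengths),
            class = "signal_track")
}

#' Read a bedGraph file into a signal track
#'
#' Unlisted positions are zero.  Overlapping runs and negative values are
#' rejected (the track must be pre-normalized to disjoint runs).
#'
#' @param path Path to a 4-column bedGraph file.
#' @param seqlengths Optional named chromosome lengths (see
#'   [read_genome_sizes()]); defaults to the furthest covered base.
#' @return A `signal_track`.
#' @export
read_signal <- function(path, seqlengths = NULL) {
  lines <- .read_tab_lines(path)
  if (length(lines) == 0L) {
    return(signal_track(GenomicRanges::GRanges(score = numeric(0)),
                        seqlengths = if (is.null(seqlengths)) integer(0)
                                     else seqlengths))
  }
  f <- strsplit(lines, "\t", fixed = TRUE)
  bad <- which(lengths(f) < 4L)
  if (length(bad)) stop_parse(path, bad[1L], "fewer than 4 bedGraph columns")
  chrom <- vapply(f, `[[`, "", 1L)
  s0 <- .as_coord(vapply(f, `[[`, "", 2L))
  e0 <- .as_coord(vapply(f, `[[`, "", 3L))
  v <- suppressWarnings(as.numeric(vapply(f, `[[`, "", 4L)))
  bad <- which(is.na(s0) | is.na(e0) | s0 >= e0 | s0 < 0L)
  if (length(bad)) stop_parse(path, bad[1L], "invalid run coordinates")
  bad <- which(is.na(v))
  if (length(bad)) stop_parse(path, bad[1L], "non-numeric value")
  bad <- which(v < 0)
  if (length(bad)) stop_parse(path, bad[1L], "negative signal value")
  gr <- GenomicRanges::GRanges(chrom, IRanges::IRanges(s0 + 1L, e0),
                               score = v)
  signal_track(gr, seqlengths = seqlengths)
}

#' Write a signal track to bedGraph
#'
#' Zero runs are omitted; coordinates are 0-based half-open.
#' @param track A `signal_track`.
#' @param path Output path.
#' @param digits Decimal places used to format values (fixed so that
#'   regenerated files are byte-identical).
#' @return `path`, invisibly.
#' @export
write_signal <- function(track, path, digits = 4L) {
  con <- file(path, "w")
  on.exit(close(con))
  for (ch in names(track$cov)) {
    r <- track$cov[[ch]]
    rl <- S4Vectors::runLength(r)
    rv <- S4Vectors::runValue(r)
    e <- cumsum(rl)
    s <- e - rl
    keep <- rv != 0
    if (any(keep)) {
      writeLines(paste(ch, s[keep], e[keep],
                       formatC(rv[keep], format = "f", digits = digits),
                       sep = "\t"), con)
    }
  }
  invisible(path)
}

#' Per-bp signal over a window
#'
#' Positions outside the chromosome (or on a chromosome the track does not
#' know) return 0; unknown chromosomes additionally raise a warning so that
#' partial fixtures still run.
#'
#' @param track A `signal_track`.
#' @param chrom Chromosome name.
#' @param start,end 1-based closed query window.
#' @return Numeric vector of length `end - start + 1`.
#' @export
track_values <- function(track, chrom, start, end) {
  n <- end - start + 1L
  if (!chrom %in% names(track$cov)) {
    warning("chromosome '", chrom, "' not in track; returning zeros",
            call. = FALSE)
    return(numeric(n))
  }
  r <- track$cov[[chrom]]
  L <- length(r)
  out <- numeric(n)
  lo <- max(1L, start)
  hi <- min(L, end)
  if (lo <= hi) out[(lo - start + 1L):(hi - start + 1L)] <-
      as.numeric(r[lo:hi])
  out
}

#' Total signal of a track
#' @param track A `signal_track`.
#' @return Sum over all runs of value times run length.
#' @export
track_total <- function(track) {
  sum(vapply(track$cov, function(r)
    sum(as.numeric(S4Vectors::runValue(r)) * S4Vectors::runLength(r)), 0))
}

#' Read a two-column genome-size file
#' @param path Path to a "chrom\\tlength" table.
#' @return Named integer vector of chromosome lengths.
#' @export
read_genome_sizes <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = FALSE,
                          col.names = c("chrom", "length"),
                          colClasses = c("character", "integer"))
  stats::setNames(df$length, df$chrom)
}

#' @rdname read_genome_sizes
#' @param sizes Named integer vector.
#' @export
write_genome_sizes <- function(sizes, path) {
  writeLines(paste(names(sizes), sizes, sep = "\t"), path)
  invisible(path)
}

#' Read an expression table (gene x sample RPKM)
#'
#' First column is the gene identifier, remaining columns one RPKM value per
#' sample.  Duplicate gene rows and non-numeric cells are errors; negative
#' RPKM is an error.
#'
#' @param path Path to a tab-separated table with a header row.
#' @return Numeric matrix, rownames = gene ids, colnames = sample labels.
#' @export
read_expression <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = TRUE,
                          check.names = FALSE, colClasses = "character")
  if (ncol(df) < 2L) stop("expression table needs gene_id + >=1 sample",
                          call. = FALSE)
  ids <- df[[1L]]
  dup <- ids[duplicated(ids)]
  if (length(dup)) stop("duplicate gene_id in ", path, ": ", dup[1L],
                        call. = FALSE)
  m <- as.matrix(df[, -1L, drop = FALSE])
  num <- suppressWarnings(matrix(as.numeric(m), nrow = nrow(m),
                                 dimnames = list(ids, colnames(m))))
  if (anyNA(num)) {
    idx <- which(is.na(num), arr.ind = TRUE)[1L, ]
    stop(sprintf("%s: non-numeric RPKM at gene '%s', sample '%s'",
                 path, ids[idx[1L]], colnames(num)[idx[2L]]), call. = FALSE)
  }
  if (any(num < 0)) stop("negative RPKM in ", path, call. = FALSE)
  num
}

#' @rdname read_expression
#' @param expr Numeric matrix of RPKM values.
#' @export
write_expression <- function(expr, path) {
  df <- data.frame(gene_id = rownames(expr), expr, check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read sequences from FASTA
#'
#' Sequences are uppercased; names are the first whitespace token of the
#' header.  Empty records are errors.
#'
#' @param path Path to a FASTA file.
#' @return Named character vector of sequences.
#' @export
read_sequences <- function(path) {
  ss <- Biostrings::readDNAStringSet(path)
  if (any(Biostrings::width(ss) == 0L))
    stop("empty FASTA record in ", path, call. = FALSE)
  seqs <- toupper(as.character(ss))
  names(seqs) <- vapply(strsplit(names(ss), "\\s+"), `[[`, "", 1L)
  seqs
}

#' @rdname read_sequences
#' @param seqs Named character vector of sequences.
#' @param width Line-wrap width.
#' @export
write_sequences <- function(seqs, path, width = 70L) {
  Biostrings::writeXStringSet(
    Biostrings::DNAStringSet(seqs), path, width = width)
  invisible(path)
}

#' Strand-aware promoter window around the TSS
#'
#' For a `+` strand gene the window covers `upstream` bp before and
#' `downstream` bp from the TSS base on; for a `-` strand gene the window is
#' the exact mirror image, so that reflecting the genome leaves promoter
#' windows fixed.  Windows are clipped at chromosome bounds; a window falling
#' entirely off-chromosome is an error.
#'
#' @param genes Gene models (`GRanges` with `tss`).
#' @param upstream,downstream Extent in bp (both `>= 0`).
#' @param seqlengths Optional chromosome lengths used for right-clipping.
#' @return Unstranded `GRanges` of promoter windows, one per gene, named by
#'   gene.
#' @export
promoter_window <- function(genes, upstream = 1000L, downstream = 1000L,
                            seqlengths = NULL) {
  stopifnot(upstream >= 0, downstream >= 0, upstream + downstream > 0)
  tss <- gene_tss(genes)
  plus <- as.character(GenomicRanges::strand(genes)) == "+"
  s <- ifelse(plus, tss - upstream, tss - downstream + 1L)
  e <- ifelse(plus, tss + downstream - 1L, tss + upstream)
  chrom <- as.character(GenomicRanges::seqnames(genes))
  if (!is.null(seqlengths)) {
    lim <- seqlengths[chrom]
    if (any(s > lim, na.rm = TRUE))
      stop("promoter window entirely off chromosome", call. = FALSE)
    e <- pmin(e, ifelse(is.na(lim), e, lim))
  }
  if (any(e < 1L)) stop("promoter window entirely off chromosome",
                        call. = FALSE)
  s <- pmax(s, 1L)
  out <- GenomicRanges::GRanges(chrom, IRanges::IRanges(s, e))
  names(out) <- names(genes)
  out
}
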