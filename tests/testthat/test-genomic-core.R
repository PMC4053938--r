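# Readers/writers and coordinate arithmetic of the core domain types.

test_that("BED intervals parse, sort and round-trip exactly", {
  f <- write_lines_tmp("chr1\t100\t200", ".bed")
  gr <- read_intervals(f)
  expect_length(gr, 1L)
  expect_equal(GenomicRanges::start(gr), 101L)   # 0-based file, 1-based API
  expect_equal(GenomicRanges::end(gr), 200L)
  expect_equal(GenomicRanges::width(gr), 100L)   # length = end - start

  unsorted <- c("chr2\t50\t60", "chr1\t500\t600", "chr1\t10\t20")
  gr2 <- read_intervals(write_lines_tmp(unsorted, ".bed"))
  expect_equal(as.character(GenomicRanges::seqnames(gr2)),
               c("chr1", "chr1", "chr2"))
  expect_equal(GenomicRanges::start(gr2) - 1L, c(10L, 500L, 50L))

  six <- "chr1\t0\t10\tpk1\t7.5\t."
  gr3 <- read_intervals(write_lines_tmp(six, ".bed"))
  expect_equal(as.character(GenomicRanges::strand(gr3)), "*")
  expect_equal(S4Vectors::mcols(gr3)$score, 7.5)

  out <- tempfile(fileext = ".bed")
  write_intervals(gr2, out)
  expect_equal(read_intervals(out), read_intervals(out))
  back <- read_intervals(out)
  expect_equal(GenomicRanges::start(back), GenomicRanges::start(gr2))
  expect_equal(GenomicRanges::end(back), GenomicRanges::end(gr2))
})

test_that("malformed BED lines are rejected with their line number", {
  bad <- c("chr1\t10\t20", "chr1\tten\t20")
  expect_error(read_intervals(write_lines_tmp(bad, ".bed")), "line 2")
  expect_error(
    read_intervals(write_lines_tmp("chr1\t30\t20", ".bed")),
    "start < end")
})

test_that("BED12 gene models reconstruct exons and strand-aware TSS", {
  rows <- c(
    "chr1\t1000\t5000\tgp\t0\t+\t1000\t5000\t0\t2\t100,200,\t0,3800,",
    "chr1\t1000\t5000\tgm\t0\t-\t1000\t5000\t0\t2\t100,200,\t0,3800,",
    "chr2\t0\t1000\tg3\t0\t+\t0\t1000\t0\t3\t100,50,300,\t0,400,700,")
  gm <- read_gene_models(write_lines_tmp(rows, ".bed12"))
  tss <- gene_tss(gm)
  expect_equal(unname(tss[["gp"]]) - 1L, 1000L)  # 0-based plus-strand TSS
  expect_equal(unname(tss[["gm"]]) - 1L, 4999L)  # last covered base on minus
  ex3 <- S4Vectors::mcols(gm)$exons[[3L]]
  expect_equal(sum(GenomicRanges::width(ex3)), 100L + 50L + 300L)
  expect_length(ex3, 3L)

  out <- tempfile(fileext = ".bed12")
  write_gene_models(gm, out)
  expect_identical(readLines(out)[2L], rows[2L])
})

test_that("inconsistent BED12 block arithmetic is a parse error", {
  bad <- "chr1\t1000\t5000\tg\t0\t+\t1000\t5000\t0\t2\t100,200,\t0,3900,"
  expect_error(read_gene_models(write_lines_tmp(bad, ".bed12")),
               "block arithmetic")
  short <- "chr1\t1000\t5000\tg\t0\t+\t1000\t5000\t0\t3\t100,200,\t0,3800,"
  expect_error(read_gene_models(write_lines_tmp(short, ".bed12")),
               "blockCount")
})

test_that("bedGraph tracks honour half-open boundaries and zero defaults", {
  tr <- toy_track(data.frame(chrom = "chr1", s0 = 0L, e0 = 10L,
                             value = 2.5))
  expect_equal(track_values(tr, "chr1", 6L, 6L), 2.5)   # 0-based pos 5
  expect_equal(suppressWarnings(track_values(tr, "chr1", 11L, 11L)), 0)
  expect_warning(track_values(tr, "chrX", 1L, 5L), "not in track")

  runs <- data.frame(chrom = "chr1",
                     s0 = c(0L, 20L, 100L, 230L, 500L),
                     e0 = c(10L, 40L, 180L, 300L, 501L),
                     value = c(2.5, 1, 0.25, 3, 10))
  tr5 <- toy_track(runs)
  expect_equal(track_total(tr5),
               sum(runs$value * (runs$e0 - runs$s0)))     # hand sum

  empty <- read_signal(write_lines_tmp(character(0), ".bedGraph"))
  expect_equal(track_total(empty), 0)
})

test_that("bedGraph rejects overlaps and negative values; round-trips", {
  ovl <- c("chr1\t0\t10\t1", "chr1\t5\t15\t2")
  expect_error(read_signal(write_lines_tmp(ovl, ".bedGraph")),
               "overlapping")
  expect_error(
    read_signal(write_lines_tmp("chr1\t0\t10\t-1", ".bedGraph")),
    "negative")

  runs <- data.frame(chrom = "chr1", s0 = c(0L, 50L), e0 = c(10L, 80L),
                     value = c(1.25, 0.5))
  tr <- toy_track(runs, seqlengths = c(chr1 = 100L))
  out <- tempfile(fileext = ".bedGraph")
  write_signal(tr, out)
  tr2 <- read_signal(out, seqlengths = c(chr1 = 100L))
  expect_equal(as.numeric(tr2$cov$chr1), as.numeric(tr$cov$chr1))
})

test_that("expression tables parse with strict gene uniqueness", {
  lines <- c("gene_id\tESC\tliver", "g1\t0.0\t12", "g2\t3.5\t0.1")
  expr <- read_expression(write_lines_tmp(lines, ".tsv"))
  expect_equal(expr["g1", "ESC"], 0)          # zero is data, gene retained
  expect_equal(expr["g2", "liver"], 0.1)
  dup <- c("gene_id\tESC", "g1\t1", "g1\t2")
  expect_error(read_expression(write_lines_tmp(dup, ".tsv")), "duplicate")
  badcell <- c("gene_id\tESC", "g1\tlots")
  expect_error(read_expression(write_lines_tmp(badcell, ".tsv")),
               "g1.*ESC")
})

test_that("FASTA sequences are uppercased, named and length-checked", {
  fa <- c(">p1 extra tokens", "acgt", ">p2", "ACGTAC", "GTACGT")
  seqs <- read_sequences(write_lines_tmp(fa, ".fa"))
  expect_equal(seqs[["p1"]], "ACGT")
  expect_equal(nchar(seqs[["p2"]]), 12L)       # multi-line concatenation

  out <- tempfile(fileext = ".fa")
  write_sequences(seqs, out)
  expect_equal(read_sequences(out), seqs)
})

test_that("promoter windows are strand-symmetric, clipped, half-open", {
  gm <- toy_genes(data.frame(chrom = "chr1", s0 = c(1000L, 1000L, 100L),
                             e0 = c(5000L, 5000L, 900L),
                             id = c("gp", "gm", "gclip"),
                             strand = c("+", "-", "+")))
  pw <- promoter_window(gm, 1000L, 1000L)
  expect_equal(GenomicRanges::start(pw["gp"]) - 1L, 0L)
  expect_equal(GenomicRanges::end(pw["gp"]), 2000L)      # [0, 2000)
  expect_equal(GenomicRanges::start(pw["gclip"]) - 1L, 0L)  # clipped
  expect_equal(GenomicRanges::end(pw["gclip"]), 1100L)

  asym <- promoter_window(gm[1:2], 1000L, 500L)
  # minus-strand window is the reflection of the plus-strand one about
  # the shared gene span: [0,1500) reflects to [4500,6000)
  expect_equal(GenomicRanges::start(asym["gm"]) - 1L, 4500L)
  expect_equal(GenomicRanges::end(asym["gm"]), 6000L)
  expect_equal(GenomicRanges::width(asym["gp"]),
               GenomicRanges::width(asym["gm"]))

  far <- toy_genes(data.frame(chrom = "chr1", s0 = 5000L, e0 = 6000L,
                              id = "goff", strand = "+"))
  expect_error(promoter_window(far, 100L, 100L,
                               seqlengths = c(chr1 = 3000L)),
               "off chromosome")
})
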