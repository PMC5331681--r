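# Format readers/writers: parsing contracts, validation errors, round trips.

test_that("BED6 peaks parse with validated widths and preserved order", {
  f <- withr::local_tempfile(fileext = ".bed")
  writeLines(c("# a comment",
               "chr1\t100\t200\tpkA\t5\t.",
               "chr1\t500\t750\tpkB\t.\t.",
               "chr2\t9\t10\tpkC\t0\t."), f)
  pk <- read_peaks(f, "bed6", timepoint = "t2", replicate = "rep2")
  expect_length(pk, 3L)
  expect_identical(mcols(pk)$peak_id, c("pkA", "pkB", "pkC"))
  expect_identical(width(pk), c(100L, 250L, 1L))
  expect_identical(start(pk), c(101L, 501L, 10L))   # 0-based -> 1-based
  expect_identical(unique(mcols(pk)$timepoint), "t2")
  expect_identical(mcols(pk)$enrichment, c(5, NA, 0))
})

test_that("malformed peak records fail naming the offending line", {
  f <- withr::local_tempfile(fileext = ".narrowPeak")
  ok <- "chr1\t10\t60\tp%d\t0\t.\t3.2\t-1\t-1\t25"
  writeLines(c(sprintf(ok, 1), "chr1\t100\t100\tpX\t0\t.\t1\t-1\t-1\t0",
               sprintf(ok, 3)), f)
  expect_error(read_peaks(f, "narrowPeak"), "line 2")
  f2 <- withr::local_tempfile(fileext = ".bed")
  writeLines("chr1\t-5\t100\tp1\t0\t.", f2)
  expect_error(read_peaks(f2, "bed6"), "line 1")
  f3 <- withr::local_tempfile(fileext = ".bed")
  writeLines(c("chr1\t1\t100\tdup\t0\t.", "chr1\t200\t300\tdup\t0\t."), f3)
  expect_error(read_peaks(f3, "bed6"), "duplicate")
})

test_that("unknown chromosomes error only when sizes are supplied", {
  f <- withr::local_tempfile(fileext = ".bed")
  writeLines("chrZ\t10\t100\tp1\t0\t.", f)
  expect_silent(pk <- read_peaks(f, "bed6"))
  expect_error(read_peaks(f, "bed6", chrom_sizes = c(chr1 = 1000)),
               "unknown chromosome")
  f2 <- withr::local_tempfile(fileext = ".bed")
  writeLines("chr1\t900\t1100\tp1\t0\t.", f2)
  expect_error(read_peaks(f2, "bed6", chrom_sizes = c(chr1 = 1000)),
               "exceeds chromosome size")
})

test_that("peak BED round trip is the identity on random fixtures", {
  set.seed(7)
  n <- 1000
  s <- sample.int(5e5, n)
  w <- sample.int(2000, n)
  pk <- make_peaks(sample(c("chr1", "chr2", "chr3"), n, replace = TRUE),
                   s, s + w - 1, ids = sprintf("pk%04d", seq_len(n)))
  f <- withr::local_tempfile(fileext = ".bed")
  write_peaks(pk, f)
  back <- read_peaks(f, "bed6")
  expect_identical(as.character(seqnames(back)), as.character(seqnames(pk)))
  expect_identical(start(back), start(pk))
  expect_identical(end(back), end(pk))
  expect_identical(mcols(back)$peak_id, mcols(pk)$peak_id)
})

test_that("GTF exons shared across transcripts merge to the base-level union", {
  f <- withr::local_tempfile(fileext = ".gtf")
  writeLines(c(
    'chr1\tx\tgene\t100\t1000\t.\t+\t.\tgene_id "gA"; transcript_id "gA";',
    'chr1\tx\texon\t100\t200\t.\t+\t.\tgene_id "gA"; transcript_id "tx1";',
    'chr1\tx\texon\t400\t500\t.\t+\t.\tgene_id "gA"; transcript_id "tx1";',
    'chr1\tx\texon\t150\t250\t.\t+\t.\tgene_id "gA"; transcript_id "tx2";',
    'chr1\tx\texon\t400\t500\t.\t+\t.\tgene_id "gA"; transcript_id "tx2";'), f)
  g <- read_genes(f, "gtf")
  expect_length(g, 1L)
  ex <- mcols(g)$exons[[1]]
  expect_identical(start(ex), c(100L, 400L))
  expect_identical(end(ex), c(250L, 500L))     # 100-200 U 150-250 = 100-250
  expect_identical(sum(width(ex)), 151L + 101L)
})

test_that("minus-strand TSS is the gene end and exon overflow is an error", {
  # span [1000, 2000] 1-based closed == [999, 2000) 0-based half-open
  g <- make_genes("chr1", 1000, 2000, strand = "-", ids = "gM")
  expect_equal(unname(gene_tss(g)), 2000)
  f <- withr::local_tempfile(fileext = ".gtf")
  writeLines(c(
    'chr1\tx\tgene\t100\t500\t.\t+\t.\tgene_id "gB"; transcript_id "gB";',
    'chr1\tx\texon\t100\t600\t.\t+\t.\tgene_id "gB"; transcript_id "tx";'), f)
  expect_error(read_genes(f, "gtf"), "outside its span")
})

test_that("BED12 genes round trip with exact exonic base totals", {
  set.seed(11)
  cfg <- sim_config("tiny", seed = 11)
  genome <- make_genome(cfg)
  f <- withr::local_tempfile(fileext = ".bed12")
  write_bed12(genome$genes, f)
  back <- read_genes(f, "bed12", chrom_sizes = genome$chrom_sizes)
  expect_identical(length(back), length(genome$genes))
  expect_identical(mcols(back)$gene_id, mcols(genome$genes)$gene_id)
  expect_identical(start(back), start(genome$genes))
  expect_identical(end(back), end(genome$genes))
  expect_identical(as.character(strand(back)), as.character(strand(genome$genes)))
  tot <- function(g) sum(width(unlist(mcols(g)$exons)))
  expect_identical(tot(back), tot(genome$genes))
  # GTF round trip of the same models
  f2 <- withr::local_tempfile(fileext = ".gtf")
  write_gtf(genome$genes, f2)
  back2 <- read_genes(f2, "gtf")
  expect_identical(start(back2), start(genome$genes))
  expect_identical(tot(back2), tot(genome$genes))
})

test_that("DE tables parse missing padj and reject duplicates", {
  f <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("gene_id\tlog2FoldChange\tpadj",
               "g1\t-1.2\t0.001", "g2\t0.3\t0.8", "g3\t2.0\t.",
               "g4\t-0.1\t0.5", "g5\t0.0\t1.0"), f)
  de <- read_de_table(f)
  expect_identical(nrow(de), 5L)
  expect_identical(sum(is.na(de$padj)), 1L)
  expect_identical(de$log2fc[1], -1.2)
  f2 <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("gene_id\tlog2fc\tpadj", "g1\t1\t0.1", "g1\t2\t0.2"), f2)
  expect_error(read_de_table(f2), "duplicate gene_id")
})

test_that("bedGraph becomes a step vector; overlapping rows are an error", {
  f <- withr::local_tempfile(fileext = ".bedGraph")
  writeLines(c("chrA\t0\t10\t2.0", "chrA\t10\t20\t0.0"), f)
  cov <- read_coverage(f, chrom_sizes = c(chrA = 30))
  expect_false(cov$stranded)
  expect_equal(groscore:::.track_window(cov, "chrA", 5, 5), 2.0)
  expect_equal(groscore:::.track_window(cov, "chrA", 15, 15), 0.0)
  expect_equal(groscore:::.track_window(cov, "chrA", 25, 25), 0.0)
  f2 <- withr::local_tempfile(fileext = ".bedGraph")
  writeLines(c("chrA\t0\t10\t2.0", "chrA\t5\t20\t1.0"), f2)
  expect_error(read_coverage(f2), "overlapping bedGraph")
  f3 <- withr::local_tempfile(fileext = ".bedGraph")
  writeLines("chrA\t0\t10\t-1", f3)
  expect_error(read_coverage(f3), "negative")
})

test_that("coverage track round trips through bedGraph", {
  set.seed(3)
  cfg <- sim_config("tiny", seed = 3)
  sim <- simulate_dataset(cfg)
  fp <- withr::local_tempfile(fileext = ".bedGraph")
  fm <- withr::local_tempfile(fileext = ".bedGraph")
  write_bedgraph(sim$coverage, fp, "+")
  write_bedgraph(sim$coverage, fm, "-")
  back <- read_coverage(fp, fm, chrom_sizes = sim$chrom_sizes)
  expect_true(back$stranded)
  expect_equal(back$plus, sim$coverage$plus)
  expect_equal(back$minus, sim$coverage$minus)
})
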