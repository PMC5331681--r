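# Replicate intersection, temporal classes, nearest-gene assignment,
# feature annotation and summaries, each against naive oracles.

test_that("replicate intersection keeps 1 bp overlaps, drops abutments", {
  a <- make_peaks("chr1", 100, 199, replicate = "rep1")   # [100,200) 0-based
  b <- make_peaks("chr1", 199, 299, replicate = "rep2")   # [199,300)
  out <- intersect_replicates(a, b)
  expect_length(out, 1L)
  expect_identical(start(out), 100L)
  expect_identical(end(out), 299L)                        # merged union span
  # half-open abutment: [100,200) and [200,300) share no base
  b2 <- make_peaks("chr1", 200, 299, replicate = "rep2")
  expect_length(intersect_replicates(a, b2), 0L)
  expect_warning(intersect_replicates(a, make_peaks("chr1", 1, 2)[0]),
                 "empty")
})

test_that("intersection span mode returns only jointly covered bases", {
  a <- make_peaks("chr1", 100, 250, replicate = "rep1")
  b <- make_peaks("chr1", 200, 400, replicate = "rep2")
  out <- intersect_replicates(a, b, span = "intersection")
  expect_identical(start(out), 200L)
  expect_identical(end(out), 250L)
})

test_that("replicate intersection is symmetric and idempotent", {
  for (seed in 1:5) {
    inst <- random_instance(seed, n_peaks = 60)
    a <- inst$peaks[1:30]
    b <- inst$peaks[31:60]
    mcols(b)$replicate <- "rep2"
    ab <- intersect_replicates(a, b)
    ba <- intersect_replicates(b, a)
    expect_identical(granges(ab), granges(ba))
    self <- intersect_replicates(a, a)
    self2 <- intersect_replicates(self, self)
    expect_identical(granges(self), granges(self2))
  }
})

test_that("replicate intersection equals the all-pairs overlap-graph oracle", {
  for (seed in 1:8) {
    set.seed(seed * 100)
    n <- 200
    sa <- sample.int(1e6 - 2000, n); wa <- sample.int(1500, n)
    sb <- sample.int(1e6 - 2000, n); wb <- sample.int(1500, n)
    a <- make_peaks("chr1", sa, sa + wa - 1, replicate = "rep1")
    b <- make_peaks("chr1", sb, sb + wb - 1, replicate = "rep2")
    got <- intersect_replicates(a, b)
    want <- oracle_intersect(a, b)
    expect_identical(length(got), nrow(want))
    expect_identical(start(got), as.integer(want$start))
    expect_identical(end(got), as.integer(want$end))
    expect_true(all(width(GenomicRanges::reduce(got, min.gapwidth = 0L)) ==
                      width(got)))    # pairwise non-overlapping
  }
})

test_that("temporal classes partition the region universe", {
  one <- make_peaks("chr1", 1000, 1500)
  sets <- list(t1 = one, t2 = one, t3 = one)
  cl <- classify_temporal(sets)
  expect_identical(cl$n_regions, 1L)
  expect_identical(unname(cl$counts[["t1,t2,t3"]]), 1L)
  expect_equal(cl$fraction_constitutive, 1.0)
  disjoint <- list(t1 = make_peaks("chr1", 1000, 1500),
                   t2 = make_peaks("chr1", 5000, 5400),
                   t3 = make_peaks("chr2", 100, 300))
  cl2 <- classify_temporal(disjoint)
  expect_identical(cl2$n_regions, 3L)
  expect_equal(cl2$fraction_unique, 1.0)
  expect_identical(sum(cl2$counts), cl2$n_regions)
})

test_that("planted temporal memberships are recovered from the generator", {
  cfg <- sim_config("tiny", seed = 21, replicate_jitter_sd = 0,
                    n_noise_peaks = 0)
  genome <- make_genome(cfg)
  pk <- plant_peaks(cfg, genome)
  reps <- lapply(c(t1 = "t1", t2 = "t2", t3 = "t3"), function(tp) {
    intersect_replicates(pk$peaks[[tp]]$rep1, pk$peaks[[tp]]$rep2)
  })
  cl <- classify_temporal(reps)
  planted <- pk$truth$regions[pk$truth$regions$kind == "planted", ]
  expect_identical(cl$n_regions, nrow(planted))
  got <- table(factor(mcols(cl$regions)$membership,
                      levels = names(cfg$temporal_class_weights)))
  want <- table(factor(planted$membership,
                       levels = names(cfg$temporal_class_weights)))
  expect_identical(as.integer(got), as.integer(want))
})

test_that("nearest-gene assignment follows overlap, tie and strand rules", {
  genes <- make_genes("chr1", c(1000, 3001), c(1999, 4000),
                      strand = c("+", "-"), ids = c("gA", "gB"))
  inside <- make_peaks("chr1", 1200, 1300)
  a <- assign_nearest_gene(inside, genes)
  expect_identical(a$gene_id, "gA")
  expect_identical(a$signed_distance, 0)
  # peak [2500,2500] is exactly 500 bp from gA's end and gB's start, and
  # both TSSs (1000 and 4000) are 1500 bp away: full tie, lexicographic win
  mid <- make_peaks("chr1", 2500, 2500)
  expect_identical(assign_nearest_gene(mid, genes)$gene_id, "gA")
  # same geometry but gB on plus strand: its TSS (3001) is closer, so the
  # TSS-gap rule decides before the lexicographic one
  genes2 <- make_genes("chr1", c(1000, 3001), c(1999, 4000),
                       strand = c("+", "+"), ids = c("gA", "gB"))
  expect_identical(assign_nearest_gene(mid, genes2)$gene_id, "gB")
  # upstream sign: peak left of a plus-strand gene is upstream (negative)
  left <- make_peaks("chr1", 500, 600)
  a3 <- assign_nearest_gene(left, genes)
  expect_identical(a3$gene_id, "gA")
  expect_identical(a3$signed_distance, -400)   # base adjacent to gene is 1
  # peak right of a minus-strand gene is upstream of its TSS
  right <- make_peaks("chr1", 4500, 4600)
  a4 <- assign_nearest_gene(right, genes)
  expect_identical(a4$gene_id, "gB")
  expect_identical(a4$signed_distance, -500)
  expect_warning(
    out <- assign_nearest_gene(make_peaks("chrZ", 10, 20), genes),
    "no genes")
  expect_true(out$no_gene)
})

test_that("nearest-gene assignment equals the exhaustive scan", {
  for (seed in 1:6) {
    inst <- random_instance(seed + 50, n_genes = 100, n_peaks = 1000,
                            chrom_len = 5e5, n_chroms = 2)
    got <- assign_nearest_gene(inst$peaks, inst$genes)
    pg <- plain_genes(inst$genes)
    pchrom <- as.character(seqnames(inst$peaks))
    want <- lapply(seq_along(inst$peaks), function(i) {
      oracle_nearest_gene(pchrom[i], start(inst$peaks)[i],
                          end(inst$peaks)[i], pg)
    })
    expect_identical(got$gene_id,
                     vapply(want, `[[`, character(1), "gene_id"))
    expect_identical(got$signed_distance,
                     vapply(want, `[[`, numeric(1), "signed"))
  }
})

test_that("peaks-per-gene histogram and mean follow the definition", {
  genes <- make_genes("chr1", c(1000, 50000), c(1999, 50999),
                      ids = c("gA", "gB"))
  three <- make_peaks("chr1", c(900, 1500, 2100), c(950, 1600, 2200))
  ppg <- peaks_per_gene(assign_nearest_gene(three, genes))
  expect_identical(as.integer(names(ppg$histogram)), 3L)
  expect_equal(ppg$mean, 3.0)
  expect_equal(ppg$fraction_multi, 1.0)
  genes4 <- make_genes("chr1", c(1, 3, 5, 7) * 10000,
                       c(1, 3, 5, 7) * 10000 + 999)
  four <- make_peaks("chr1", c(1, 3, 5, 7) * 10000 + 100,
                     c(1, 3, 5, 7) * 10000 + 200)
  ppg4 <- peaks_per_gene(assign_nearest_gene(four, genes4))
  expect_equal(ppg4$mean, 1.0)
  expect_equal(ppg4$fraction_multi, 0.0)
})

test_that("feature annotation matches the brute-force classifier", {
  # hand-built: promoter beats exon beats intron beats intergenic
  ex <- GRangesList(gA = GRanges("chr1", IRanges(c(1000, 1600), c(1199, 1999))))
  genes <- make_genes("chr1", 1000, 1999, ids = "gA", exons = ex)
  expect_identical(
    as.character(annotate_feature(make_peaks("chr1", 990, 1010), genes)$category),
    "promoter")
  expect_identical(
    as.character(annotate_feature(make_peaks("chr1", 1550, 1580), genes,
                                  promoter_window = 200)$category),
    "intron")
  expect_identical(
    as.character(annotate_feature(make_peaks("chr1", 1700, 1750), genes,
                                  promoter_window = 200)$category),
    "exon")
  expect_identical(
    as.character(annotate_feature(make_peaks("chr1", 9000, 9100), genes)$category),
    "intergenic")
  # randomized instances against the per-base oracle
  for (seed in 1:5) {
    cfg <- sim_config("tiny", seed = seed, n_genes = 30)
    genome <- make_genome(cfg)
    set.seed(seed)
    s <- sample.int(4.9e5, 80)
    pk <- make_peaks("chr1", s, s + sample.int(1500, 80) - 1)
    got <- annotate_feature(pk, genome$genes)
    pg <- plain_genes(genome$genes)
    want <- vapply(seq_along(pk), function(i) {
      oracle_annotate(start(pk)[i], end(pk)[i],
                      as.character(seqnames(pk))[i], pg)
    }, character(1))
    expect_identical(as.character(got$category), want)
  }
})

test_that("TSS distance profile signs distances by gene strand", {
  genes <- make_genes("chr1", c(10000, 30000), c(10999, 30999),
                      strand = c("+", "-"), ids = c("gP", "gM"))
  # width-201 peak centered exactly on the plus-strand TSS
  center <- make_peaks("chr1", 10000 - 100, 10000 + 100)
  pr <- tss_distance_profile(center, genes, bin = 50, range = 1000)
  expect_identical(pr$distances$distance, 0)
  # midpoint 100 bp 5' of the minus-strand TSS (30999) is at 31099
  up_minus <- make_peaks("chr1", 31099, 31099)
  pr2 <- tss_distance_profile(up_minus, genes, bin = 50, range = 1000)
  expect_identical(pr2$distances$gene_id, "gM")
  expect_identical(pr2$distances$distance, -100)
  expect_identical(sum(pr2$counts), 1L)
})

test_that("peaks planted around TSSs put the profile mode at zero", {
  cfg <- sim_config("tiny", seed = 5, n_genes = 60)
  genome <- make_genome(cfg)
  set.seed(5)
  tss <- gene_tss(genome$genes)
  mid <- round(rnorm(300, sample(tss, 300, replace = TRUE), 200))
  pk <- make_peaks("chr1", mid - 50, mid + 50)
  pr <- tss_distance_profile(pk, genome$genes, bin = 200, range = 2000)
  # distances are centered on the TSS, so the mode sits in one of the two
  # bins adjacent to zero
  expect_true(which.max(as.integer(pr$counts)) %in% c(10L, 11L))
})

test_that("width summary reports median and quartiles", {
  pk <- make_peaks("chr1", seq(1, 1000, 100) * 10,
                   seq(1, 1000, 100) * 10 + c(99, 199, 299, 399, 499,
                                              599, 699, 799, 899, 999))
  ws <- width_summary(pk)
  expect_identical(ws$n, 10L)
  expect_equal(ws$median, 550)
  expect_equal(ws$q1, 325)
  expect_equal(ws$q3, 775)
})
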