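# Promoter-proximal density ratios, metagene profiles, and the two
# enrichment tests.

make_track <- function(chrom_len, segments, minus_segments = NULL) {
  df <- function(seg) {
    if (is.null(seg)) return(NULL)
    data.frame(chrom = "chrA", start = seg[, 1] - 1, end = seg[, 2],
               value = seg[, 3])
  }
  to_rle <- function(seg) {
    if (is.null(seg)) {
      return(groscore:::.bedgraph_to_rle(
        data.frame(chrom = character(0), start = numeric(0),
                   end = numeric(0), value = numeric(0)),
        c(chrA = chrom_len)))
    }
    groscore:::.bedgraph_to_rle(df(seg), c(chrA = chrom_len))
  }
  coverage_track(to_rle(segments),
                 if (is.null(minus_segments)) NULL else to_rle(minus_segments))
}

test_that("pausing ratio integrates the two windows correctly", {
  genes <- make_genes("chrA", 1001, 2000, ids = "gU")
  uniform <- make_track(5000, cbind(1001, 2000, 2.0))
  r <- pausing_ratio(genes, uniform)
  expect_equal(r$ratio, 1.0)
  expect_equal(r$proximal_density, 2.0)
  # all signal in the first 300 bp: body density zero, ratio missing
  front <- make_track(5000, cbind(1001, 1300, 4.0))
  r2 <- pausing_ratio(genes, front)
  expect_equal(r2$body_density, 0)
  expect_true(is.na(r2$ratio))
  expect_false(r2$excluded)
  # two-level track: proximal 10, body 2 -> ratio 5 by direct integration
  two <- make_track(5000, rbind(cbind(1001, 1300, 10.0),
                                cbind(1301, 2000, 2.0)))
  expect_equal(pausing_ratio(genes, two)$ratio, 5.0)
  # minus-strand gene reads its proximal window at the right edge
  gm <- make_genes("chrA", 1001, 2000, strand = "-", ids = "gM")
  two_m <- make_track(5000, NULL,
                      rbind(cbind(1001, 1700, 2.0), cbind(1701, 2000, 10.0)))
  expect_equal(pausing_ratio(gm, two_m)$ratio, 5.0)
  # short gene flagged excluded
  short <- make_genes("chrA", 100, 500, ids = "gS")
  expect_true(pausing_ratio(short, uniform)$excluded)
  # scale invariance
  scaled <- make_track(5000, rbind(cbind(1001, 1300, 30.0),
                                   cbind(1301, 2000, 6.0)))
  expect_equal(pausing_ratio(genes, scaled)$ratio, 5.0)
})

test_that("metagene profiles are area-preserving and strand-aware", {
  genes <- make_genes("chrA", 1001, 2000, ids = "gU")
  uniform <- make_track(5000, cbind(1001, 2000, 3.0))
  mg <- metagene(genes, uniform, n_bins = 20)
  expect_equal(mg$profile, rep(1 / 20, 20))
  expect_equal(sum(mg$profile), 1)
  # minus-strand gene: its 5' end is the genomic right, so coverage rising
  # toward the right flips into a profile that peaks at bin 1
  gm <- make_genes("chrA", 1001, 2000, strand = "-", ids = "gM")
  rising_right_m <- make_track(5000, NULL,
                               cbind(1000 + seq(1, 1000, 100),
                                     1000 + seq(100, 1000, 100),
                                     1:10))
  mgm <- metagene(gm, rising_right_m, n_bins = 10)
  expect_true(all(diff(mgm$profile) < 0))
  expect_equal(mgm$profile[1], 10 / sum(1:10))
  # the strand-mirrored plus-strand instance gives the identical profile
  gp <- make_genes("chrA", 1001, 2000, strand = "+", ids = "gP")
  falling_right_p <- make_track(5000, cbind(1000 + seq(1, 1000, 100),
                                            1000 + seq(100, 1000, 100),
                                            10:1))
  mgp <- metagene(gp, falling_right_p, n_bins = 10)
  expect_equal(mgp$profile, mgm$profile)
  # exact fractional binning: 1000 bp into 3 bins splits areas exactly
  mg3 <- metagene(genes, uniform, n_bins = 3)
  expect_equal(mg3$profile, rep(1 / 3, 3))
  expect_error(metagene(genes, uniform, n_bins = 1500), "fractional")
  expect_equal(metagene(genes, uniform, n_bins = 1500,
                        fractional = TRUE)$n_bins, 1500L)
})

test_that("permutation enrichment separates planted ratios and flips sign", {
  # slight jitter keeps the median statistic continuous so the planted
  # separation is maximally significant
  set.seed(44)
  rec <- data.frame(gene_id = sprintf("g%03d", 1:100),
                    ratio = c(5.0, 1.0)[rep(1:2, each = 50)] *
                      exp(rnorm(100, 0, 0.05)))
  hi <- rec$gene_id[1:50]
  lo <- rec$gene_id[51:100]
  r <- compare_sets(rec, hi, lo, n_perm = 999, seed = 10)
  expect_equal(r$p_value, 1 / 1000)
  expect_equal(r$statistic, log(5), tolerance = 0.05)
  swapped <- compare_sets(rec, lo, hi, n_perm = 99, seed = 10)
  expect_equal(swapped$statistic, -r$statistic)
  # undefined ratios are excluded and counted
  rec$ratio[1] <- NA
  r2 <- compare_sets(rec, hi, lo, n_perm = 99, seed = 1)
  expect_identical(r2$n_excluded, 1L)
  expect_identical(r2$n_target, 49L)
  expect_error(compare_sets(rec, hi, c(lo, hi[1])), "disjoint")
})

test_that("categorical enrichment equals the exact hypergeometric tail", {
  # targets = all genes of a class occupying half the universe -> fold 2
  uni <- sprintf("g%02d", 1:40)
  cls <- stats::setNames(rep(c("stalled", "active"), each = 20), uni)
  r <- categorical_enrichment(uni[1:20], uni, cls, "stalled")
  expect_equal(r$statistic, 2.0)
  expect_lt(r$p_value, 1e-9)
  # no target in class: fold 0, p = 1
  r0 <- categorical_enrichment(uni[21:30], uni, cls, "stalled")
  expect_equal(r0$statistic, 0)
  expect_equal(r0$p_value, 1)
  # random contingency instances vs explicit enumeration of the tail
  set.seed(8)
  for (i in 1:20) {
    N <- sample(20:60, 1)
    K <- sample(5:(N - 5), 1)
    n <- sample(3:(N - 1), 1)
    uni <- sprintf("u%03d", 1:N)
    cls <- stats::setNames(
      sample(c(rep("yes", K), rep("no", N - K))), uni)
    targ <- sample(uni, n)
    k <- sum(cls[targ] == "yes")
    tail_p <- sum(vapply(k:min(K, n), function(j) {
      choose(K, j) * choose(N - K, n - j) / choose(N, n)
    }, numeric(1)))
    r <- categorical_enrichment(targ, uni, cls, "yes")
    expect_equal(r$p_value, tail_p, tolerance = 1e-10)
  }
  expect_error(categorical_enrichment(uni[1], uni, cls, "absent"), "absent")
})

test_that("top-quartile classes split a pausing index as advertised", {
  idx <- stats::setNames(1:100, sprintf("g%03d", 1:100))
  cl <- quartile_classes(idx)
  expect_identical(sum(cl == "top_quartile"), 25L)
  expect_true(all(names(which(cl == "top_quartile")) == sprintf("g%03d", 76:100)))
})

test_that("generated coverage recovers configured ratios exactly without noise", {
  cfg <- sim_config("tiny", seed = 6, coverage_noise = FALSE)
  sim <- simulate_dataset(cfg)
  pr <- pausing_ratio(sim$genes, sim$coverage,
                      proximal_window = cfg$proximal_window)
  ok <- !pr$excluded & !is.na(pr$ratio)
  expect_true(all(ok))
  expect_equal(pr$ratio, unname(sim$truth$ratio[pr$gene_id]),
               tolerance = 1e-9)
  # targets vs background separate at the minimal permutation p
  targ <- sim$truth$true_targets
  bg <- setdiff(pr$gene_id, targ)
  r <- compare_sets(pr, targ, bg, n_perm = 999, seed = 2)
  expect_equal(r$p_value, 1 / 1000)
})
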