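# Promoter-proximal vs gene-body transcript density from
# chromatin-associated RNA coverage, metagene profiles, and gene-set
# enrichment tests (permutation and hypergeometric).

#' Promoter-proximal to gene-body density ratio
#'
#' For each gene, integrates strand-matched coverage over the first
#' `proximal_window` bases downstream of the TSS and over the remainder of
#' the gene span, converts both to densities (reads per bp), and reports
#' their ratio — a proxy for promoter-proximal Pol II pausing. Genes
#' shorter than `min_gene_length` are flagged excluded; a zero body density
#' leaves the ratio missing (infinite pausing is not folded into the
#' statistic).
#'
#' @param genes Gene models.
#' @param coverage A `coverage_track` (see [read_coverage()]).
#' @param proximal_window Proximal window length in bp (default 300).
#' @param min_gene_length Minimum analyzable gene length in bp
#'   (default 600).
#' @return A data.frame with one row per gene: `gene_id`,
#'   `proximal_density`, `body_density`, `ratio`, `excluded`.
#' @export
pausing_ratio <- function(genes, coverage, proximal_window = 300L,
                          min_gene_length = 600L) {
  .validate_gene_models(genes)
  stopifnot(inherits(coverage, "coverage_track"))
  .assert_scalar_number(proximal_window, "proximal_window", lower = 1)
  .assert_scalar_number(min_gene_length, "min_gene_length",
                        lower = proximal_window + 1)
  n <- length(genes)
  gid <- S4Vectors::mcols(genes)$gene_id
  out <- data.frame(gene_id = gid, proximal_density = NA_real_,
                    body_density = NA_real_, ratio = NA_real_,
                    excluded = FALSE, stringsAsFactors = FALSE)
  chrom <- as.character(GenomeInfoDb::seqnames(genes))
  gs <- GenomicRanges::start(genes)
  ge <- GenomicRanges::end(genes)
  str <- as.character(GenomicRanges::strand(genes))
  for (i in seq_len(n)) {
    len <- ge[i] - gs[i] + 1
    if (len < min_gene_length) {
      out$excluded[i] <- TRUE
      next
    }
    v <- .track_window(coverage, chrom[i], gs[i], ge[i], str[i])
    if (str[i] == "-") v <- rev(v)          # orient 5' -> 3'
    prox <- v[seq_len(proximal_window)]
    body <- v[(proximal_window + 1):len]
    out$proximal_density[i] <- sum(prox) / proximal_window
    out$body_density[i] <- sum(body) / (len - proximal_window)
    if (out$body_density[i] > 0) {
      out$ratio[i] <- out$proximal_density[i] / out$body_density[i]
    }
  }
  out
}

# Exact area-preserving resampling of a per-bp vector to n_bins: the
# cumulative coverage is piecewise linear, so linear interpolation at the
# bin boundaries is exact.
.rebin_exact <- function(v, n_bins) {
  L <- length(v)
  cum <- c(0, cumsum(v))
  bounds <- L * (0:n_bins) / n_bins
  diff(stats::approx(0:L, cum, xout = bounds)$y)
}

#' Metagene coverage profile of a gene set
#'
#' Each gene's strand-matched coverage is oriented 5' to 3',
#' length-normalized to `n_bins` by exact area-preserving binning,
#' normalized to sum to 1 (so every gene contributes equally regardless of
#' expression level), and the profile is the unweighted mean over genes.
#' Genes with zero total coverage are skipped.
#'
#' @param genes Gene models.
#' @param coverage A `coverage_track`.
#' @param n_bins Number of profile bins (default 100).
#' @param fractional Allow genes shorter than `n_bins` bp (fractional
#'   binning); when `FALSE` such genes are an error.
#' @return An object of class `metagene_profile`: `profile` (length
#'   `n_bins`, averaging per-gene distributions that each sum to 1) and
#'   `n_genes` used.
#' @export
metagene <- function(genes, coverage, n_bins = 100L, fractional = FALSE) {
  .validate_gene_models(genes)
  .assert_scalar_number(n_bins, "n_bins", lower = 2)
  if (length(genes) == 0L) stop("empty gene set", call. = FALSE)
  if (!fractional && any(GenomicRanges::width(genes) < n_bins)) {
    stop("gene shorter than n_bins bp; enable fractional binning",
         call. = FALSE)
  }
  chrom <- as.character(GenomeInfoDb::seqnames(genes))
  gs <- GenomicRanges::start(genes)
  ge <- GenomicRanges::end(genes)
  str <- as.character(GenomicRanges::strand(genes))
  acc <- numeric(n_bins)
  used <- 0L
  for (i in seq_along(genes)) {
    v <- .track_window(coverage, chrom[i], gs[i], ge[i], str[i])
    if (str[i] == "-") v <- rev(v)
    tot <- sum(v)
    if (tot == 0) next
    acc <- acc + .rebin_exact(v, n_bins) / tot
    used <- used + 1L
  }
  if (used == 0L) stop("no gene in the set has nonzero coverage", call. = FALSE)
  structure(list(profile = acc / used, n_bins = as.integer(n_bins),
                 n_genes = used),
            class = "metagene_profile")
}

#' @export
print.metagene_profile <- function(x, ...) {
  cat(sprintf("metagene profile over %d genes, %d bins; first/last decile mean ratio %.2f\n",
              x$n_genes, x$n_bins,
              mean(utils::head(x$profile, x$n_bins %/% 10)) /
                mean(utils::tail(x$profile, x$n_bins %/% 10))))
  invisible(x)
}

#' Permutation test for pausing-ratio enrichment in a gene set
#'
#' Statistic: difference of median log pausing ratios (targets minus
#' background). The p-value is the one-sided add-one permutation p over
#' `n_perm` relabelings of the pooled genes, testing whether targets have
#' higher promoter-proximal bias than background. Genes with an undefined
#' ratio (zero body density) are excluded and counted separately.
#'
#' @param records Pausing table from [pausing_ratio()].
#' @param target_set,background_set Character vectors of gene ids; the sets
#'   must be disjoint (pass background = universe minus targets for a
#'   universe comparison).
#' @param n_perm Number of permutations (default 999).
#' @param seed Integer seed.
#' @return An object of class `set_enrichment`: `statistic`, `p_value`,
#'   `method = "permutation-of-gene-labels"`, `n_excluded`.
#' @export
compare_sets <- function(records, target_set, background_set,
                         n_perm = 999L, seed = 1L) {
  stopifnot(all(c("gene_id", "ratio") %in% names(records)))
  .assert_scalar_number(n_perm, "n_perm", lower = 1)
  if (length(intersect(target_set, background_set))) {
    stop("target and background sets must be disjoint", call. = FALSE)
  }
  r <- stats::setNames(records$ratio, records$gene_id)
  rt <- r[intersect(target_set, names(r))]
  rb <- r[intersect(background_set, names(r))]
  n_excl <- sum(is.na(rt)) + sum(is.na(rb))
  rt <- rt[!is.na(rt)]
  rb <- rb[!is.na(rb)]
  if (length(rt) == 0L || length(rb) == 0L) {
    stop("no usable pausing ratios in one of the sets", call. = FALSE)
  }
  stat <- function(a, b) stats::median(log(a)) - stats::median(log(b))
  obs <- stat(rt, rb)
  pool <- c(rt, rb)
  nt <- length(rt)
  old <- .save_rng()
  on.exit(.restore_rng(old), add = TRUE)
  set.seed(.derive_seed(seed, "compare_sets"))
  perm <- numeric(n_perm)
  for (i in seq_len(n_perm)) {
    idx <- sample.int(length(pool), nt)
    perm[i] <- stat(pool[idx], pool[-idx])
  }
  structure(list(statistic = obs,
                 p_value = (sum(perm >= obs) + 1) / (n_perm + 1),
                 method = "permutation-of-gene-labels",
                 n_perm = as.integer(n_perm),
                 n_target = nt, n_background = length(rb),
                 n_excluded = n_excl, seed = as.integer(seed)),
            class = "set_enrichment")
}

#' Hypergeometric enrichment of a categorical Pol II class
#'
#' One-sided hypergeometric test for overrepresentation of
#' `class_of_interest` among the targets, with fold-enrichment
#' `(k/n) / (K/N)` where `k` of the `n` targets and `K` of the `N` universe
#' genes carry the class.
#'
#' @param target_set Character vector of target gene ids (every target must
#'   be in the universe and classed).
#' @param universe Character vector of universe gene ids.
#' @param class_table Named character vector mapping gene_id to class.
#' @param class_of_interest The class tested for overrepresentation (must
#'   occur in the universe).
#' @return An object of class `set_enrichment` with `statistic`
#'   (fold-enrichment), `p_value`, `method = "hypergeometric"`, and the
#'   contingency counts.
#' @export
categorical_enrichment <- function(target_set, universe, class_table,
                                   class_of_interest) {
  if (!all(target_set %in% universe)) {
    stop("every target must be in the universe", call. = FALSE)
  }
  if (!all(universe %in% names(class_table))) {
    stop("every universe gene must be classed", call. = FALSE)
  }
  cls <- class_table[universe]
  if (!class_of_interest %in% cls) {
    stop("class '", class_of_interest, "' absent from the universe",
         call. = FALSE)
  }
  N <- length(universe)
  K <- sum(cls == class_of_interest)
  n <- length(target_set)
  k <- sum(class_table[target_set] == class_of_interest)
  p <- stats::phyper(k - 1, K, N - K, n, lower.tail = FALSE)
  structure(list(statistic = (k / n) / (K / N), p_value = p,
                 method = "hypergeometric",
                 k = k, n = n, K = K, N = N),
            class = "set_enrichment")
}

#' Split a numeric pausing index into top-quartile vs rest classes
#'
#' Convenience for enrichment tests phrased as "high pausing indices
#' (top quartile)".
#'
#' @param index Named numeric vector of pausing indices (gene_id names).
#' @return Named character vector with values `"top_quartile"` / `"rest"`.
#' @export
quartile_classes <- function(index) {
  stopifnot(!is.null(names(index)))
  q3 <- stats::quantile(index, 0.75, na.rm = TRUE, names = FALSE)
  stats::setNames(ifelse(index > q3, "top_quartile", "rest"), names(index))
}

#' @export
print.set_enrichment <- function(x, ...) {
  if (x$method == "hypergeometric") {
    cat(sprintf("hypergeometric enrichment: %d/%d targets vs %d/%d universe, fold %.2f, p = %.3g\n",
                x$k, x$n, x$K, x$N, x$statistic, x$p_value))
  } else {
    cat(sprintf("permutation test (%d perms): median log-ratio difference %.3f, p = %.3g\n",
                x$n_perm, x$statistic, x$p_value))
  }
  invisible(x)
}
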