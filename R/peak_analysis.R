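# Reproducible-peak derivation, temporal dynamics, peak-to-gene assignment,
# genomic-feature annotation, width/TSS-distance summaries, and the Monte
# Carlo peaks-per-gene null.

# Connected components of a set of ranges under "overlap >= min_overlap bp",
# via union-find over the overlap graph. Returns a component id per range.
.overlap_components <- function(gr, min_overlap = 1L) {
  n <- length(gr)
  parent <- seq_len(n)
  find <- function(i) {
    while (parent[i] != i) {
      parent[i] <- parent[parent[i]]
      i <- parent[i]
    }
    i
  }
  hits <- GenomicRanges::findOverlaps(gr, minoverlap = min_overlap,
                                      drop.self = TRUE, drop.redundant = TRUE,
                                      ignore.strand = TRUE)
  for (k in seq_along(hits)) {
    a <- find(S4Vectors::queryHits(hits)[k])
    b <- find(S4Vectors::subjectHits(hits)[k])
    if (a != b) parent[b] <- a
  }
  vapply(seq_len(n), find, integer(1L))
}

#' Replicate-reproducible peaks for one timepoint
#'
#' Peaks supported by both replicates — a minimum 1 bp overlap between
#' replicates by default — are kept for downstream analysis. Overlapping
#' peaks are grouped into maximal mutually-touching clusters of the pooled
#' replicate set; every cluster containing at least one peak from each
#' replicate yields one output region. By default the merged union span of
#' the supporting cluster is returned (preserving the full extent of the
#' binding evidence for width and assignment analyses); `span =
#' "intersection"` returns only the bases covered by both replicates
#' instead.
#'
#' @param rep_a,rep_b Peak GRanges for the two replicates of one timepoint
#'   (as from [read_peaks()]).
#' @param min_overlap Minimum overlap in bp for two peaks to count as
#'   touching. Half-open abutment is 0 bp and never suffices.
#' @param span `"union"` (default) or `"intersection"`.
#' @return GRanges of non-overlapping reproducible regions with metadata
#'   columns `peak_id`, `timepoint`, `n_rep_a`, `n_rep_b`.
#' @export
intersect_replicates <- function(rep_a, rep_b, min_overlap = 1L,
                                 span = c("union", "intersection")) {
  span <- match.arg(span)
  .assert_scalar_number(min_overlap, "min_overlap", lower = 1)
  tp_a <- unique(S4Vectors::mcols(rep_a)$timepoint)
  tp_b <- unique(S4Vectors::mcols(rep_b)$timepoint)
  if (length(tp_a) == 1L && length(tp_b) == 1L && !identical(tp_a, tp_b)) {
    stop("replicates come from different timepoints: ", tp_a, " vs ", tp_b,
         call. = FALSE)
  }
  timepoint <- if (length(tp_a) == 1L) tp_a else NA_character_
  if (length(rep_a) == 0L || length(rep_b) == 0L) {
    warning("empty replicate peak set; no reproducible peaks")
    out <- GenomicRanges::GRanges()
    S4Vectors::mcols(out) <- S4Vectors::DataFrame(
      peak_id = character(0), timepoint = character(0),
      n_rep_a = integer(0), n_rep_b = integer(0))
    return(out)
  }
  a <- GenomicRanges::granges(rep_a)
  b <- GenomicRanges::granges(rep_b)
  GenomicRanges::strand(a) <- "*"
  GenomicRanges::strand(b) <- "*"
  pooled <- suppressWarnings(c(a, b))
  src <- rep(c("a", "b"), c(length(a), length(b)))
  comp <- .overlap_components(pooled, as.integer(min_overlap))
  has_a <- tapply(src == "a", comp, any)
  has_b <- tapply(src == "b", comp, any)
  good <- as.integer(names(has_a)[has_a & has_b])
  if (length(good) == 0L) {
    out <- GenomicRanges::GRanges()
    S4Vectors::mcols(out) <- S4Vectors::DataFrame(
      peak_id = character(0), timepoint = character(0),
      n_rep_a = integer(0), n_rep_b = integer(0))
    return(out)
  }
  keep <- comp %in% good
  spans <- unlist(range(GenomicRanges::split(pooled[keep],
                                             factor(comp[keep], levels = good))))
  n_a <- as.integer(tapply(src == "a", comp, sum)[as.character(good)])
  n_b <- as.integer(tapply(src == "b", comp, sum)[as.character(good)])
  if (span == "intersection") {
    both <- GenomicRanges::intersect(GenomicRanges::reduce(a),
                                     GenomicRanges::reduce(b),
                                     ignore.strand = TRUE)
    hit <- GenomicRanges::findOverlaps(both, spans, type = "within")
    idx <- S4Vectors::subjectHits(hit)
    out <- both[S4Vectors::queryHits(hit)]
    n_a <- n_a[idx]
    n_b <- n_b[idx]
  } else {
    out <- spans
  }
  o <- order(as.character(GenomeInfoDb::seqnames(out)),
             GenomicRanges::start(out))
  out <- out[o]
  S4Vectors::mcols(out) <- S4Vectors::DataFrame(
    peak_id = sprintf("%s_rp%04d", ifelse(is.na(timepoint), "tp", timepoint),
                      seq_along(out)),
    timepoint = timepoint,
    n_rep_a = n_a[o], n_rep_b = n_b[o])
  names(out) <- NULL
  out
}

#' Classify temporal binding dynamics across three timepoints
#'
#' Pools the reproducible peak sets of the three timepoints, groups them
#' into maximal overlapping regions, and assigns each region the subset of
#' timepoints with at least one peak overlapping it by `min_overlap` bp.
#' The seven non-empty membership classes partition the region universe.
#'
#' @param sets Named list of three reproducible peak GRanges; names are the
#'   timepoint labels (conventionally `t1`, `t2`, `t3`).
#' @param min_overlap Minimum overlap in bp for recurrence.
#' @return An object of class `temporal_classes`: region GRanges with a
#'   `membership` column, the 7 class counts, and the unique-to-one and
#'   constitutive fractions.
#' @export
classify_temporal <- function(sets, min_overlap = 1L) {
  stopifnot(is.list(sets), length(sets) == 3L, !is.null(names(sets)))
  tps <- names(sets)
  grs <- lapply(sets, function(g) {
    g <- GenomicRanges::granges(g)
    GenomicRanges::strand(g) <- "*"
    g
  })
  pooled <- suppressWarnings(do.call(c, unname(grs)))
  src <- rep(tps, lengths(grs))
  if (length(pooled) == 0L) stop("all three peak sets are empty", call. = FALSE)
  comp <- .overlap_components(pooled, as.integer(min_overlap))
  ids <- sort(unique(comp))
  regions <- unlist(range(GenomicRanges::split(pooled,
                                               factor(comp, levels = ids))))
  member <- vapply(ids, function(k) {
    paste(tps[tps %in% unique(src[comp == k])], collapse = ",")
  }, character(1L))
  class_levels <- c(tps,
                    paste(tps[c(1, 1, 2)], tps[c(2, 3, 3)], sep = ","),
                    paste(tps, collapse = ","))
  counts <- table(factor(member, levels = class_levels))
  S4Vectors::mcols(regions)$membership <- member
  names(regions) <- NULL
  o <- order(as.character(GenomeInfoDb::seqnames(regions)),
             GenomicRanges::start(regions))
  structure(list(
    regions = regions[o],
    counts = counts,
    n_regions = length(regions),
    fraction_unique = sum(counts[tps]) / length(regions),
    fraction_constitutive = unname(counts[paste(tps, collapse = ",")]) /
      length(regions)),
    class = "temporal_classes")
}

#' @export
print.temporal_classes <- function(x, ...) {
  cat("Temporal peak classes over", x$n_regions, "regions\n")
  print(x$counts)
  cat(sprintf("unique-to-one fraction: %.3f, constitutive fraction: %.3f\n",
              x$fraction_unique, x$fraction_constitutive))
  invisible(x)
}

#' Assign each peak to its closest gene
#'
#' A peak overlapping a gene span is assigned to that gene at distance 0;
#' otherwise to the gene minimizing the gap between closest edges. Ties are
#' broken deterministically: smaller gap to the TSS, then lexicographically
#' smaller `gene_id`. The signed distance is 0 for overlap, otherwise the
#' closest-edge distance in bp (the base adjacent to the gene is at
#' distance 1), negative when the peak lies upstream of the TSS relative to
#' the gene's strand.
#'
#' @param peaks Peak GRanges.
#' @param genes Gene models.
#' @return A data.frame with columns `peak_id`, `gene_id` (`NA` and flagged
#'   when the peak's chromosome carries no gene), `signed_distance`,
#'   `no_gene`.
#' @export
assign_nearest_gene <- function(peaks, genes) {
  .validate_gene_models(genes)
  pid <- S4Vectors::mcols(peaks)$peak_id
  if (is.null(pid)) pid <- sprintf("peak%d", seq_along(peaks))
  if (length(peaks) == 0L) {
    return(data.frame(peak_id = character(0), gene_id = character(0),
                      signed_distance = numeric(0), no_gene = logical(0)))
  }
  idx <- .gene_index(genes)
  hit <- .assign_nearest_core(as.character(GenomeInfoDb::seqnames(peaks)),
                              GenomicRanges::start(peaks),
                              GenomicRanges::end(peaks), idx)
  found <- !is.na(hit$gene)
  gi <- hit$gene[found]
  str <- idx$strand[gi]
  left <- GenomicRanges::end(peaks)[found] < idx$gs[gi]
  upstream <- (left & str == "+") | (!left & str == "-")
  magnitude <- ifelse(hit$gap[found] < 0, 0, hit$gap[found] + 1)
  out <- data.frame(peak_id = pid, gene_id = NA_character_,
                    signed_distance = NA_real_, no_gene = TRUE,
                    stringsAsFactors = FALSE)
  out$gene_id[found] <- idx$gid[gi]
  out$signed_distance[found] <- ifelse(upstream, -magnitude, magnitude)
  out$no_gene[found] <- FALSE
  if (any(out$no_gene)) {
    warning(sum(out$no_gene), " peak(s) on chromosome(s) with no genes")
  }
  out
}

# Precompute plain-numeric per-chromosome gene arrays so nearest-gene
# assignment (and the Monte Carlo null that repeats it thousands of times)
# runs without S4 dispatch in the inner loop. Tie rank is the C-locale
# lexicographic order of gene_id.
.gene_index <- function(genes) {
  gid <- S4Vectors::mcols(genes)$gene_id
  gs <- GenomicRanges::start(genes)
  ge <- GenomicRanges::end(genes)
  chrom <- as.character(GenomeInfoDb::seqnames(genes))
  rank <- integer(length(gid))
  rank[order(gid, method = "radix")] <- seq_along(gid)
  tss <- unname(gene_tss(genes))
  by_chrom <- split(seq_along(gid), chrom)
  list(gid = gid, gs = gs, ge = ge, tss = tss, rank = rank,
       strand = as.character(GenomicRanges::strand(genes)),
       by_chrom = by_chrom)
}

# For each peak, the closest gene under the tie rule (min edge gap, then
# min gap to TSS, then lexicographic gene_id). Returns the global gene row
# (NA when the chromosome has no genes) and the signed-free edge gap in
# intervening bases (negative when overlapping). Vectorized per chromosome
# over a peaks x genes gap matrix (chunked to bound memory); only rows with
# a distance tie fall back to the explicit tie-rule scan.
.assign_nearest_core <- function(chrom, ps, pe, idx) {
  n <- length(ps)
  gene <- rep(NA_integer_, n)
  gap_out <- rep(NA_real_, n)
  for (ch in unique(chrom)) {
    rows <- idx$by_chrom[[ch]]
    if (is.null(rows)) next
    ggs <- idx$gs[rows]
    gge <- idx$ge[rows]
    pk <- which(chrom == ch)
    chunk <- max(1L, floor(4e6 / length(rows)))
    for (lo in seq(1L, length(pk), by = chunk)) {
      sel <- pk[lo:min(lo + chunk - 1L, length(pk))]
      gap <- pmax(rep(ggs, each = length(sel)) - pe[sel] - 1,
                  ps[sel] - rep(gge, each = length(sel)) - 1)
      dim(gap) <- c(length(sel), length(rows))
      d <- pmax(gap, 0)
      jbest <- max.col(-d, ties.method = "first")
      dmin <- d[cbind(seq_along(sel), jbest)]
      tied <- rowSums(d == dmin) > 1L
      for (i in which(tied)) {
        cand <- which(d[i, ] == dmin[i])
        tss <- idx$tss[rows][cand]
        tgap <- ifelse(ps[sel[i]] <= tss & tss <= pe[sel[i]], 0,
                       pmin(abs(ps[sel[i]] - tss), abs(pe[sel[i]] - tss)))
        cand <- cand[tgap == min(tgap)]
        if (length(cand) > 1L) {
          cand <- cand[which.min(idx$rank[rows][cand])]
        }
        jbest[i] <- cand[1L]
      }
      gene[sel] <- rows[jbest]
      gap_out[sel] <- gap[cbind(seq_along(sel), jbest)]
    }
  }
  list(gene = gene, gap = gap_out)
}

#' Peaks per associated gene
#'
#' Counts, over genes with at least one assigned peak, how many peaks each
#' gene attracted; the mean is total assigned peaks over associated genes.
#'
#' @param assignments Output of [assign_nearest_gene()].
#' @return An object of class `peaks_per_gene`: histogram (`table` of
#'   peaks-per-gene counts), `mean`, `fraction_multi` (genes with >= 2
#'   peaks), `n_genes`, `n_peaks`.
#' @export
peaks_per_gene <- function(assignments) {
  a <- assignments[!is.na(assignments$gene_id), , drop = FALSE]
  per_gene <- table(a$gene_id)
  structure(list(
    histogram = table(as.integer(per_gene)),
    mean = if (length(per_gene)) nrow(a) / length(per_gene) else NA_real_,
    fraction_multi = if (length(per_gene)) mean(per_gene >= 2L) else NA_real_,
    n_genes = length(per_gene),
    n_peaks = nrow(a)),
    class = "peaks_per_gene")
}

#' @export
print.peaks_per_gene <- function(x, ...) {
  cat(sprintf("%d peaks over %d associated genes; mean %.3f peaks/gene, %.1f%% of genes with >= 2 peaks\n",
              x$n_peaks, x$n_genes, x$mean, 100 * x$fraction_multi))
  invisible(x)
}

#' Monte Carlo null for peak clustering around genes
#'
#' Tests whether the observed mean number of peaks per associated gene
#' exceeds what a random placement of the same peaks would give. Each
#' iteration places the observed width multiset uniformly at random
#' (chromosome drawn with probability proportional to its length, start
#' uniform so the interval fits; overlaps allowed), reassigns the random
#' peaks to nearest genes with [assign_nearest_gene()], and records the
#' peaks-per-associated-gene mean. The empirical p-value uses the add-one
#' estimator `(count(null >= observed) + 1) / (iterations + 1)`, which never
#' reports zero.
#'
#' @param peaks Observed peak GRanges.
#' @param genes Gene models.
#' @param chrom_sizes Named chromosome lengths covering all peaks.
#' @param iterations Number of Monte Carlo draws (a warning is issued below
#'   20, where the p-value is uninformative).
#' @param seed Integer seed; every iteration derives an independent
#'   sub-stream from (seed, operation, iteration).
#' @param exclude Optional GRanges of regions random peaks must not touch
#'   (e.g. assembly gaps); draws landing there are rejected and redrawn.
#' @return An object of class `peaks_per_gene_null` with `observed_mean`,
#'   `null_means`, `empirical_p`, `iterations`, `seed`.
#' @export
peaks_per_gene_null <- function(peaks, genes, chrom_sizes, iterations = 1000L,
                                seed = 1L, exclude = NULL) {
  .assert_scalar_number(iterations, "iterations", lower = 1)
  if (iterations < 20) {
    warning("fewer than 20 iterations: empirical p-value is uninformative")
  }
  stopifnot(length(peaks) > 0L, !is.null(names(chrom_sizes)))
  widths <- GenomicRanges::width(peaks)
  pk_chrom <- as.character(GenomeInfoDb::seqnames(peaks))
  if (!all(pk_chrom %in% names(chrom_sizes))) {
    stop("chromosome sizes do not cover all peaks", call. = FALSE)
  }
  obs <- peaks_per_gene(assign_nearest_gene(peaks, genes))$mean
  n <- length(widths)
  lens <- unname(chrom_sizes)
  chrs <- names(chrom_sizes)
  if (any(widths > max(lens))) {
    stop("a peak is wider than every chromosome", call. = FALSE)
  }
  # precompute the numeric gene index once; every iteration reuses the
  # exact assignment rule of assign_nearest_gene through its shared core
  idx <- .gene_index(genes)
  excl <- if (is.null(exclude)) NULL else {
    list(chrom = as.character(GenomeInfoDb::seqnames(exclude)),
         s = GenomicRanges::start(exclude), e = GenomicRanges::end(exclude))
  }
  old <- .save_rng()
  on.exit(.restore_rng(old), add = TRUE)
  null_means <- numeric(iterations)
  for (i in seq_len(iterations)) {
    set.seed(.derive_seed(seed, "peaks_per_gene_null", i))
    repeat {
      ci <- sample.int(length(chrs), n, replace = TRUE, prob = lens)
      fits <- widths <= lens[ci]
      if (!all(fits)) {        # redraw chromosomes the peak cannot fit on
        ci[!fits] <- vapply(which(!fits), function(j) {
          ok <- which(lens >= widths[j])
          ok[sample.int(length(ok), 1L, prob = lens[ok])]
        }, integer(1L))
      }
      starts <- floor(runif(n, 1, lens[ci] - widths + 2))
      ends <- starts + widths - 1
      if (is.null(excl)) break
      clash <- FALSE
      for (j in seq_len(n)) {
        same <- excl$chrom == chrs[ci[j]]
        if (any(same & starts[j] <= excl$e[same] & ends[j] >= excl$s[same])) {
          clash <- TRUE
          break
        }
      }
      if (!clash) break
    }
    hit <- .assign_nearest_core(chrs[ci], starts, ends, idx)
    assigned <- hit$gene[!is.na(hit$gene)]
    null_means[i] <- if (length(assigned)) {
      length(assigned) / length(unique(assigned))
    } else NA_real_
  }
  structure(list(observed_mean = obs,
                 null_means = null_means,
                 empirical_p = (sum(null_means >= obs, na.rm = TRUE) + 1) /
                   (iterations + 1),
                 iterations = as.integer(iterations),
                 seed = as.integer(seed)),
            class = "peaks_per_gene_null")
}

#' @export
print.peaks_per_gene_null <- function(x, ...) {
  cat(sprintf("observed mean peaks/gene %.3f vs null mean %.3f (%d iterations): empirical p = %.4g\n",
              x$observed_mean, mean(x$null_means, na.rm = TRUE),
              x$iterations, x$empirical_p))
  invisible(x)
}

#' Annotate peaks by genomic feature
#'
#' Assigns each peak exactly one category with precedence
#' promoter > exon > intron > intergenic. A promoter is the window
#' `[TSS - promoter_window, TSS + promoter_window)` of any gene; exon means
#' overlap with any exonic base; intron means overlap with a gene span but
#' no exonic base and no promoter window. Genes without exon structure are
#' treated as single-exon genes.
#'
#' @param peaks Peak GRanges.
#' @param genes Gene models (with exon structure where available).
#' @param promoter_window Half-width of the promoter window in bp.
#' @return A data.frame with columns `peak_id` and `category` (factor).
#' @export
annotate_feature <- function(peaks, genes, promoter_window = 500L) {
  .assert_scalar_number(promoter_window, "promoter_window", lower = 1)
  .validate_gene_models(genes)
  pid <- S4Vectors::mcols(peaks)$peak_id
  if (is.null(pid)) pid <- sprintf("peak%d", seq_along(peaks))
  tss <- gene_tss(genes)
  prom <- GenomicRanges::GRanges(
    seqnames = GenomeInfoDb::seqnames(genes),
    ranges = IRanges::IRanges(start = pmax(1, tss - promoter_window),
                              end = tss + promoter_window - 1))
  ex <- S4Vectors::mcols(genes)$exons
  exonic <- if (is.null(ex)) {
    GenomicRanges::granges(genes)
  } else {
    none <- lengths(ex) == 0L
    exbases <- unlist(ex, use.names = FALSE)
    if (any(none)) {
      exbases <- c(exbases, GenomicRanges::granges(genes[none]))
    }
    exbases
  }
  p <- GenomicRanges::granges(peaks)
  GenomicRanges::strand(p) <- "*"
  in_prom <- IRanges::overlapsAny(p, prom, ignore.strand = TRUE)
  in_exon <- IRanges::overlapsAny(p, exonic, ignore.strand = TRUE)
  in_gene <- IRanges::overlapsAny(p, genes, ignore.strand = TRUE)
  category <- ifelse(in_prom, "promoter",
                     ifelse(in_exon, "exon",
                            ifelse(in_gene, "intron", "intergenic")))
  data.frame(peak_id = pid,
             category = factor(category, levels = c("promoter", "exon",
                                                    "intron", "intergenic")))
}

#' Peak midpoint distances to the nearest TSS
#'
#' The distance runs from the peak midpoint (offset `floor(width / 2)` from
#' the peak start) to the nearest gene TSS, signed by that gene's strand:
#' negative means the midpoint lies upstream (5') of the TSS.
#'
#' @param peaks Peak GRanges.
#' @param genes Gene models.
#' @param bin Histogram bin width in bp.
#' @param range Histogram half-range in bp (must be a multiple of `bin`);
#'   distances outside it are kept in the distance table but not binned.
#' @return An object of class `tss_profile`: `breaks`, `counts`, and a
#'   `distances` data.frame (`peak_id`, `gene_id`, `distance`).
#' @export
tss_distance_profile <- function(peaks, genes, bin = 100L, range = 5000L) {
  .assert_scalar_number(bin, "bin", lower = 1)
  .assert_scalar_number(range, "range", lower = bin)
  if (range %% bin != 0) stop("'range' must be a multiple of 'bin'", call. = FALSE)
  .validate_gene_models(genes)
  pid <- S4Vectors::mcols(peaks)$peak_id
  if (is.null(pid)) pid <- sprintf("peak%d", seq_along(peaks))
  mid_pos <- GenomicRanges::start(peaks) +
    floor(GenomicRanges::width(peaks) / 2)
  mids <- GenomicRanges::GRanges(
    seqnames = GenomeInfoDb::seqnames(peaks),
    ranges = IRanges::IRanges(start = mid_pos, width = 1L))
  tss <- gene_tss(genes)
  tss_gr <- GenomicRanges::GRanges(
    seqnames = GenomeInfoDb::seqnames(genes),
    ranges = IRanges::IRanges(start = tss, width = 1L))
  lv <- union(GenomeInfoDb::seqlevels(mids), GenomeInfoDb::seqlevels(tss_gr))
  GenomeInfoDb::seqlevels(mids) <- lv
  GenomeInfoDb::seqlevels(tss_gr) <- lv
  hits <- GenomicRanges::distanceToNearest(mids, tss_gr, select = "all",
                                           ignore.strand = TRUE)
  qh <- S4Vectors::queryHits(hits)
  sh <- S4Vectors::subjectHits(hits)
  gid <- S4Vectors::mcols(genes)$gene_id[sh]
  o <- order(qh, S4Vectors::mcols(hits)$distance, gid)
  first <- o[!duplicated(qh[o])]
  qh <- qh[first]; sh <- sh[first]; gid <- gid[first]
  str <- as.character(GenomicRanges::strand(genes))[sh]
  d <- ifelse(str == "-", tss[sh] - mid_pos[qh], mid_pos[qh] - tss[sh])
  breaks <- seq(-range, range, by = bin)
  inside <- d >= -range & d < range
  counts <- table(cut(d[inside], breaks = breaks, right = FALSE,
                      include.lowest = FALSE))
  structure(list(breaks = breaks, counts = counts,
                 distances = data.frame(peak_id = pid[qh], gene_id = gid,
                                        distance = d)),
            class = "tss_profile")
}

#' Peak width summary
#'
#' @param peaks Peak GRanges.
#' @return List with `n`, `median`, `q1`, `q3` of peak widths in bp.
#' @export
width_summary <- function(peaks) {
  w <- GenomicRanges::width(peaks)
  list(n = length(w),
       median = stats::median(w),
       q1 = unname(stats::quantile(w, 0.25)),
       q3 = unname(stats::quantile(w, 0.75)))
}
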