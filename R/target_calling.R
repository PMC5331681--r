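# Integration of occupancy scores with differential expression: response
# curves, randomized gene-set baselines, piecewise-linear breakpoint
# detection, and the high-confidence target set.

#' Differential-expression thresholds
#'
#' A gene is differentially expressed when its adjusted p-value is strictly
#' below `alpha` and its |log2 fold-change| is at least `min_abs_log2fc`
#' (the magnitude bound is inclusive).
#'
#' @param min_abs_log2fc Minimum |log2 fold-change| (default 0.5).
#' @param alpha Adjusted p-value bound (default 0.05, strict).
#' @return An object of class `de_thresholds`.
#' @export
de_thresholds <- function(min_abs_log2fc = 0.5, alpha = 0.05) {
  .assert_scalar_number(min_abs_log2fc, "min_abs_log2fc", lower = 0)
  .assert_scalar_number(alpha, "alpha", lower = 1e-12, upper = 1 - 1e-12)
  structure(list(min_abs_log2fc = min_abs_log2fc, alpha = alpha),
            class = "de_thresholds")
}

#' Classify genes as down- or up-regulated
#'
#' Genes with a missing adjusted p-value (unexpressed/filtered) are
#' excluded from both sets.
#'
#' @param de DE table (data.frame with `gene_id`, `log2fc`, `padj`, as from
#'   [read_de_table()]).
#' @param thresholds [de_thresholds()].
#' @return List with character vectors `down` and `up`.
#' @export
classify_de <- function(de, thresholds = de_thresholds()) {
  stopifnot(all(c("gene_id", "log2fc", "padj") %in% names(de)))
  ok <- !is.na(de$padj) & de$padj < thresholds$alpha
  list(down = de$gene_id[ok & de$log2fc <= -thresholds$min_abs_log2fc],
       up = de$gene_id[ok & de$log2fc >= thresholds$min_abs_log2fc])
}

# Count, for each descending cutoff, how many of `values` are >= it.
# Cutoffs must be sorted descending; exact float ties are honored because
# sampled values come from the same score vector the cutoffs were built on.
.count_ge <- function(values, cutoffs_desc) {
  asc <- rev(cutoffs_desc)
  m <- findInterval(values, asc)            # number of cutoffs <= value
  m <- m[m > 0L]
  k <- length(cutoffs_desc) - m + 1L        # first descending index reached
  cumsum(tabulate(k, nbins = length(cutoffs_desc)))
}

#' Experimental arm of a response curve
#'
#' For each score cutoff `c`, taken in decreasing stringency, counts the
#' genes with score >= `c` and how many of those are in the DE set. By
#' default the cutoff grid is every distinct positive score, so the curve
#' is exact.
#'
#' @param scores Score table from [score_all_genes()] (or a data.frame with
#'   `gene_id` and `score` covering the expressed-gene universe).
#' @param de_genes Character vector of DE gene ids (one direction).
#' @param cutoffs Optional explicit descending cutoff grid; defaults to the
#'   distinct positive scores.
#' @return A data.frame of class `response_curve` with columns `cutoff`,
#'   `n_above`, `n_de_above`; the score vector and DE set travel along as
#'   attributes for downstream baseline and breakpoint steps.
#' @export
response_curve <- function(scores, de_genes, cutoffs = NULL) {
  stopifnot(all(c("gene_id", "score") %in% names(scores)))
  if (anyDuplicated(scores$gene_id)) {
    stop("duplicate gene_id in score table", call. = FALSE)
  }
  if (length(de_genes) == 0L) {
    warning("empty DE set: response curve is identically zero")
  }
  sc <- stats::setNames(scores$score, scores$gene_id)
  if (is.null(cutoffs)) {
    cutoffs <- sort(unique(sc[sc > 0]), decreasing = TRUE)
  } else {
    cutoffs <- sort(cutoffs, decreasing = TRUE)
  }
  if (length(cutoffs) == 0L) stop("no positive scores to build a curve from",
                                  call. = FALSE)
  de_in <- intersect(de_genes, names(sc))
  out <- data.frame(cutoff = cutoffs,
                    n_above = .count_ge(unname(sc), cutoffs),
                    n_de_above = .count_ge(unname(sc[de_in]), cutoffs))
  attr(out, "scores") <- sc
  attr(out, "de_genes") <- de_in
  class(out) <- c("response_curve", "data.frame")
  out
}

#' Randomized-baseline arm of a response curve
#'
#' Repeats the experimental counting with random gene sets: per repetition,
#' `set_size` genes are sampled uniformly without replacement from the
#' scored universe and the curve recomputed; the reported baseline is the
#' per-cutoff mean and SD over repetitions (the average of 100 such random
#' gene sets by default).
#'
#' @param scores Score table (as for [response_curve()]).
#' @param set_size Size of each random gene set, matching the experimental
#'   DE set.
#' @param n_reps Number of random sets (default 100).
#' @param seed Integer seed; results are bit-identical across runs for the
#'   same seed.
#' @param cutoffs Optional descending cutoff grid (defaults to distinct
#'   positive scores).
#' @return A data.frame with `cutoff`, `baseline_mean`, `baseline_sd` and
#'   attribute `n_baseline_reps`.
#' @export
randomized_baseline <- function(scores, set_size, n_reps = 100L, seed = 1L,
                                cutoffs = NULL) {
  stopifnot(all(c("gene_id", "score") %in% names(scores)))
  .assert_scalar_number(n_reps, "n_reps", lower = 1)
  .assert_scalar_number(set_size, "set_size", lower = 1)
  sc <- scores$score
  if (set_size > length(sc)) {
    stop("set_size exceeds the number of scored genes", call. = FALSE)
  }
  if (is.null(cutoffs)) cutoffs <- sort(unique(sc[sc > 0]), decreasing = TRUE)
  else cutoffs <- sort(cutoffs, decreasing = TRUE)
  old <- .save_rng()
  on.exit(.restore_rng(old), add = TRUE)
  set.seed(.derive_seed(seed, "randomized_baseline"))
  draws <- matrix(0, nrow = length(cutoffs), ncol = n_reps)
  for (r in seq_len(n_reps)) {
    draws[, r] <- .count_ge(sc[sample.int(length(sc), set_size)], cutoffs)
  }
  out <- data.frame(cutoff = cutoffs,
                    baseline_mean = rowMeans(draws),
                    baseline_sd = apply(draws, 1L, stats::sd))
  attr(out, "n_baseline_reps") <- as.integer(n_reps)
  out
}

#' Assemble a full response curve with its baseline
#'
#' Convenience wrapper gluing [response_curve()] and
#' [randomized_baseline()] on a shared cutoff grid.
#'
#' @inheritParams response_curve
#' @inheritParams randomized_baseline
#' @param direction Direction label carried on the curve (`"down"` or
#'   `"up"`).
#' @return A `response_curve` data.frame with baseline columns.
#' @export
make_response_curve <- function(scores, de_genes, n_reps = 100L, seed = 1L,
                                cutoffs = NULL,
                                direction = c("down", "up")) {
  direction <- match.arg(direction)
  curve <- response_curve(scores, de_genes, cutoffs = cutoffs)
  set_size <- length(attr(curve, "de_genes"))
  if (set_size > 0L) {
    base <- randomized_baseline(scores, set_size, n_reps = n_reps,
                                seed = seed, cutoffs = curve$cutoff)
    curve$baseline_mean <- base$baseline_mean
    curve$baseline_sd <- base$baseline_sd
    attr(curve, "n_baseline_reps") <- attr(base, "n_baseline_reps")
  } else {
    curve$baseline_mean <- 0
    curve$baseline_sd <- 0
    attr(curve, "n_baseline_reps") <- 0L
  }
  attr(curve, "direction") <- direction
  curve
}

#' @export
print.response_curve <- function(x, ...) {
  cat(sprintf("response_curve (%s): %d cutoffs, universe %d genes, DE set %d genes\n",
              attr(x, "direction") %||% "?", nrow(x),
              length(attr(x, "scores")), length(attr(x, "de_genes"))))
  print.data.frame(utils::head(as.data.frame(x), 5L))
  if (nrow(x) > 5L) cat("...\n")
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Detect the inflection point of a response curve
#'
#' Fits a continuous two-segment piecewise-linear model to the curve of DE
#' counts against the number of genes meeting each descending cutoff (the
#' plotting space in which the slope change is judged: under
#' score-independent DE labels the expected DE count is exactly
#' proportional to that number, so a straight line fits the null), by
#' exhaustive breakpoint search over the cutoff grid minimizing the
#' residual sum of squares with at least `min_segment` points per segment. A threshold is declared only when the
#' slope change is clearly evident: the two-segment fit must improve the
#' single-line SSE by at least `min_sse_improvement` (20% by default) and
#' the experimental DE count at the breakpoint must be at least
#' `min_separation` times the baseline mean there. Otherwise the result is
#' "none detected", mirroring curves not clearly differentiated from their
#' randomized controls.
#'
#' @param curve A `response_curve` with baseline columns (see
#'   [make_response_curve()]); at least 8 cutoff points are required.
#' @param min_separation Required experimental/baseline ratio at the
#'   breakpoint (default 2).
#' @param min_sse_improvement Required fractional SSE improvement of the
#'   two-segment fit over a single line (default 0.2).
#' @param min_segment Minimum points per segment (default 3).
#' @return An object of class `target_call`: `detected`, `threshold_score`
#'   (`NA` when none detected), `breakpoint_index`, `fit_sse`,
#'   `sse_improvement`, `separation`, and the called `targets` (genes with
#'   score >= threshold that are in the curve's DE set).
#' @export
detect_inflection <- function(curve, min_separation = 2,
                              min_sse_improvement = 0.2, min_segment = 3L) {
  stopifnot(inherits(curve, "response_curve"))
  y <- curve$n_de_above
  n <- length(y)
  none <- function(reason, sse = NA_real_, improvement = NA_real_,
                   separation = NA_real_, k = NA_integer_) {
    structure(list(detected = FALSE, threshold_score = NA_real_,
                   breakpoint_index = k, fit_sse = sse,
                   sse_improvement = improvement, separation = separation,
                   targets = character(0), reason = reason,
                   direction = attr(curve, "direction")),
              class = "target_call")
  }
  if (n < max(8L, 2L * min_segment)) {
    warning("response curve has too few cutoff points for breakpoint detection")
    return(none("too few points"))
  }
  x <- as.numeric(curve$n_above)
  fit1 <- stats::lm.fit(cbind(1, x), y)
  sse1 <- sum(fit1$residuals^2)
  if (sse1 <= .Machine$double.eps * n) {
    return(none("single line fits exactly", sse = sse1, improvement = 0))
  }
  ks <- seq.int(min_segment, n - min_segment + 1L)
  sse2 <- vapply(ks, function(k) {
    sum(stats::lm.fit(cbind(1, x, pmax(x - x[k], 0)), y)$residuals^2)
  }, numeric(1L))
  best <- which.min(sse2)
  k <- ks[best]
  improvement <- 1 - sse2[best] / sse1
  base <- curve$baseline_mean
  if (is.null(base)) stop("curve lacks a randomized baseline", call. = FALSE)
  separation <- if (base[k] > 0) y[k] / base[k] else if (y[k] > 0) Inf else 0
  if (improvement < min_sse_improvement) {
    return(none("slope change not clearly evident", sse = sse2[best],
                improvement = improvement, separation = separation, k = k))
  }
  if (separation < min_separation) {
    return(none("not separated from randomized baseline", sse = sse2[best],
                improvement = improvement, separation = separation, k = k))
  }
  threshold <- curve$cutoff[k]
  sc <- attr(curve, "scores")
  de <- attr(curve, "de_genes")
  targets <- intersect(names(sc)[sc >= threshold], de)
  structure(list(detected = TRUE, threshold_score = threshold,
                 breakpoint_index = k, fit_sse = sse2[best],
                 sse_improvement = improvement, separation = separation,
                 targets = sort(targets), reason = "ok",
                 direction = attr(curve, "direction")),
            class = "target_call")
}

#' @export
print.target_call <- function(x, ...) {
  if (x$detected) {
    cat(sprintf("threshold score %.4g at cutoff rank %d (SSE improvement %.1f%%, separation %.2fx): %d targets\n",
                x$threshold_score, x$breakpoint_index,
                100 * x$sse_improvement, x$separation, length(x$targets)))
  } else {
    cat("none detected:", x$reason, "\n")
  }
  invisible(x)
}

#' Call high-confidence targets across timepoints
#'
#' Per timepoint: classify the DE table, build the experimental response
#' curve for the requested direction, average `n_reps` randomized gene-set
#' curves of matched size, and detect the inflection threshold. The final
#' high-confidence set is the union over timepoints of genes passing that
#' timepoint's threshold while being DE in the stated direction there. A
#' timepoint with no detectable inflection contributes nothing.
#'
#' @param score_tables Named list (one per timepoint) of score tables from
#'   [score_all_genes()].
#' @param de_tables Named list (same names) of DE data.frames.
#' @param direction `"down"` (default: repressed upon corepressor
#'   overexpression, the usable signal) or `"up"`.
#' @param thresholds [de_thresholds()].
#' @param n_reps Randomized baseline repetitions (default 100).
#' @param seed Integer seed for the baselines.
#' @param min_separation,min_sse_improvement Passed to
#'   [detect_inflection()].
#' @return An object of class `target_call_set`: per-timepoint
#'   `target_call`s and curves, the union `targets`, and a per-gene table
#'   with the supporting timepoints.
#' @export
call_targets <- function(score_tables, de_tables, direction = c("down", "up"),
                         thresholds = de_thresholds(), n_reps = 100L,
                         seed = 1L, min_separation = 2,
                         min_sse_improvement = 0.2) {
  direction <- match.arg(direction)
  stopifnot(is.list(score_tables), is.list(de_tables),
            identical(names(score_tables), names(de_tables)),
            !is.null(names(score_tables)))
  tps <- names(score_tables)
  calls <- curves <- stats::setNames(vector("list", length(tps)), tps)
  for (i in seq_along(tps)) {
    de_sets <- classify_de(de_tables[[i]], thresholds)
    curve <- make_response_curve(score_tables[[i]], de_sets[[direction]],
                                 n_reps = n_reps,
                                 seed = .derive_seed(seed, "call_targets", i),
                                 direction = direction)
    curves[[i]] <- curve
    calls[[i]] <- detect_inflection(curve, min_separation = min_separation,
                                    min_sse_improvement = min_sse_improvement)
  }
  per_tp <- lapply(calls, `[[`, "targets")
  union_targets <- sort(unique(unlist(per_tp)))
  tbl <- data.frame(
    gene_id = union_targets,
    timepoints = vapply(union_targets, function(g) {
      paste(tps[vapply(per_tp, function(s) g %in% s, logical(1L))],
            collapse = ",")
    }, character(1L)),
    row.names = NULL, stringsAsFactors = FALSE)
  structure(list(calls = calls, curves = curves, targets = union_targets,
                 table = tbl, direction = direction),
            class = "target_call_set")
}

#' @export
print.target_call_set <- function(x, ...) {
  cat(sprintf("high-confidence targets (%s-regulated): %d genes across %d timepoints\n",
              x$direction, length(x$targets), length(x$calls)))
  for (tp in names(x$calls)) {
    cat(sprintf("  %s: ", tp))
    print(x$calls[[tp]])
  }
  invisible(x)
}
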