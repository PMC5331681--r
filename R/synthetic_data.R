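# Parameterized synthetic inputs with known ground truth: genome
# annotation, planted peaks, DE tables and coverage tracks, so every
# pipeline stage is testable without external data.

#' Simulation configuration
#'
#' Returns the full parameter set of the synthetic-data generator. The
#' `"default"` preset emulates the study conditions at desk scale: 2,000
#' genes over four 2.5 Mb chromosomes, 50 true repression targets carrying
#' on average 2.5 clustered binding sites each (planted so roughly half of
#' bound target genes show two or more sites), peak widths log-normal with
#' median 600 bp, targets down-regulated under corepressor overexpression
#' (mean log2 fold-change -1.5) against a 5% spurious DE rate, and a
#' promoter-proximal coverage ratio of 5 for targets vs 1 for background.
#' The `"tiny"` preset runs the full pipeline in seconds; `"genome_scale"`
#' approaches the size of a fly-genome analysis.
#'
#' @param preset `"default"`, `"tiny"`, or `"genome_scale"`.
#' @param ... Named overrides of any configuration field.
#' @return An object of class `sim_config` (a named list).
#' @export
sim_config <- function(preset = c("default", "tiny", "genome_scale"), ...) {
  preset <- match.arg(preset)
  cfg <- list(
    n_chroms = 4L,
    chrom_length = 2.5e6,
    n_genes = 2000L,
    gene_length_meanlog = log(2000),
    gene_length_sdlog = 0.5,
    gene_min_length = 700,
    gene_max_length = 20000,
    make_exons = TRUE,
    n_true_targets = 50L,
    peaks_per_target_mean = 2.5,
    peak_width_meanlog = log(600),
    peak_width_sdlog = 0.4,
    peak_min_width = 50,
    peak_max_width = 5000,
    peak_placement_sd = 500,
    edge_fraction = 0.5,
    n_noise_peaks = 200L,
    replicate_jitter_sd = 10,
    temporal_class_weights = c("t1" = 0.12, "t2" = 0.28, "t3" = 0.18,
                               "t1,t2" = 0.04, "t1,t3" = 0.04,
                               "t2,t3" = 0.25, "t1,t2,t3" = 0.09),
    de_effect = -1.5,
    de_noise_sd = 0.4,
    null_de_rate = 0.05,
    de_min_lfc = 0.5,
    de_alpha = 0.05,
    target_padj_shape2 = 100,
    pausing_ratio_targets = 5,
    pausing_ratio_background = 1,
    proximal_window = 300,
    read_depth = 1e6,
    coverage_noise = TRUE,
    coverage_step = 50,
    seed = 1L)
  if (preset == "tiny") {
    cfg$n_chroms <- 1L
    cfg$chrom_length <- 5e5
    cfg$n_genes <- 100L
    cfg$n_true_targets <- 10L
    cfg$n_noise_peaks <- 30L
  } else if (preset == "genome_scale") {
    cfg$n_chroms <- 6L
    cfg$chrom_length <- 2e7
    cfg$n_genes <- 12000L
    cfg$n_true_targets <- 187L
    cfg$n_noise_peaks <- 3000L
  }
  dots <- list(...)
  bad <- setdiff(names(dots), names(cfg))
  if (length(bad)) stop("unknown sim_config field(s): ",
                        paste(bad, collapse = ", "), call. = FALSE)
  cfg[names(dots)] <- dots
  stopifnot(cfg$n_genes >= 0, cfg$n_true_targets <= cfg$n_genes,
            abs(sum(cfg$temporal_class_weights) - 1) < 1e-9,
            cfg$edge_fraction >= 0, cfg$edge_fraction <= 1)
  structure(cfg, class = "sim_config")
}

#' Generate a synthetic genome annotation
#'
#' Places `n_genes` non-overlapping genes (log-normal lengths, strands
#' balanced 1:1) on `n_chroms` chromosomes, optionally with 2-5 exons per
#' gene. Deterministic for a given config seed.
#'
#' @param config A [sim_config()].
#' @return List with `genes` (gene models) and `chrom_sizes`.
#' @export
make_genome <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  old <- .save_rng()
  on.exit(.restore_rng(old), add = TRUE)
  set.seed(.derive_seed(config$seed, "make_genome"))
  sizes <- stats::setNames(rep(config$chrom_length, config$n_chroms),
                           sprintf("chr%d", seq_len(config$n_chroms)))
  if (config$n_genes == 0L) {
    return(list(genes = .make_gene_models(character(0), numeric(0),
                                          numeric(0), character(0),
                                          character(0),
                                          chrom_sizes = sizes),
                chrom_sizes = sizes))
  }
  lens <- round(pmin(pmax(rlnorm(config$n_genes, config$gene_length_meanlog,
                                 config$gene_length_sdlog),
                          config$gene_min_length), config$gene_max_length))
  chrom_of <- rep(seq_len(config$n_chroms), length.out = config$n_genes)
  starts <- numeric(config$n_genes)
  for (ci in seq_len(config$n_chroms)) {
    idx <- which(chrom_of == ci)
    total <- sum(lens[idx])
    free <- config$chrom_length - total - 2000   # 1 kb margin at each end
    if (free < length(idx)) {
      stop(sprintf("infeasible packing: chromosome length of at least %d required",
                   ceiling(total + length(idx) + 2000)), call. = FALSE)
    }
    cuts <- sort(runif(length(idx)))
    gaps <- floor(free * diff(c(0, cuts)))
    starts[idx] <- 1000 + cumsum(gaps) +
      c(0, cumsum(lens[idx])[-length(idx)]) + seq_along(idx)
  }
  strand <- sample(rep(c("+", "-"), length.out = config$n_genes))
  ids <- sprintf("g%05d", seq_len(config$n_genes))
  exons <- NULL
  if (config$make_exons) {
    # build all exon intervals flat, then split once into a GRangesList
    ex_s <- ex_e <- ex_g <- vector("list", config$n_genes)
    for (i in seq_len(config$n_genes)) {
      k <- sample(2:5, 1L)
      L <- lens[i]
      m <- cbind(starts[i], starts[i] + L - 1)    # single-exon fallback
      if (L >= 4 * k) {
        w <- diff(c(0, sort(runif(2L * k - 2L)), 1))
        seg <- pmax(1, round(w * L))
        seg[length(seg)] <- L - sum(seg[-length(seg)])
        if (seg[length(seg)] >= 1) {
          ends <- starts[i] - 1 + cumsum(seg)
          s <- c(starts[i], ends[-length(ends)] + 1)
          pick <- seq(1L, 2L * k - 1L, by = 2L)
          m <- cbind(s[pick], ends[pick])
        }
      }
      ex_s[[i]] <- m[, 1L]
      ex_e[[i]] <- m[, 2L]
      ex_g[[i]] <- rep(i, nrow(m))
    }
    gidx <- unlist(ex_g)
    flat <- GenomicRanges::GRanges(
      seqnames = sprintf("chr%d", chrom_of[gidx]),
      ranges = IRanges::IRanges(unlist(ex_s), unlist(ex_e)))
    exons <- S4Vectors::split(flat, factor(gidx, levels = seq_len(config$n_genes)))
    names(exons) <- ids
  }
  genes <- .make_gene_models(sprintf("chr%d", chrom_of), starts,
                             starts + lens - 1, strand, ids,
                             exons = exons, chrom_sizes = sizes)
  list(genes = genes, chrom_sizes = sizes)
}

# Draw a peak width from the configured (clamped) log-normal.
.draw_widths <- function(n, config) {
  round(pmin(pmax(rlnorm(n, config$peak_width_meanlog, config$peak_width_sdlog),
                  config$peak_min_width), config$peak_max_width))
}

# Rejection placement: keep proposed [start, end] only if it stays on the
# chromosome and does not touch previously accepted regions.
.try_place <- function(occupied, chrom, start, end, L) {
  if (start < 1 || end > L || end < start) return(FALSE)
  occ <- occupied[[chrom]]
  if (!is.null(occ) && any(start <= occ[, 2L] & end >= occ[, 1L])) return(FALSE)
  TRUE
}

#' Plant synthetic ChIP-seq peaks with ground truth
#'
#' Each true target receives `1 + Poisson(mean - 1)` planted binding
#' regions, centered near the gene's 5' end or a random interior anchor
#' (Normal jitter with SD `peak_placement_sd`); noise regions are placed
#' uniformly. Regions are mutually non-overlapping so the ledger counts are
#' exact. Every region's temporal membership -- target-proximal or noise --
#' is drawn from the configured class weights, so the simulated site-level
#' dynamics follow the configured unique/pairwise/constitutive pattern; for
#' each member timepoint the region is emitted into both replicates with
#' independent edge jitter, so replicate intersection recovers planted
#' regions at default jitter.
#'
#' @param config A [sim_config()].
#' @param genome Output of [make_genome()].
#' @return List with `peaks` (nested list timepoint -> replicate ->
#'   GRanges) and `truth` (planted-region table plus bookkeeping).
#' @export
plant_peaks <- function(config, genome) {
  stopifnot(inherits(config, "sim_config"))
  old <- .save_rng()
  on.exit(.restore_rng(old), add = TRUE)
  set.seed(.derive_seed(config$seed, "plant_peaks"))
  genes <- genome$genes
  sizes <- genome$chrom_sizes
  gid <- S4Vectors::mcols(genes)$gene_id
  targets <- sort(sample(gid, config$n_true_targets))
  tps <- c("t1", "t2", "t3")
  occupied <- stats::setNames(vector("list", length(sizes)), names(sizes))
  regions <- list()
  add_region <- function(chrom, start, end, gene, kind) {
    occupied[[chrom]] <<- rbind(occupied[[chrom]], c(start, end))
    regions[[length(regions) + 1L]] <<- data.frame(
      chrom = chrom, start = start, end = end, gene_id = gene, kind = kind,
      stringsAsFactors = FALSE)
  }
  tss <- gene_tss(genes)
  gs <- GenomicRanges::start(genes)
  ge <- GenomicRanges::end(genes)
  chrom_g <- as.character(GenomeInfoDb::seqnames(genes))
  # planted, target-proximal regions
  for (g in targets) {
    i <- match(g, gid)
    k <- 1L + rpois(1L, config$peaks_per_target_mean - 1)
    for (j in seq_len(k)) {
      for (try in 1:100) {
        anchor <- if (runif(1) < config$edge_fraction) tss[i] else
          round(runif(1, gs[i], ge[i]))
        center <- round(rnorm(1, anchor, config$peak_placement_sd))
        w <- .draw_widths(1L, config)
        s <- center - floor(w / 2)
        e <- s + w - 1
        if (.try_place(occupied, chrom_g[i], s, e, sizes[[chrom_g[i]]])) {
          add_region(chrom_g[i], s, e, g, "planted")
          break
        }
      }
    }
  }
  # noise regions, placed uniformly across the genome
  placed <- 0L
  while (placed < config$n_noise_peaks) {
    ci <- sample.int(length(sizes), 1L, prob = unname(sizes))
    w <- .draw_widths(1L, config)
    s <- floor(runif(1, 1, sizes[[ci]] - w + 2))
    if (.try_place(occupied, names(sizes)[ci], s, s + w - 1,
                   sizes[[ci]])) {
      add_region(names(sizes)[ci], s, s + w - 1, NA_character_, "noise")
      placed <- placed + 1L
    }
  }
  reg <- do.call(rbind, regions)
  classes <- names(config$temporal_class_weights)
  # every region -- target-proximal or noise -- draws its temporal
  # membership from the same class weights, so the simulated site-level
  # dynamics (unique/pairwise/constitutive fractions) follow the
  # configured pattern genome-wide
  reg$membership <- sample(classes, nrow(reg), replace = TRUE,
                           prob = config$temporal_class_weights)
  planted_idx <- which(reg$kind == "planted")
  # ensure every target is bound somewhere: guaranteed since classes non-empty
  peaks <- lapply(stats::setNames(tps, tps), function(tp) {
    sel <- which(vapply(strsplit(reg$membership, ",", fixed = TRUE),
                        function(m) tp %in% m, logical(1L)))
    lapply(stats::setNames(c("rep1", "rep2"), c("rep1", "rep2")),
           function(rp) {
      if (length(sel) == 0L) return(.empty_peaks())
      s <- reg$start[sel] + round(rnorm(length(sel), 0,
                                        config$replicate_jitter_sd))
      e <- reg$end[sel] + round(rnorm(length(sel), 0,
                                      config$replicate_jitter_sd))
      s <- pmax(1, s)
      e <- pmax(s + 1, pmin(e, sizes[reg$chrom[sel]]))
      gr <- GenomicRanges::GRanges(
        seqnames = factor(reg$chrom[sel], levels = names(sizes)),
        ranges = IRanges::IRanges(start = s, end = e))
      GenomeInfoDb::seqlengths(gr) <- unname(sizes)
      S4Vectors::mcols(gr)$peak_id <- sprintf("%s_%s_pk%04d", tp, rp,
                                              seq_along(sel))
      S4Vectors::mcols(gr)$timepoint <- tp
      S4Vectors::mcols(gr)$replicate <- rp
      S4Vectors::mcols(gr)$enrichment <- NA_real_
      gr
    })
  })
  per_target <- table(factor(reg$gene_id[planted_idx], levels = targets))
  truth <- list(
    true_targets = targets,
    regions = reg,
    peaks_per_target = as.integer(per_target),
    fraction_targets_multi = mean(per_target >= 2),
    class_counts = table(factor(reg$membership[planted_idx],
                                levels = classes)),
    class_counts_all = table(factor(reg$membership, levels = classes)))
  list(peaks = peaks, truth = truth)
}

#' Simulate differential-expression tables
#'
#' True targets bound at a timepoint receive a log2 fold-change drawn from
#' `Normal(de_effect, de_noise_sd)` and a Beta-skewed small adjusted
#' p-value; null genes get `Normal(0, de_noise_sd)` and uniform padj, with
#' exactly a `null_de_rate` fraction made spuriously significant (and
#' accidental significance among the rest suppressed, so the realized null
#' DE rate equals the configured one).
#'
#' @param config A [sim_config()].
#' @param genome Output of [make_genome()].
#' @param truth Truth component of [plant_peaks()].
#' @return List with `de` (timepoint -> data.frame) and `de_truth`
#'   (timepoint -> character vector of truly down-regulated targets).
#' @export
simulate_de <- function(config, genome, truth) {
  stopifnot(inherits(config, "sim_config"))
  old <- .save_rng()
  on.exit(.restore_rng(old), add = TRUE)
  set.seed(.derive_seed(config$seed, "simulate_de"))
  gid <- S4Vectors::mcols(genome$genes)$gene_id
  tps <- c("t1", "t2", "t3")
  reg <- truth$regions[truth$regions$kind == "planted", , drop = FALSE]
  bound_at <- lapply(stats::setNames(tps, tps), function(tp) {
    unique(reg$gene_id[vapply(strsplit(reg$membership, ",", fixed = TRUE),
                              function(m) tp %in% m, logical(1L))])
  })
  de <- de_truth <- stats::setNames(vector("list", 3L), tps)
  for (tp in tps) {
    lfc <- rnorm(length(gid), 0, config$de_noise_sd)
    padj <- runif(length(gid))
    is_t <- gid %in% bound_at[[tp]]
    lfc[is_t] <- rnorm(sum(is_t), config$de_effect, config$de_noise_sd)
    padj[is_t] <- rbeta(sum(is_t), 1, config$target_padj_shape2)
    null_idx <- which(!is_t)
    n_spur <- round(config$null_de_rate * length(null_idx))
    spur <- sample(null_idx, n_spur)
    padj[spur] <- runif(n_spur, 0, config$de_alpha * 0.999)
    lfc[spur] <- sample(c(-1, 1), n_spur, replace = TRUE) *
      (config$de_min_lfc + stats::rexp(n_spur, rate = 1 / 0.3))
    accidental <- setdiff(null_idx[padj[null_idx] < config$de_alpha &
                                     abs(lfc[null_idx]) >= config$de_min_lfc],
                          spur)
    padj[accidental] <- runif(length(accidental), config$de_alpha, 1)
    de[[tp]] <- data.frame(gene_id = gid, log2fc = lfc, padj = padj,
                           stringsAsFactors = FALSE)
    de_truth[[tp]] <- sort(gid[is_t & padj < config$de_alpha &
                                 lfc <= -config$de_min_lfc])
  }
  list(de = de, de_truth = de_truth)
}

#' Simulate stranded chromatin-associated RNA coverage
#'
#' Per gene, a piecewise-constant two-level density: the proximal level is
#' `pausing_ratio x body level` for the gene's class (target or
#' background), body levels log-normal across genes, the whole track scaled
#' to `read_depth` total reads; optional Poisson noise is applied per
#' `coverage_step`-bp step. Intergenic background is zero.
#'
#' @param config A [sim_config()].
#' @param genome Output of [make_genome()].
#' @param truth Truth component of [plant_peaks()] (defines the target
#'   class).
#' @return List with `coverage` (a `coverage_track`) and `coverage_truth`
#'   (per-gene true ratio and total integrated coverage).
#' @export
simulate_coverage <- function(config, genome, truth) {
  stopifnot(inherits(config, "sim_config"))
  old <- .save_rng()
  on.exit(.restore_rng(old), add = TRUE)
  set.seed(.derive_seed(config$seed, "simulate_coverage"))
  genes <- genome$genes
  sizes <- genome$chrom_sizes
  gid <- S4Vectors::mcols(genes)$gene_id
  is_t <- gid %in% truth$true_targets
  ratio <- ifelse(is_t, config$pausing_ratio_targets,
                  config$pausing_ratio_background)
  body_level <- rlnorm(length(gid), 0, 1)
  w <- config$proximal_window
  gs <- GenomicRanges::start(genes)
  ge <- GenomicRanges::end(genes)
  str <- as.character(GenomicRanges::strand(genes))
  chrom <- as.character(GenomeInfoDb::seqnames(genes))
  len <- ge - gs + 1
  # two segments per gene: proximal (first w bases from the TSS) and body
  prox_s <- ifelse(str == "+", gs, ge - w + 1)
  prox_e <- ifelse(str == "+", gs + w - 1, ge)
  body_s <- ifelse(str == "+", gs + w, gs)
  body_e <- ifelse(str == "+", ge, ge - w)
  seg <- data.frame(
    chrom = rep(chrom, 2L),
    start = c(prox_s, body_s), end = c(prox_e, body_e),
    strand = rep(str, 2L),
    level = c(ratio * body_level, body_level))
  total <- sum(seg$level * (seg$end - seg$start + 1))
  seg$level <- seg$level * config$read_depth / total
  if (config$coverage_noise) {
    pieces <- vector("list", nrow(seg))
    for (i in seq_len(nrow(seg))) {
      slen <- seg$end[i] - seg$start[i] + 1
      nstep <- ceiling(slen / config$coverage_step)
      s <- seg$start[i] + (seq_len(nstep) - 1L) * config$coverage_step
      e <- pmin(s + config$coverage_step - 1L, seg$end[i])
      lam <- seg$level[i] * (e - s + 1)
      pieces[[i]] <- data.frame(chrom = seg$chrom[i], start = s, end = e,
                                strand = seg$strand[i],
                                level = rpois(nstep, lam) / (e - s + 1))
    }
    seg <- do.call(rbind, pieces)
  }
  to_rle <- function(sdf) {
    gr <- GenomicRanges::GRanges(
      seqnames = factor(sdf$chrom, levels = names(sizes)),
      ranges = IRanges::IRanges(sdf$start, sdf$end))
    GenomeInfoDb::seqlengths(gr) <- unname(sizes)
    .clamp_rle_zero(GenomicRanges::coverage(gr, weight = sdf$level))
  }
  track <- coverage_track(to_rle(seg[seg$strand == "+", , drop = FALSE]),
                          to_rle(seg[seg$strand == "-", , drop = FALSE]))
  list(coverage = track,
       coverage_truth = list(
         ratio = stats::setNames(ratio, gid),
         total_coverage = sum(seg$level * (seg$end - seg$start + 1))))
}

#' Generate a complete synthetic dataset
#'
#' Single call producing every pipeline input — genome annotation, six peak
#' sets (three timepoints, two replicates), three DE tables, a stranded
#' coverage track — together with the ground truth needed to score
#' recovery. Deterministic for a given config seed.
#'
#' @param config A [sim_config()].
#' @return An object of class `gro_sim`.
#' @export
simulate_dataset <- function(config = sim_config()) {
  genome <- make_genome(config)
  pk <- plant_peaks(config, genome)
  dx <- simulate_de(config, genome, pk$truth)
  cv <- simulate_coverage(config, genome, pk$truth)
  structure(list(config = config,
                 genes = genome$genes,
                 chrom_sizes = genome$chrom_sizes,
                 peaks = pk$peaks,
                 de = dx$de,
                 coverage = cv$coverage,
                 truth = c(pk$truth, list(de_down = dx$de_truth),
                           cv$coverage_truth)),
            class = "gro_sim")
}

#' @export
print.gro_sim <- function(x, ...) {
  cat(sprintf("synthetic dataset: %d genes on %d chromosome(s), %d true targets, seed %d\n",
              length(x$genes), length(x$chrom_sizes),
              length(x$truth$true_targets), x$config$seed))
  invisible(x)
}

#' Write a synthetic dataset to standard-format files
#'
#' Emits GTF + BED12 gene models, a chromosome-sizes file, six BED6 peak
#' files, three DE TSVs, a stranded bedGraph pair, and the ground truth as
#' JSON. Byte-identical output for the same seed.
#'
#' @param sim A `gro_sim` from [simulate_dataset()].
#' @param dir Output directory (created if needed).
#' @return Invisibly, the directory.
#' @export
write_dataset <- function(sim, dir) {
  stopifnot(inherits(sim, "gro_sim"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_gtf(sim$genes, file.path(dir, "genes.gtf"))
  write_bed12(sim$genes, file.path(dir, "genes.bed12"))
  write_chrom_sizes(sim$chrom_sizes, file.path(dir, "chrom.sizes"))
  for (tp in names(sim$peaks)) {
    for (rp in names(sim$peaks[[tp]])) {
      write_peaks(sim$peaks[[tp]][[rp]],
                  file.path(dir, sprintf("peaks_%s_%s.bed", tp, rp)))
    }
    write_tsv(sim$de[[tp]], file.path(dir, sprintf("de_%s.tsv", tp)))
  }
  write_bedgraph(sim$coverage, file.path(dir, "coverage_plus.bedGraph"), "+")
  write_bedgraph(sim$coverage, file.path(dir, "coverage_minus.bedGraph"), "-")
  truth <- sim$truth
  truth$class_counts <- as.list(truth$class_counts)
  truth$class_counts_all <- as.list(truth$class_counts_all)
  jsonlite::write_json(truth, file.path(dir, "ground_truth.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(dir)
}

#' Run the full analysis pipeline on a synthetic dataset
#'
#' Reproducible peaks per timepoint, occupancy scores for every gene,
#' target calling with randomized baselines, and recovery metrics against
#' the planted truth.
#'
#' @param sim A `gro_sim`.
#' @param params [scoring_parameters()].
#' @param n_reps Randomized-baseline repetitions.
#' @param seed Seed for the baselines (defaults to the simulation seed).
#' @return List with `reproducible`, `scores`, `call` (a
#'   `target_call_set`), and `recovery` (sensitivity/precision against the
#'   planted targets).
#' @export
run_pipeline <- function(sim, params = scoring_parameters(), n_reps = 100L,
                         seed = NULL) {
  stopifnot(inherits(sim, "gro_sim"))
  if (is.null(seed)) seed <- sim$config$seed
  tps <- names(sim$peaks)
  reproducible <- lapply(stats::setNames(tps, tps), function(tp) {
    intersect_replicates(sim$peaks[[tp]]$rep1, sim$peaks[[tp]]$rep2)
  })
  scores <- lapply(reproducible, function(pk) {
    score_all_genes(sim$genes, pk, params)
  })
  call <- call_targets(scores, sim$de,
                       direction = "down",
                       thresholds = de_thresholds(sim$config$de_min_lfc,
                                                  sim$config$de_alpha),
                       n_reps = n_reps, seed = seed)
  list(reproducible = reproducible, scores = scores, call = call,
       recovery = evaluate_recovery(call$targets, sim$truth$true_targets))
}

#' Sensitivity and precision of a called target set
#'
#' @param called Character vector of called gene ids.
#' @param true_targets Character vector of planted target gene ids.
#' @return List with `sensitivity`, `precision`, `n_called`, `n_true`,
#'   `n_correct`.
#' @export
evaluate_recovery <- function(called, true_targets) {
  correct <- length(intersect(called, true_targets))
  list(sensitivity = if (length(true_targets)) correct / length(true_targets)
       else NA_real_,
       precision = if (length(called)) correct / length(called) else NA_real_,
       n_called = length(called), n_true = length(true_targets),
       n_correct = correct)
}
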