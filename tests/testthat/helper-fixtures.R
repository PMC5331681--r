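# Shared fixture builders and independent brute-force oracles. Oracles are
# deliberately naive (quadratic scans, per-base loops) and never call the
# code paths they check.

suppressPackageStartupMessages({
  library(GenomicRanges)
  library(IRanges)
  library(S4Vectors)
})

make_peaks <- function(chrom, start, end, timepoint = "t1",
                       replicate = "rep1", ids = NULL) {
  gr <- GRanges(chrom, IRanges(start = start, end = end))
  mcols(gr)$peak_id <- if (is.null(ids)) {
    sprintf("%s_%s_p%03d", timepoint, replicate, seq_along(gr))
  } else ids
  mcols(gr)$timepoint <- timepoint
  mcols(gr)$replicate <- replicate
  mcols(gr)$enrichment <- NA_real_
  gr
}

make_genes <- function(chrom, start, end, strand = "+", ids = NULL,
                       exons = NULL, chrom_sizes = NULL) {
  groscore:::.make_gene_models(
    chrom, start, end,
    rep(strand, length.out = length(start)),
    if (is.null(ids)) sprintf("g%03d", seq_along(start)) else ids,
    exons = exons, chrom_sizes = chrom_sizes)
}

random_instance <- function(seed, n_genes = 25, n_peaks = 40,
                            chrom_len = 2e5, n_chroms = 1,
                            gene_len = c(500, 3000), peak_len = c(1, 1200)) {
  set.seed(seed)
  chroms <- sprintf("chr%d", seq_len(n_chroms))
  g_chrom <- sample(chroms, n_genes, replace = TRUE)
  g_len <- sample(gene_len[1]:gene_len[2], n_genes, replace = TRUE)
  g_start <- vapply(g_len, function(l) sample.int(chrom_len - l, 1), numeric(1))
  genes <- make_genes(g_chrom, g_start, g_start + g_len - 1,
                      strand = sample(c("+", "-"), n_genes, replace = TRUE),
                      chrom_sizes = setNames(rep(chrom_len, n_chroms), chroms))
  p_chrom <- sample(chroms, n_peaks, replace = TRUE)
  p_len <- sample(peak_len[1]:peak_len[2], n_peaks, replace = TRUE)
  p_start <- vapply(p_len, function(l) sample.int(chrom_len - l, 1), numeric(1))
  peaks <- make_peaks(p_chrom, p_start, p_start + p_len - 1)
  list(genes = genes, peaks = peaks,
       chrom_sizes = setNames(rep(chrom_len, n_chroms), chroms))
}

# ---- oracles ---------------------------------------------------------------

# O(width) per-base enumeration of the mean per-base occupancy score.
oracle_peak_score <- function(ps, pe, gs, ge, params) {
  total <- 0
  for (b in ps:pe) {
    if (b >= gs && b <= ge) {
      total <- total + params$overlap_score
    } else {
      d <- if (b < gs) gs - b else b - ge
      d <- d - (1 - params$d0)
      total <- total + 1 / (1 + exp(params$steepness * (d - params$offset)))
    }
  }
  total / (pe - ps + 1)
}

# Extract plain-R gene arrays once so the per-peak oracle loops carry no
# S4 overhead (exons become a list of start/end matrices).
plain_genes <- function(genes) {
  ex <- mcols(genes)$exons
  exl <- if (is.null(ex)) {
    replicate(length(genes), NULL)
  } else {
    flat <- unlist(ex, use.names = FALSE)
    grp <- rep(seq_along(genes), lengths(ex))
    m <- cbind(start(flat), end(flat))
    lapply(seq_along(genes), function(j) m[grp == j, , drop = FALSE])
  }
  list(gid = mcols(genes)$gene_id, gs = start(genes), ge = end(genes),
       chrom = as.character(seqnames(genes)),
       strand = as.character(strand(genes)),
       tss = unname(gene_tss(genes)), exons = exl)
}

# Exhaustive nearest-gene scan with the tie rule (min edge gap, then gap to
# TSS, then lexicographic gene_id); returns gene_id and signed distance.
oracle_nearest_gene <- function(p_chrom, ps, pe, pg) {
  gid <- pg$gid
  gs <- pg$gs; ge <- pg$ge
  gchrom <- pg$chrom
  strand <- pg$strand
  tss <- pg$tss
  sel <- which(gchrom == p_chrom)
  if (!length(sel)) return(list(gene_id = NA_character_, signed = NA_real_))
  gap <- pmax(gs[sel] - pe - 1, ps - ge[sel] - 1)
  d <- pmax(gap, 0)
  tg <- ifelse(ps <= tss[sel] & tss[sel] <= pe, 0,
               pmin(abs(ps - tss[sel]), abs(pe - tss[sel])))
  o <- sel[order(d, tg, gid[sel], method = "radix")[1]]
  g <- gap[match(o, sel)]
  if (g < 0) return(list(gene_id = gid[o], signed = 0))
  mag <- g + 1
  left <- pe < gs[o]
  up <- (left && strand[o] == "+") || (!left && strand[o] == "-")
  list(gene_id = gid[o], signed = if (up) -mag else mag)
}

# All-pairs replicate intersection: the full overlap adjacency matrix is
# built explicitly (quadratic) and component labels propagate to the
# neighborhood minimum until a fixed point.
oracle_intersect <- function(rep_a, rep_b, min_overlap = 1) {
  s <- c(start(rep_a), start(rep_b))
  e <- c(end(rep_a), end(rep_b))
  ch <- c(as.character(seqnames(rep_a)), as.character(seqnames(rep_b)))
  src <- rep(c("a", "b"), c(length(rep_a), length(rep_b)))
  n <- length(s)
  adj <- outer(seq_len(n), seq_len(n), function(i, j) {
    ch[i] == ch[j] & pmin(e[i], e[j]) - pmax(s[i], s[j]) + 1 >= min_overlap
  })
  comp <- seq_len(n)
  repeat {
    nxt <- vapply(seq_len(n), function(i) min(comp[adj[i, ]]), numeric(1))
    if (identical(nxt, comp)) break
    comp <- nxt
  }
  out <- NULL
  for (k in unique(comp)) {
    idx <- which(comp == k)
    if (length(unique(src[idx])) == 2) {
      out <- rbind(out, data.frame(chrom = ch[idx[1]], start = min(s[idx]),
                                   end = max(e[idx])))
    }
  }
  if (is.null(out)) return(out)
  out[order(out$chrom, out$start), , drop = FALSE]
}

# Per-base feature classifier with promoter > exon > intron > intergenic.
oracle_annotate <- function(ps, pe, p_chrom, pg, window = 500) {
  hit_prom <- hit_exon <- hit_gene <- FALSE
  for (j in seq_along(pg$gid)) {
    if (pg$chrom[j] != p_chrom) next
    if (ps <= pg$tss[j] + window - 1 && pe >= max(1, pg$tss[j] - window)) {
      hit_prom <- TRUE
    }
    if (ps <= pg$ge[j] && pe >= pg$gs[j]) hit_gene <- TRUE
    exj <- pg$exons[[j]]
    if (is.null(exj) || nrow(exj) == 0) exj <- cbind(pg$gs[j], pg$ge[j])
    for (r in seq_len(nrow(exj))) {
      if (ps <= exj[r, 2] && pe >= exj[r, 1]) hit_exon <- TRUE
    }
  }
  if (hit_prom) "promoter" else if (hit_exon) "exon"
  else if (hit_gene) "intron" else "intergenic"
}

# Brute-force response curve: double loop over cutoffs and genes.
oracle_response_curve <- function(scores_df, de_genes, cutoffs) {
  t(vapply(cutoffs, function(cc) {
    above <- scores_df$gene_id[scores_df$score >= cc]
    c(n_above = length(above),
      n_de_above = length(intersect(above, de_genes)))
  }, c(n_above = 0, n_de_above = 0)))
}
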