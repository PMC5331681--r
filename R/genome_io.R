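# Readers/writers for the standard formats the pipeline touches, plus the
# shared coordinate conventions. Internally every interval is a GRanges
# (1-based, closed); BED-family inputs (0-based, half-open) are converted at
# the parse/write boundary and nothing downstream re-parses text.

# Read a whitespace-table file keeping original line numbers, skipping
# comment/track/browser and blank lines.
.read_table_lines <- function(path) {
  if (!file.exists(path)) stop("file does not exist: ", path, call. = FALSE)
  raw <- readLines(path, warn = FALSE)
  keep <- !grepl("^(#|track\\b|browser\\b)", raw) & nzchar(trimws(raw))
  list(fields = strsplit(raw[keep], "\t", fixed = TRUE), lineno = which(keep))
}

.parse_coord <- function(x, what, lineno) {
  v <- suppressWarnings(as.numeric(x))
  bad <- is.na(v) | v != floor(v) | v < 0
  if (any(bad)) {
    stop(sprintf("malformed %s coordinate at line %d: '%s'",
                 what, lineno[which(bad)[1L]], x[which(bad)[1L]]), call. = FALSE)
  }
  v
}

.check_chroms <- function(chrom, end1, chrom_sizes, lineno, what) {
  if (is.null(chrom_sizes)) return(invisible(NULL))
  unknown <- !(chrom %in% names(chrom_sizes))
  if (any(unknown)) {
    stop(sprintf("%s: unknown chromosome '%s' at line %d (not in chromosome sizes)",
                 what, chrom[which(unknown)[1L]], lineno[which(unknown)[1L]]),
         call. = FALSE)
  }
  over <- end1 > unname(chrom_sizes[chrom])
  if (any(over)) {
    stop(sprintf("%s: interval end exceeds chromosome size at line %d",
                 what, lineno[which(over)[1L]]), call. = FALSE)
  }
  invisible(NULL)
}

#' Read ChIP-seq peak calls from BED6 or ENCODE narrowPeak
#'
#' Every record becomes a validated interval; input order is preserved and
#' the number of peaks returned equals the number of non-comment lines.
#' BED coordinates (0-based half-open) are converted to the package's
#' internal 1-based closed convention.
#'
#' @param path Path to a BED6 or narrowPeak file.
#' @param format `"bed6"` or `"narrowPeak"`.
#' @param timepoint Timepoint label attached to every peak (e.g. `"t1"`).
#' @param replicate Replicate label attached to every peak.
#' @param chrom_sizes Optional named numeric vector of chromosome lengths.
#'   When supplied, unknown chromosomes and out-of-bounds intervals are hard
#'   errors; without it they only warn (there is nothing to check against).
#' @return A [GenomicRanges::GRanges] with metadata columns `peak_id`,
#'   `timepoint`, `replicate`, `enrichment`.
#' @export
read_peaks <- function(path, format = c("bed6", "narrowPeak"),
                       timepoint = "t1", replicate = "rep1",
                       chrom_sizes = NULL) {
  format <- match.arg(format)
  tab <- .read_table_lines(path)
  n <- length(tab$fields)
  if (n == 0L) {
    warning("no peak records in ", path)
    return(.empty_peaks())
  }
  ncol_min <- if (format == "bed6") 6L else 10L
  nc <- lengths(tab$fields)
  if (any(nc < ncol_min)) {
    stop(sprintf("%s record with %d column(s) at line %d (need >= %d)",
                 format, min(nc), tab$lineno[which(nc < ncol_min)[1L]], ncol_min),
         call. = FALSE)
  }
  col <- function(i) vapply(tab$fields, `[[`, character(1L), i)
  chrom <- col(1L)
  start0 <- .parse_coord(col(2L), "start", tab$lineno)
  end0 <- .parse_coord(col(3L), "end", tab$lineno)
  bad <- start0 >= end0
  if (any(bad)) {
    stop(sprintf("start >= end at line %d", tab$lineno[which(bad)[1L]]),
         call. = FALSE)
  }
  .check_chroms(chrom, end0, chrom_sizes, tab$lineno, basename(path))
  peak_id <- col(4L)
  auto <- peak_id == "." | peak_id == ""
  peak_id[auto] <- sprintf("%s_%s_peak%d", timepoint, replicate, which(auto))
  if (anyDuplicated(peak_id)) {
    stop("duplicate peak_id within (", timepoint, ", ", replicate, "): ",
         peak_id[duplicated(peak_id)][1L], call. = FALSE)
  }
  enr_col <- if (format == "bed6") 5L else 7L
  enrichment <- suppressWarnings(as.numeric(col(enr_col)))
  if (any(!is.na(enrichment) & enrichment < 0)) {
    stop("negative enrichment value in ", path, call. = FALSE)
  }
  gr <- GenomicRanges::GRanges(
    seqnames = chrom,
    ranges = IRanges::IRanges(start = start0 + 1, end = end0))
  S4Vectors::mcols(gr)$peak_id <- peak_id
  S4Vectors::mcols(gr)$timepoint <- timepoint
  S4Vectors::mcols(gr)$replicate <- replicate
  S4Vectors::mcols(gr)$enrichment <- enrichment
  if (!is.null(chrom_sizes)) {
    GenomeInfoDb::seqlevels(gr) <- names(chrom_sizes)
    GenomeInfoDb::seqlengths(gr) <- unname(chrom_sizes)
  }
  gr
}

.empty_peaks <- function() {
  gr <- GenomicRanges::GRanges()
  S4Vectors::mcols(gr)$peak_id <- character(0)
  S4Vectors::mcols(gr)$timepoint <- character(0)
  S4Vectors::mcols(gr)$replicate <- character(0)
  S4Vectors::mcols(gr)$enrichment <- numeric(0)
  gr
}

#' Write peaks to BED6
#'
#' Inverse of [read_peaks()] for the BED6 dialect: coordinates go back to
#' 0-based half-open, enrichment is written to the score column (`0` when
#' missing) and strand as `.`.
#'
#' @param peaks GRanges as returned by [read_peaks()].
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_peaks <- function(peaks, path) {
  score <- S4Vectors::mcols(peaks)$enrichment
  if (is.null(score)) score <- rep(NA_real_, length(peaks))
  score[is.na(score)] <- 0
  id <- S4Vectors::mcols(peaks)$peak_id
  if (is.null(id)) id <- sprintf("peak%d", seq_along(peaks))
  df <- data.frame(
    chrom = as.character(GenomeInfoDb::seqnames(peaks)),
    start = GenomicRanges::start(peaks) - 1,
    end = GenomicRanges::end(peaks),
    name = id,
    score = score,
    strand = ".")
  write.table(df, path, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  invisible(path)
}

# ---- gene models -----------------------------------------------------------

.validate_gene_models <- function(genes) {
  stopifnot(methods::is(genes, "GRanges"))
  if (is.null(S4Vectors::mcols(genes)$gene_id)) {
    stop("gene models must carry a 'gene_id' metadata column", call. = FALSE)
  }
  if (anyDuplicated(S4Vectors::mcols(genes)$gene_id)) {
    stop("duplicate gene_id in gene models", call. = FALSE)
  }
  if (any(!as.character(GenomicRanges::strand(genes)) %in% c("+", "-"))) {
    stop("every gene must be stranded (+ or -)", call. = FALSE)
  }
  ex <- S4Vectors::mcols(genes)$exons
  if (!is.null(ex) && sum(lengths(ex)) > 0L) {
    # flatten once; per-exon gene index avoids per-gene S4 extraction
    flat <- unlist(ex, use.names = FALSE)
    grp <- rep(seq_along(genes), lengths(ex))
    es <- GenomicRanges::start(flat)
    ee <- GenomicRanges::end(flat)
    bad <- as.character(GenomeInfoDb::seqnames(flat)) !=
      as.character(GenomeInfoDb::seqnames(genes))[grp] |
      es < GenomicRanges::start(genes)[grp] |
      ee > GenomicRanges::end(genes)[grp]
    if (any(bad)) {
      stop("gene '", S4Vectors::mcols(genes)$gene_id[grp[which(bad)[1L]]],
           "' has exons outside its span", call. = FALSE)
    }
    o <- order(grp, es)
    same <- grp[o][-1L] == grp[o][-length(o)]
    clash <- same & es[o][-1L] <= ee[o][-length(o)]
    if (any(clash)) {
      stop("gene '",
           S4Vectors::mcols(genes)$gene_id[grp[o][-1L][which(clash)[1L]]],
           "' has overlapping exons after merging", call. = FALSE)
    }
  }
  invisible(genes)
}

.make_gene_models <- function(chrom, start, end, strand, gene_id,
                              exons = NULL, chrom_sizes = NULL) {
  gr <- GenomicRanges::GRanges(
    seqnames = chrom,
    ranges = IRanges::IRanges(start = start, end = end),
    strand = strand)
  S4Vectors::mcols(gr)$gene_id <- gene_id
  if (!is.null(exons)) S4Vectors::mcols(gr)$exons <- exons
  if (!is.null(chrom_sizes)) {
    GenomeInfoDb::seqlevels(gr) <- names(chrom_sizes)
    GenomeInfoDb::seqlengths(gr) <- unname(chrom_sizes)
  }
  o <- order(as.character(GenomeInfoDb::seqnames(gr)),
             GenomicRanges::start(gr), S4Vectors::mcols(gr)$gene_id)
  gr <- gr[o]
  .validate_gene_models(gr)
}

#' Transcription start sites of gene models
#'
#' The TSS is the strand-aware 5' end: `start` for a plus-strand gene and
#' `end` for a minus-strand gene (equivalently `end - 1` in 0-based
#' half-open coordinates).
#'
#' @param genes Gene models from [read_genes()] or [make_genome()].
#' @return Integer vector of TSS positions (1-based), named by `gene_id`.
#' @export
gene_tss <- function(genes) {
  minus <- as.character(GenomicRanges::strand(genes)) == "-"
  pos <- ifelse(minus, GenomicRanges::end(genes), GenomicRanges::start(genes))
  names(pos) <- S4Vectors::mcols(genes)$gene_id
  pos
}

#' Read gene models from GTF or BED12
#'
#' Produces one gene model per unique `gene_id`. Exons repeated across
#' transcripts are merged: the exon set of a gene is the base-level union of
#' all its transcripts' exons. A gene feature whose exons fall outside its
#' annotated span is a hard error.
#'
#' @param path Path to a GTF or BED12 file.
#' @param format `"gtf"` or `"bed12"`.
#' @param chrom_sizes Optional named chromosome lengths used for validation.
#' @return A GRanges of gene spans (strand `+`/`-`) with metadata columns
#'   `gene_id` and `exons` (a GRangesList of merged exons).
#' @export
read_genes <- function(path, format = c("gtf", "bed12"), chrom_sizes = NULL) {
  format <- match.arg(format)
  if (format == "gtf") {
    gr <- rtracklayer::import(path, format = "gtf")
    gid <- S4Vectors::mcols(gr)$gene_id
    if (is.null(gid) || anyNA(gid)) {
      stop("GTF features missing gene_id attribute in ", path, call. = FALSE)
    }
    type <- as.character(S4Vectors::mcols(gr)$type)
    ex <- gr[type == "exon"]
    gene_rows <- gr[type == "gene"]
    if (length(ex) == 0L && length(gene_rows) == 0L) {
      stop("GTF contains neither 'gene' nor 'exon' features: ", path,
           call. = FALSE)
    }
    ids <- unique(c(S4Vectors::mcols(gene_rows)$gene_id,
                    S4Vectors::mcols(ex)$gene_id))
    exons_by <- if (length(ex)) {
      GenomicRanges::reduce(
        GenomicRanges::split(GenomicRanges::granges(ex),
                             factor(S4Vectors::mcols(ex)$gene_id, levels = ids)))
    } else NULL
    span <- vector("list", length(ids))
    strandv <- chromv <- character(length(ids))
    for (i in seq_along(ids)) {
      g <- gene_rows[S4Vectors::mcols(gene_rows)$gene_id == ids[i]]
      e <- if (is.null(exons_by)) GenomicRanges::GRanges() else exons_by[[ids[i]]]
      if (length(g) == 1L) {
        if (length(e) &&
            (min(GenomicRanges::start(e)) < GenomicRanges::start(g) ||
             max(GenomicRanges::end(e)) > GenomicRanges::end(g))) {
          stop("gene '", ids[i], "' has exons outside its span in ", path,
               call. = FALSE)
        }
        span[[i]] <- c(GenomicRanges::start(g), GenomicRanges::end(g))
        strandv[i] <- as.character(GenomicRanges::strand(g))
        chromv[i] <- as.character(GenomeInfoDb::seqnames(g))
      } else if (length(e)) {
        span[[i]] <- c(min(GenomicRanges::start(e)), max(GenomicRanges::end(e)))
        ss <- unique(as.character(GenomicRanges::strand(
          ex[S4Vectors::mcols(ex)$gene_id == ids[i]])))
        strandv[i] <- ss[1L]
        chromv[i] <- as.character(GenomeInfoDb::seqnames(e))[1L]
      } else {
        stop("gene '", ids[i], "' appears more than once as a gene feature",
             call. = FALSE)
      }
    }
    exlist <- if (is.null(exons_by)) {
      NULL
    } else {
      ex_missing <- GenomicRanges::GRangesList(lapply(ids, function(id) {
        if (id %in% names(exons_by)) exons_by[[id]] else GenomicRanges::GRanges()
      }))
      names(ex_missing) <- ids
      ex_missing
    }
    .make_gene_models(chromv, vapply(span, `[[`, numeric(1), 1L),
                      vapply(span, `[[`, numeric(1), 2L), strandv, ids,
                      exons = exlist, chrom_sizes = chrom_sizes)
  } else {
    tab <- .read_table_lines(path)
    nc <- lengths(tab$fields)
    if (any(nc < 12L)) {
      stop(sprintf("BED12 record with %d column(s) at line %d",
                   min(nc), tab$lineno[which(nc < 12L)[1L]]), call. = FALSE)
    }
    col <- function(i) vapply(tab$fields, `[[`, character(1L), i)
    chrom <- col(1L)
    start0 <- .parse_coord(col(2L), "start", tab$lineno)
    end0 <- .parse_coord(col(3L), "end", tab$lineno)
    if (any(start0 >= end0)) {
      stop(sprintf("start >= end at line %d",
                   tab$lineno[which(start0 >= end0)[1L]]), call. = FALSE)
    }
    .check_chroms(chrom, end0, chrom_sizes, tab$lineno, basename(path))
    name <- col(4L)
    strand <- col(6L)
    if (any(!strand %in% c("+", "-"))) {
      stop("BED12 gene without +/- strand at line ",
           tab$lineno[which(!strand %in% c("+", "-"))[1L]], call. = FALSE)
    }
    n_blocks <- as.integer(col(10L))
    sizes <- strsplit(sub(",$", "", col(11L)), ",", fixed = TRUE)
    offs <- strsplit(sub(",$", "", col(12L)), ",", fixed = TRUE)
    tx_exons <- vector("list", length(chrom))
    for (i in seq_along(chrom)) {
      sz <- as.numeric(sizes[[i]])
      of <- as.numeric(offs[[i]])
      if (length(sz) != n_blocks[i] || length(of) != n_blocks[i]) {
        stop("BED12 block count mismatch at line ", tab$lineno[i], call. = FALSE)
      }
      es <- start0[i] + of        # 0-based starts
      ee <- es + sz               # 0-based ends
      if (any(ee > end0[i])) {
        stop("gene '", name[i], "' has exon blocks outside its span at line ",
             tab$lineno[i], call. = FALSE)
      }
      tx_exons[[i]] <- cbind(es + 1, ee)
    }
    ids <- unique(name)
    chromv <- strandv <- character(length(ids))
    s1 <- e1 <- numeric(length(ids))
    exlist <- vector("list", length(ids))
    for (j in seq_along(ids)) {
      sel <- which(name == ids[j])
      if (length(unique(chrom[sel])) != 1L ||
          length(unique(strand[sel])) != 1L) {
        stop("gene '", ids[j], "' spans multiple chromosomes or strands",
             call. = FALSE)
      }
      chromv[j] <- chrom[sel[1L]]
      strandv[j] <- strand[sel[1L]]
      s1[j] <- min(start0[sel]) + 1
      e1[j] <- max(end0[sel])
      m <- do.call(rbind, tx_exons[sel])
      exlist[[j]] <- GenomicRanges::reduce(GenomicRanges::GRanges(
        seqnames = chromv[j], ranges = IRanges::IRanges(m[, 1L], m[, 2L])))
    }
    exl <- GenomicRanges::GRangesList(exlist)
    names(exl) <- ids
    .make_gene_models(chromv, s1, e1, strandv, ids, exons = exl,
                      chrom_sizes = chrom_sizes)
  }
}

#' Write gene models
#'
#' `write_gtf()` emits one `gene` feature plus one `exon` feature per merged
#' exon (transcript_id set equal to gene_id); `write_bed12()` emits one
#' BED12 line per gene with exons as blocks (a single block when the model
#' has no exon structure).
#'
#' @param genes Gene models.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_gtf <- function(genes, path) {
  .validate_gene_models(genes)
  con <- file(path, open = "wt")
  on.exit(close(con))
  ex <- S4Vectors::mcols(genes)$exons
  for (i in seq_along(genes)) {
    gid <- S4Vectors::mcols(genes)$gene_id[i]
    chrom <- as.character(GenomeInfoDb::seqnames(genes[i]))
    strand <- as.character(GenomicRanges::strand(genes[i]))
    attr_str <- sprintf('gene_id "%s"; transcript_id "%s";', gid, gid)
    writeLines(sprintf("%s\tgroscore\tgene\t%d\t%d\t.\t%s\t.\t%s",
                       chrom, GenomicRanges::start(genes[i]),
                       GenomicRanges::end(genes[i]), strand, attr_str), con)
    e <- if (is.null(ex)) NULL else ex[[i]]
    if (!is.null(e) && length(e)) {
      writeLines(sprintf("%s\tgroscore\texon\t%d\t%d\t.\t%s\t.\t%s",
                         chrom, GenomicRanges::start(e),
                         GenomicRanges::end(e), strand, attr_str), con)
    }
  }
  invisible(path)
}

#' @rdname write_gtf
#' @export
write_bed12 <- function(genes, path) {
  .validate_gene_models(genes)
  ex <- S4Vectors::mcols(genes)$exons
  lines <- character(length(genes))
  for (i in seq_along(genes)) {
    s0 <- GenomicRanges::start(genes[i]) - 1
    e0 <- GenomicRanges::end(genes[i])
    e <- if (is.null(ex)) NULL else ex[[i]]
    if (is.null(e) || length(e) == 0L) {
      sizes <- e0 - s0
      offs <- 0
    } else {
      sizes <- GenomicRanges::width(e)
      offs <- GenomicRanges::start(e) - 1 - s0
    }
    lines[i] <- paste(
      as.character(GenomeInfoDb::seqnames(genes[i])), s0, e0,
      S4Vectors::mcols(genes)$gene_id[i], 0,
      as.character(GenomicRanges::strand(genes[i])), s0, e0, "0",
      length(sizes), paste0(paste(sizes, collapse = ","), ","),
      paste0(paste(offs, collapse = ","), ","), sep = "\t")
  }
  writeLines(lines, path)
  invisible(path)
}

# ---- chromosome sizes ------------------------------------------------------

#' Read or write a two-column chromosome-sizes file
#' @param path Path to a `<chrom>\t<length>` file.
#' @return Named numeric vector of chromosome lengths.
#' @export
read_chrom_sizes <- function(path) {
  tab <- .read_table_lines(path)
  len <- .parse_coord(vapply(tab$fields, `[[`, character(1L), 2L),
                      "length", tab$lineno)
  chrom <- vapply(tab$fields, `[[`, character(1L), 1L)
  if (anyDuplicated(chrom)) stop("duplicate chromosome in ", path, call. = FALSE)
  stats::setNames(len, chrom)
}

#' @rdname read_chrom_sizes
#' @param sizes Named numeric vector of chromosome lengths.
#' @export
write_chrom_sizes <- function(sizes, path) {
  writeLines(sprintf("%s\t%d", names(sizes), as.integer(sizes)), path)
  invisible(path)
}

# ---- differential expression table ----------------------------------------

#' Read a differential-expression table
#'
#' Expects a tab-delimited file with a header row and columns `gene_id`,
#' `log2FoldChange` (or `log2fc`) and `padj`; `.` or empty marks a missing
#' adjusted p-value (allowed only for unexpressed/filtered genes, which the
#' DE classifier then skips). Duplicate gene ids are a hard error.
#'
#' @param path Path to the TSV.
#' @return A data.frame with columns `gene_id`, `log2fc`, `padj`.
#' @export
read_de_table <- function(path) {
  df <- read.delim(path, header = TRUE, sep = "\t",
                   na.strings = c("NA", ".", ""), stringsAsFactors = FALSE)
  if (!"gene_id" %in% names(df)) stop("DE table lacks gene_id column", call. = FALSE)
  if ("log2FoldChange" %in% names(df) && !"log2fc" %in% names(df)) {
    df$log2fc <- df$log2FoldChange
  }
  if (!all(c("log2fc", "padj") %in% names(df))) {
    stop("DE table needs log2FoldChange (or log2fc) and padj columns",
         call. = FALSE)
  }
  if (anyDuplicated(df$gene_id)) {
    stop("duplicate gene_id in DE table: ",
         df$gene_id[duplicated(df$gene_id)][1L], call. = FALSE)
  }
  if (any(!is.na(df$padj) & (df$padj < 0 | df$padj > 1))) {
    stop("padj outside [0, 1] in ", path, call. = FALSE)
  }
  df[, c("gene_id", "log2fc", "padj")]
}

#' Write a tab-delimited table
#'
#' Header row, UTF-8, `.` for missing values; the package's standard TSV
#' dialect (round-trips through [read_de_table()] for DE tables).
#'
#' @param df A data.frame.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_tsv <- function(df, path) {
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
              col.names = TRUE, na = ".")
  invisible(path)
}

# ---- coverage tracks -------------------------------------------------------

.read_bedgraph_df <- function(path, chrom_sizes = NULL) {
  tab <- .read_table_lines(path)
  if (length(tab$fields) == 0L) {
    return(data.frame(chrom = character(0), start = numeric(0),
                      end = numeric(0), value = numeric(0)))
  }
  nc <- lengths(tab$fields)
  if (any(nc < 4L)) {
    stop("bedGraph record with fewer than 4 columns at line ",
         tab$lineno[which(nc < 4L)[1L]], call. = FALSE)
  }
  col <- function(i) vapply(tab$fields, `[[`, character(1L), i)
  chrom <- col(1L)
  start0 <- .parse_coord(col(2L), "start", tab$lineno)
  end0 <- .parse_coord(col(3L), "end", tab$lineno)
  if (any(start0 >= end0)) {
    stop("start >= end at line ", tab$lineno[which(start0 >= end0)[1L]],
         call. = FALSE)
  }
  value <- suppressWarnings(as.numeric(col(4L)))
  if (anyNA(value) || any(value < 0)) {
    stop("bedGraph value missing or negative at line ",
         tab$lineno[which(is.na(value) | value < 0)[1L]], call. = FALSE)
  }
  .check_chroms(chrom, end0, chrom_sizes, tab$lineno, basename(path))
  # overlapping intervals are disallowed: coverage must be a step function
  o <- order(chrom, start0)
  same <- chrom[o][-1L] == chrom[o][-length(o)]
  clash <- same & start0[o][-1L] < end0[o][-length(o)]
  if (any(clash)) {
    stop("overlapping bedGraph intervals at line ",
         tab$lineno[o][-1L][which(clash)[1L]], call. = FALSE)
  }
  data.frame(chrom = chrom, start = start0, end = end0, value = value)
}

# coverage() accumulates weights by cumulative sums, which can leave
# +/-1e-16 residue where nothing is covered; snap those to exact zero.
.clamp_rle_zero <- function(rlelist, tol = 1e-9) {
  methods::as(lapply(rlelist, function(r) {
    v <- S4Vectors::runValue(r)
    v[abs(v) < tol] <- 0
    # reconstruct so adjacent equal-valued runs re-merge
    S4Vectors::Rle(values = v, lengths = S4Vectors::runLength(r))
  }), "SimpleRleList")
}

.bedgraph_to_rle <- function(df, chrom_sizes) {
  gr <- GenomicRanges::GRanges(
    seqnames = factor(df$chrom, levels = names(chrom_sizes)),
    ranges = IRanges::IRanges(start = df$start + 1, end = df$end))
  GenomeInfoDb::seqlengths(gr) <- unname(chrom_sizes)
  .clamp_rle_zero(GenomicRanges::coverage(gr, weight = df$value))
}

#' Build or read a coverage track
#'
#' A coverage track stores per-chromosome step vectors of non-negative read
#' density (reads per bp) as run-length encodings. A stranded track keeps a
#' plus and a minus component, as produced by stranded chromatin-associated
#' RNA-seq; an unstranded track keeps a single component.
#'
#' @param plus Path to the bedGraph with plus-strand (or all) signal.
#' @param minus Optional path to the minus-strand bedGraph.
#' @param chrom_sizes Optional named chromosome lengths; inferred from the
#'   largest interval end per chromosome when absent.
#' @return An object of class `coverage_track`: a list with elements
#'   `plus` and `minus` ([IRanges::RleList] or `NULL`) and `stranded`.
#' @export
read_coverage <- function(plus, minus = NULL, chrom_sizes = NULL) {
  dfp <- .read_bedgraph_df(plus, chrom_sizes)
  dfm <- if (is.null(minus)) NULL else .read_bedgraph_df(minus, chrom_sizes)
  if (is.null(chrom_sizes)) {
    all_df <- rbind(dfp, dfm)
    if (nrow(all_df) == 0L) stop("empty coverage input", call. = FALSE)
    chrom_sizes <- vapply(split(all_df$end, all_df$chrom), max, numeric(1L))
  }
  coverage_track(.bedgraph_to_rle(dfp, chrom_sizes),
                 if (is.null(dfm)) NULL else .bedgraph_to_rle(dfm, chrom_sizes))
}

#' @rdname read_coverage
#' @param plus_rle,minus_rle RleLists of per-chromosome density.
#' @export
coverage_track <- function(plus_rle, minus_rle = NULL) {
  if (any(unlist(lapply(plus_rle, function(r) any(S4Vectors::runValue(r) < 0))))) {
    stop("coverage density must be non-negative", call. = FALSE)
  }
  structure(list(plus = plus_rle, minus = minus_rle,
                 stranded = !is.null(minus_rle)),
            class = "coverage_track")
}

#' @export
print.coverage_track <- function(x, ...) {
  cat(sprintf("coverage_track: %s, %d chromosome(s)\n",
              if (x$stranded) "stranded" else "unstranded", length(x$plus)))
  invisible(x)
}

# Density vector along [start, end] on the requested strand, 5'->3' in
# genomic orientation (no flipping here; metagene flips).
.track_window <- function(track, chrom, start, end, strand = "*") {
  rle <- if (track$stranded && strand == "-") track$minus else track$plus
  if (!chrom %in% names(rle)) {
    stop("chromosome '", chrom, "' not in coverage track", call. = FALSE)
  }
  v <- rle[[chrom]]
  if (end > length(v)) stop("window beyond chromosome end", call. = FALSE)
  as.numeric(S4Vectors::window(v, start, end))
}

#' Write one strand of a coverage track as bedGraph
#'
#' @param track A `coverage_track`.
#' @param path Output path.
#' @param strand `"+"` or `"-"` (ignored for unstranded tracks).
#' @param drop_zero Omit zero-density runs (conventional for bedGraph).
#' @return Invisibly, `path`.
#' @export
write_bedgraph <- function(track, path, strand = "+", drop_zero = TRUE) {
  rle <- if (track$stranded && strand == "-") track$minus else track$plus
  con <- file(path, open = "wt")
  on.exit(close(con))
  for (chrom in names(rle)) {
    v <- rle[[chrom]]
    ends <- cumsum(S4Vectors::runLength(v))
    starts0 <- c(0, ends[-length(ends)])
    val <- S4Vectors::runValue(v)
    keep <- if (drop_zero) val != 0 else rep(TRUE, length(val))
    if (any(keep)) {
      writeLines(sprintf("%s\t%d\t%d\t%s", chrom, starts0[keep], ends[keep],
                         formatC(val[keep], format = "g", digits = 17)),
                 con)
    }
  }
  invisible(path)
}
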