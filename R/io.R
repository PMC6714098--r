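# File I/O: BED annotations, bedGraph tracks, GTF/BED12 gene models,
# chromosome sizes, SNP positions. All readers/writers go through
# rtracklayer; internal coordinates are 0-based half-open.

#' Read chromosome sizes
#' @param path two-column TSV (chromosome, length in bp), no header.
#' @return a `GenomeLayout`.
#' @export
read_chrom_sizes <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = FALSE,
                          col.names = c("chrom", "length"),
                          stringsAsFactors = FALSE)
  genome_layout(df$chrom, df$length)
}

#' Write chromosome sizes
#' @param layout a `GenomeLayout`.
#' @param path output TSV path.
#' @export
write_chrom_sizes <- function(layout, path) {
  utils::write.table(
    data.frame(chrom = layout$chroms,
               length = format(layout$lengths, scientific = FALSE,
                               trim = TRUE)),
    path, sep = "\t", quote = FALSE, row.names = FALSE, col.names = FALSE)
  invisible(path)
}

# ---- annotations (BED4 / BED9) --------------------------------------------

#' Default display colors for interpretation terms
#' @return named character vector of hex colors.
#' @export
term_colors <- function() {
  c(Quiescent = "#DDDDDD", ConstitutiveHet = "#4B0082",
    FacultativeHet = "#9370DB", Transcribed = "#228B22",
    Promoter = "#FF4500", Enhancer = "#FFA500",
    RegPermissive = "#FFD700", Bivalent = "#C71585",
    Unclassified = "#808080", LowConfidence = "#A9A9A9")
}

#' Write an annotation as BED
#'
#' Without `terms`, writes BED4 with the integer state as the name column.
#' With `terms` (named vector, state label as name), writes BED9 with
#' `stateN_Term` names and term colors in the itemRgb column.
#'
#' @param ann an `Annotation`.
#' @param path output BED path.
#' @param terms optional named character vector mapping state label (as
#'   character) to interpretation term.
#' @export
write_annotation_bed <- function(ann, path, terms = NULL) {
  stopifnot(inherits(ann, "Annotation"))
  seg <- ann$segments
  gr <- .intervals_to_gr(seg)
  if (is.null(terms)) {
    S4Vectors::mcols(gr)$name <- as.character(seg$state)
  } else {
    tm <- unname(terms[as.character(seg$state)])
    if (anyNA(tm)) stop("terms must cover every state present")
    S4Vectors::mcols(gr)$name <- paste0("state", seg$state, "_", tm)
    S4Vectors::mcols(gr)$score <- 0L
    S4Vectors::mcols(gr)$thick <- IRanges::ranges(gr)
    cols <- term_colors()
    S4Vectors::mcols(gr)$itemRgb <- unname(cols[tm])
  }
  rtracklayer::export(gr, path, format = "bed")
  invisible(path)
}

#' Read an annotation from BED
#'
#' Accepts BED4 (name = integer state) or BED9 (name = `stateN_Term`).
#' Segment boundaries not aligned to the resolution grid are snapped to the
#' nearest grid point with a warning, which preserves a partition (a 200-bp
#' ChromHMM segmentation re-bins cleanly to 100 bp without snapping).
#'
#' @param path BED path.
#' @param cell_type identifier to attach.
#' @param resolution bin size in bp.
#' @param n_states optional state count.
#' @return an `Annotation`; when the BED carries terms, a named character
#'   vector mapping state to term is attached as attribute `"terms"`.
#' @export
read_annotation_bed <- function(path, cell_type, resolution = 100,
                                n_states = NULL) {
  gr <- rtracklayer::import(path, format = "bed")
  nm <- S4Vectors::mcols(gr)$name
  if (is.null(nm)) stop("annotation BED requires a name column")
  terms <- NULL
  if (all(grepl("^state[0-9]+_", nm))) {
    states <- as.integer(sub("^state([0-9]+)_.*$", "\\1", nm))
    tms <- sub("^state[0-9]+_", "", nm)
    terms <- tapply(tms, states, function(x) x[1])
    terms <- stats::setNames(as.character(terms), names(terms))
  } else {
    states <- suppressWarnings(as.integer(nm))
    if (anyNA(states))
      stop("annotation BED names must be integer states or 'stateN_Term'")
  }
  seg <- data.frame(chrom = as.character(GenomicRanges::seqnames(gr)),
                    start = GenomicRanges::start(gr) - 1,
                    end = GenomicRanges::end(gr),
                    state = states, stringsAsFactors = FALSE)
  if (any(seg$start %% resolution != 0) || any(seg$end %% resolution != 0)) {
    warning("segments not aligned to ", resolution,
            " bp grid; snapping boundaries to the grid")
    seg$start <- round(seg$start / resolution) * resolution
    seg$end <- round(seg$end / resolution) * resolution
    seg <- seg[seg$end > seg$start, , drop = FALSE]
  }
  ann <- annotation(seg, cell_type, resolution, n_states)
  if (!is.null(terms)) attr(ann, "terms") <- terms
  ann
}

# ---- bedGraph tracks -------------------------------------------------------

#' Write a binned track as bedGraph
#'
#' One row per unmasked bin. Values are rounded to `digits` decimals before
#' writing, so that a written file re-reads to exactly the written values.
#'
#' @param track a `BinnedTrack`.
#' @param path output path.
#' @param digits decimal places kept (default 6).
#' @export
write_track_bedgraph <- function(track, path, digits = 6) {
  stopifnot(inherits(track, "BinnedTrack"))
  bs <- track$bin_size
  parts <- lapply(names(track$values), function(ch) {
    v <- track$values[[ch]]
    keep <- which(!is.na(v))
    if (length(keep) == 0) return(NULL)
    data.frame(chrom = ch, start = (keep - 1) * bs, end = keep * bs,
               score = round(v[keep], digits), stringsAsFactors = FALSE)
  })
  df <- do.call(rbind, parts)
  gr <- .intervals_to_gr(df)
  S4Vectors::mcols(gr)$score <- df$score
  rtracklayer::export(gr, path, format = "bedGraph")
  invisible(path)
}

#' Read a bedGraph (or bigWig) into a binned track
#'
#' Input intervals need not be bin-aligned: values are averaged base-wise
#' within each bin when rebinning finer or unaligned data. Bins with no
#' covering data are masked (`NA`).
#'
#' @param path bedGraph (or bigWig, where supported) path.
#' @param layout a `GenomeLayout` giving chromosome lengths.
#' @param bin_size target bin size in bp.
#' @param format passed to [rtracklayer::import()]; inferred by default.
#' @return a `BinnedTrack` with one vector per layout chromosome.
#' @export
read_track_bedgraph <- function(path, layout, bin_size = 100,
                                format = "bedGraph") {
  gr <- rtracklayer::import(path, format = format)
  df <- data.frame(chrom = as.character(GenomicRanges::seqnames(gr)),
                   start = GenomicRanges::start(gr) - 1,
                   end = GenomicRanges::end(gr),
                   score = S4Vectors::mcols(gr)$score,
                   stringsAsFactors = FALSE)
  values <- lapply(layout$chroms, function(ch) {
    n <- floor(layout$lengths[[ch]] / bin_size)
    acc <- numeric(n); cnt <- numeric(n)
    d <- df[df$chrom == ch, , drop = FALSE]
    if (nrow(d) > 0) {
      aligned <- all(d$start %% bin_size == 0) && all(d$end %% bin_size == 0)
      if (aligned) {
        nb <- (d$end - d$start) / bin_size
        bin <- unlist(mapply(function(s, k) s / bin_size + seq_len(k), d$start,
                             nb, SIMPLIFY = FALSE), use.names = FALSE)
        val <- rep(d$score, times = nb)
        keep <- bin <= n
        acc_tab <- rowsum(val[keep] * bin_size, bin[keep])
        cnt_tab <- rowsum(rep(bin_size, sum(keep)), bin[keep])
        idx <- as.integer(rownames(acc_tab))
        acc[idx] <- acc_tab[, 1]; cnt[idx] <- cnt_tab[, 1]
      } else {
        # base-wise accumulation for arbitrary intervals
        for (i in seq_len(nrow(d))) {
          s <- max(0, d$start[i]); e <- min(n * bin_size, d$end[i])
          if (e <= s) next
          b <- (floor(s / bin_size)):(ceiling(e / bin_size) - 1)
          lo <- pmax(b * bin_size, s); hi <- pmin((b + 1) * bin_size, e)
          acc[b + 1] <- acc[b + 1] + d$score[i] * (hi - lo)
          cnt[b + 1] <- cnt[b + 1] + (hi - lo)
        }
      }
    }
    out <- ifelse(cnt > 0, acc / cnt, NA_real_)
    out
  })
  names(values) <- layout$chroms
  binned_track(values, bin_size)
}

# ---- gene models -----------------------------------------------------------

#' Gene models (one transcript per gene)
#'
#' One row per exon: `gene_id`, `chrom`, `strand` (`+`/`-`), `start`, `end`
#' (0-based half-open), `exon_rank` (1 = 5'-most exon in transcription
#' order). Exons within a gene must be non-overlapping.
#'
#' @param exons data frame as described above.
#' @return an object of class `GeneModels`.
#' @export
gene_models <- function(exons) {
  exons <- as.data.frame(exons)
  need <- c("gene_id", "chrom", "strand", "start", "end")
  stopifnot(all(need %in% names(exons)))
  if (any(exons$end <= exons$start))
    stop("gene model with end <= start")
  if (!all(exons$strand %in% c("+", "-")))
    stop("gene strand must be '+' or '-'")
  exons <- exons[order(exons$gene_id, exons$start), , drop = FALSE]
  # exon rank follows transcription order
  ranks <- unlist(lapply(split(seq_len(nrow(exons)), exons$gene_id),
                         function(i) {
    k <- length(i)
    if (exons$strand[i[1]] == "+") seq_len(k) else rev(seq_len(k))
  }), use.names = FALSE)
  exons$exon_rank <- ranks[order(order(exons$gene_id, exons$start))]
  # overlap check within gene
  for (g in unique(exons$gene_id)) {
    d <- exons[exons$gene_id == g, , drop = FALSE]
    if (nrow(d) > 1 && any(d$start[-1] < d$end[-nrow(d)]))
      stop("exons of gene ", g, " overlap")
  }
  rownames(exons) <- NULL
  structure(list(exons = exons), class = "GeneModels")
}

#' @export
print.GeneModels <- function(x, ...) {
  cat("GeneModels:", length(unique(x$exons$gene_id)), "genes,",
      nrow(x$exons), "exons\n")
  invisible(x)
}

#' Gene-level table (span and TSS) of gene models
#' @param genes a `GeneModels`.
#' @return data frame with one row per gene: `gene_id`, `chrom`, `strand`,
#'   `start`, `end`, `tss` (0-based position of the transcription start).
#' @export
gene_table <- function(genes) {
  ex <- genes$exons
  sp <- do.call(rbind, lapply(split(ex, ex$gene_id), function(d) {
    data.frame(gene_id = d$gene_id[1], chrom = d$chrom[1],
               strand = d$strand[1], start = min(d$start), end = max(d$end),
               stringsAsFactors = FALSE)
  }))
  sp$tss <- ifelse(sp$strand == "+", sp$start, sp$end - 1)
  rownames(sp) <- NULL
  sp
}

#' Read gene models from GTF
#'
#' GTF coordinates (1-based inclusive) are converted to 0-based half-open at
#' this boundary. When a gene has several transcripts, the longest (by
#' genomic span) is kept.
#'
#' @param path GTF path.
#' @return a `GeneModels`.
#' @export
read_genes_gtf <- function(path) {
  gr <- rtracklayer::import(path, format = "gtf")
  gr <- gr[S4Vectors::mcols(gr)$type == "exon"]
  mc <- S4Vectors::mcols(gr)
  df <- data.frame(gene_id = as.character(mc$gene_id),
                   transcript_id = as.character(mc$transcript_id),
                   chrom = as.character(GenomicRanges::seqnames(gr)),
                   strand = as.character(GenomicRanges::strand(gr)),
                   start = GenomicRanges::start(gr) - 1,
                   end = GenomicRanges::end(gr), stringsAsFactors = FALSE)
  # longest transcript per gene
  spans <- lapply(split(df, df$transcript_id), function(d)
    data.frame(transcript_id = d$transcript_id[1], gene_id = d$gene_id[1],
               span = max(d$end) - min(d$start)))
  spans <- do.call(rbind, spans)
  keep <- unlist(lapply(split(spans, spans$gene_id), function(d)
    d$transcript_id[order(-d$span, d$transcript_id)][1]))
  df <- df[df$transcript_id %in% keep, , drop = FALSE]
  gene_models(df[, c("gene_id", "chrom", "strand", "start", "end")])
}

#' Write gene models as GTF
#' @param genes a `GeneModels`.
#' @param path output path.
#' @export
write_genes_gtf <- function(genes, path) {
  ex <- genes$exons
  gr <- GenomicRanges::GRanges(
    ex$chrom, IRanges::IRanges(ex$start + 1, ex$end), strand = ex$strand)
  S4Vectors::mcols(gr)$source <- "stateatlas"
  S4Vectors::mcols(gr)$type <- "exon"
  S4Vectors::mcols(gr)$gene_id <- ex$gene_id
  S4Vectors::mcols(gr)$transcript_id <- paste0(ex$gene_id, ".t1")
  rtracklayer::export(gr, path, format = "gtf")
  invisible(path)
}

#' Read gene models from BED12
#' @param path BED12 path (blocks = exons, one transcript per row).
#' @return a `GeneModels` (longest transcript per name kept).
#' @export
read_genes_bed12 <- function(path) {
  gr <- rtracklayer::import(path, format = "bed")
  blocks <- S4Vectors::mcols(gr)$blocks
  if (is.null(blocks)) stop("BED12 input with block fields required")
  rows <- lapply(seq_along(gr), function(i) {
    b <- blocks[[i]]
    data.frame(gene_id = S4Vectors::mcols(gr)$name[i],
               chrom = as.character(GenomicRanges::seqnames(gr))[i],
               strand = as.character(GenomicRanges::strand(gr))[i],
               start = GenomicRanges::start(gr)[i] - 1 +
                 (IRanges::start(b) - 1),
               end = GenomicRanges::start(gr)[i] - 1 + IRanges::end(b),
               stringsAsFactors = FALSE)
  })
  df <- do.call(rbind, rows)
  df$strand[df$strand == "*"] <- "+"
  gene_models(df)
}

# ---- SNP positions ---------------------------------------------------------

#' Read SNP positions
#'
#' Accepts 3-column BED (chrom, start, end; position = start) or 2-column
#' TSV (chrom, pos). With `one_based = TRUE` the TSV positions are converted
#' from 1-based to the internal 0-based convention.
#'
#' @param path input path.
#' @param one_based treat 2-column input as 1-based positions.
#' @return data frame with columns `chrom`, `pos` (0-based).
#' @export
read_snps <- function(path, one_based = FALSE) {
  df <- utils::read.table(path, sep = "\t", header = FALSE,
                          stringsAsFactors = FALSE)
  if (ncol(df) >= 3 && is.numeric(df[[3]])) {
    out <- data.frame(chrom = df[[1]], pos = df[[2]])
  } else {
    out <- data.frame(chrom = df[[1]], pos = df[[2]] - as.integer(one_based))
  }
  out
}

#' Write SNP positions as 3-column BED
#' @param snps data frame with `chrom`, `pos` (0-based).
#' @param path output path.
#' @export
write_snps_bed <- function(snps, path) {
  utils::write.table(
    data.frame(snps$chrom, format(snps$pos, scientific = FALSE, trim = TRUE),
               format(snps$pos + 1, scientific = FALSE, trim = TRUE)),
    path, sep = "\t", quote = FALSE, row.names = FALSE, col.names = FALSE)
  invisible(path)
}
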