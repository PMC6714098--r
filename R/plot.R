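# Conservation-associated activity plots: stacked per-term score areas with
# encyclopedia segment bars, a conservation lane, and gene pictograms.

#' Build a conservation-associated activity plot
#'
#' Displays a window of the aggregated position score as stacked per-term
#' areas: the total stack height at each bin equals the bin's total score,
#' colored proportionally to the fraction of the score deriving from each
#' term. Optional lanes add encyclopedia segment boundary bars, an absolute
#' conservation (phyloP) area, and box-and-arrow gene pictograms.
#'
#' @param scores a `PositionScoreTrack`.
#' @param chrom,start,end window (bp, 0-based half-open) within scored
#'   territory.
#' @param segments optional data frame from
#'   [extract_encyclopedia_segments()].
#' @param genes optional `GeneModels`.
#' @param phylop optional conservation `BinnedTrack`.
#' @return an object of class `CaaPlot`: list with `plot` (a
#'   ggplot/patchwork object) and `data` (long data frame with `chrom`,
#'   `pos` (bin start), `term`, `score`; summing `score` within a bin
#'   reconstructs the bin's total).
#' @export
build_caa_plot <- function(scores, chrom, start, end, segments = NULL,
                           genes = NULL, phylop = NULL) {
  stopifnot(inherits(scores, "PositionScoreTrack"))
  if (end <= start) stop("empty window")
  bs <- scores$bin_size
  if (!chrom %in% names(scores$total))
    stop("chromosome ", chrom, " not in scored territory")
  b0 <- floor(start / bs) + 1
  b1 <- ceiling(end / bs)
  if (b1 > length(scores$total[[chrom]]))
    stop("window extends beyond scored territory")
  bins <- b0:b1
  bt <- scores$by_term[[chrom]][bins, , drop = FALSE]
  d <- data.frame(chrom = chrom,
                  pos = rep((bins - 1) * bs, times = length(scores$terms)),
                  term = rep(scores$terms, each = length(bins)),
                  score = as.vector(bt), stringsAsFactors = FALSE)
  cols <- term_colors()
  extra <- setdiff(scores$terms, names(cols))
  if (length(extra) > 0)
    cols <- c(cols, stats::setNames(rep("#555555", length(extra)), extra))
  d$term <- factor(d$term, levels = scores$terms)
  p_main <- ggplot2::ggplot(d, ggplot2::aes(x = .data$pos + bs / 2,
                                            y = .data$score,
                                            fill = .data$term)) +
    ggplot2::geom_area(position = "stack") +
    ggplot2::scale_fill_manual(values = cols, name = NULL) +
    ggplot2::labs(x = NULL, y = "activity score",
                  title = paste0(chrom, ":", start, "-", end)) +
    ggplot2::theme_minimal()
  if (!is.null(segments)) {
    sg <- segments[segments$chrom == chrom & segments$end > start &
                     segments$start < end, , drop = FALSE]
    if (nrow(sg) > 0)
      p_main <- p_main +
        ggplot2::annotate("segment", x = pmax(sg$start, start),
                          xend = pmin(sg$end, end), y = 0, yend = 0,
                          linewidth = 2, colour = "black")
  }
  panels <- list(p_main)
  heights <- 3
  if (!is.null(phylop)) {
    pv <- abs(phylop$values[[chrom]][bins])
    dp <- data.frame(pos = (bins - 1) * bs + bs / 2, phylop = pv)
    p_cons <- ggplot2::ggplot(dp, ggplot2::aes(x = .data$pos,
                                               y = .data$phylop)) +
      ggplot2::geom_area(fill = "black") +
      ggplot2::labs(x = NULL, y = "|phyloP|") +
      ggplot2::theme_minimal()
    panels <- c(panels, list(p_cons)); heights <- c(heights, 1)
  }
  if (!is.null(genes)) {
    gt <- gene_table(genes)
    gt <- gt[gt$chrom == chrom & gt$end > start & gt$start < end, ,
             drop = FALSE]
    ex <- genes$exons[genes$exons$gene_id %in% gt$gene_id, , drop = FALSE]
    p_genes <- ggplot2::ggplot() +
      ggplot2::xlim(start, end) + ggplot2::ylim(0, 1) +
      ggplot2::labs(x = paste0("position on ", chrom), y = NULL) +
      ggplot2::theme_minimal() +
      ggplot2::theme(axis.text.y = ggplot2::element_blank())
    if (nrow(gt) > 0) {
      p_genes <- p_genes +
        ggplot2::annotate("segment",
                          x = ifelse(gt$strand == "+", pmax(gt$start, start),
                                     pmin(gt$end, end)),
                          xend = ifelse(gt$strand == "+", pmin(gt$end, end),
                                        pmax(gt$start, start)),
                          y = 0.5, yend = 0.5,
                          arrow = ggplot2::arrow(length =
                                                   ggplot2::unit(4, "pt"))) +
        ggplot2::annotate("rect", xmin = pmax(ex$start, start),
                          xmax = pmin(ex$end, end), ymin = 0.3, ymax = 0.7,
                          fill = "grey30")
    }
    panels <- c(panels, list(p_genes)); heights <- c(heights, 1)
  }
  plt <- if (length(panels) == 1) panels[[1]]
  else patchwork::wrap_plots(panels, ncol = 1, heights = heights)
  structure(list(plot = plt, data = d), class = "CaaPlot")
}

#' @export
print.CaaPlot <- function(x, ...) {
  print(x$plot)
  invisible(x)
}

#' Write the machine-readable data behind a CAA plot
#' @param x a `CaaPlot`.
#' @param path output TSV path.
#' @export
write_caa_plot_data <- function(x, path) {
  stopifnot(inherits(x, "CaaPlot"))
  utils::write.table(x$data, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Save a CAA plot to SVG or PNG
#' @param x a `CaaPlot`.
#' @param path output path (`.svg` or `.png`).
#' @param width,height device size in inches.
#' @export
save_caa_plot <- function(x, path, width = 9, height = 5) {
  stopifnot(inherits(x, "CaaPlot"))
  ggplot2::ggsave(path, x$plot, width = width, height = height)
  invisible(path)
}
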