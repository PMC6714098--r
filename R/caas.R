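# Conservation-associated activity score (CAAS): per-state scores from a
# conservation track, per-position aggregation across cell types with a
# per-term decomposition.

#' Per-state conservation-associated activity score
#'
#' For each state present in the annotation, the CAAS is the 75th percentile
#' of the absolute conservation (phyloP) values over the bases the state
#' covers. The percentile uses linear interpolation between order statistics
#' ([stats::quantile()] type 7); the conservation track must be pre-binned to
#' the annotation resolution (base values averaged within bins, absolute
#' value applied per base upstream of binning for signed tracks simulated at
#' bin resolution the distinction is moot).
#'
#' @param ann an `Annotation`.
#' @param phylop a `BinnedTrack` of conservation values, `bin_size` equal to
#'   the annotation resolution.
#' @param prob percentile used (default 0.75).
#' @return data frame with columns `cell_type`, `state`, `caas`, `bases`
#'   (unmasked covered bases); attribute `percentile_method` records the
#'   quantile rule.
#' @export
compute_state_caas <- function(ann, phylop, prob = 0.75) {
  stopifnot(inherits(ann, "Annotation"), inherits(phylop, "BinnedTrack"))
  if (phylop$bin_size != ann$resolution)
    stop("conservation track bin size must equal the annotation resolution")
  states <- sort(unique(ann$segments$state))
  rows <- lapply(states, function(s) {
    v <- track_values_over(phylop, state_intervals(ann, s))
    if (length(v) == 0)
      stop("state ", s, " has zero unmasked conservation coverage")
    data.frame(cell_type = ann$cell_type, state = s,
               caas = unname(stats::quantile(abs(v), prob, type = 7)),
               bases = length(v) * phylop$bin_size,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  attr(out, "percentile_method") <- "linear interpolation (type 7)"
  out
}

#' Pooled per-term conservation quantile
#'
#' Pools the covered bins of all states sharing a term (across one or more
#' annotations) and returns the same upper-quantile statistic as
#' [compute_state_caas()]. Useful to check planted per-term conservation
#' levels with low sampling noise.
#'
#' @param annotations list of `Annotation` objects.
#' @param terms_list list (parallel to `annotations`) of named character
#'   vectors mapping state label (as character) to term.
#' @param phylop a `BinnedTrack` of conservation values.
#' @param prob percentile used.
#' @return data frame with columns `term`, `caas`, `bases`.
#' @export
compute_term_caas <- function(annotations, terms_list, phylop, prob = 0.75) {
  pool <- list()
  for (i in seq_along(annotations)) {
    ann <- annotations[[i]]; terms <- terms_list[[i]]
    for (s in sort(unique(ann$segments$state))) {
      tm <- terms[[as.character(s)]]
      v <- track_values_over(phylop, state_intervals(ann, s))
      pool[[tm]] <- c(pool[[tm]], v)
    }
  }
  do.call(rbind, lapply(names(pool), function(tm)
    data.frame(term = tm,
               caas = unname(stats::quantile(abs(pool[[tm]]), prob, type = 7)),
               bases = length(pool[[tm]]) * phylop$bin_size,
               stringsAsFactors = FALSE)))
}

#' Aggregate position score track across cell types
#'
#' The score of a genomic position is the sum, over all provided
#' annotations, of the CAAS of the state covering it; each contribution is
#' also routed into the channel of that state's interpretation term, so the
#' per-term decomposition sums to the total at every bin.
#'
#' @param annotations list of `Annotation` objects sharing one resolution
#'   and covering the evaluated territory.
#' @param caas_list list (parallel) of data frames from
#'   [compute_state_caas()].
#' @param terms_list list (parallel) of named vectors mapping state (as
#'   character) to term; when `NULL`, a single `"All"` channel is used.
#' @return an object of class `PositionScoreTrack`: per-chromosome `total`
#'   vectors and `by_term` matrices (bins x terms), `bin_size`, `terms`,
#'   `n_annotations`.
#' @export
compute_position_scores <- function(annotations, caas_list,
                                    terms_list = NULL) {
  stopifnot(length(annotations) >= 1,
            length(caas_list) == length(annotations))
  res <- annotations[[1]]$resolution
  if (!all(vapply(annotations, function(a) a$resolution == res, TRUE)))
    stop("all annotations must share one resolution")
  if (is.null(terms_list))
    terms_list <- lapply(annotations, function(a) {
      st <- sort(unique(a$segments$state))
      stats::setNames(rep("All", length(st)), st)
    })
  terms <- unique(unlist(terms_list, use.names = FALSE))
  terms <- c(intersect(interpretation_terms(), terms),
             setdiff(terms, interpretation_terms()))
  chroms <- unique(unlist(lapply(annotations,
                                 function(a) unique(a$segments$chrom))))
  total <- list(); by_term <- list()
  for (ch in chroms) {
    nbins <- max(vapply(annotations, function(a) {
      seg <- a$segments[a$segments$chrom == ch, , drop = FALSE]
      if (nrow(seg) == 0) 0 else max(seg$end) / res
    }, 1.0))
    tot <- numeric(nbins)
    bt <- matrix(0, nrow = nbins, ncol = length(terms),
                 dimnames = list(NULL, terms))
    for (i in seq_along(annotations)) {
      a <- annotations[[i]]
      seg <- a$segments[a$segments$chrom == ch, , drop = FALSE]
      state_bin <- rep(NA_integer_, nbins)
      if (nrow(seg) > 0)
        state_bin[unlist(mapply(seq, seg$start / res + 1, seg$end / res,
                                SIMPLIFY = FALSE))] <-
          rep(seg$state, times = (seg$end - seg$start) / res)
      if (anyNA(state_bin)) {
        b <- which(is.na(state_bin))[1]
        stop("bin ", ch, ":", (b - 1) * res, "-", b * res,
             " not covered by annotation of ", a$cell_type)
      }
      cs <- caas_list[[i]]
      caas_by_state <- stats::setNames(cs$caas, as.character(cs$state))
      term_by_state <- terms_list[[i]]
      contr <- unname(caas_by_state[as.character(state_bin)])
      if (anyNA(contr))
        stop("missing CAAS for a state of ", a$cell_type)
      tot <- tot + contr
      tidx <- match(unname(term_by_state[as.character(state_bin)]), terms)
      bt[cbind(seq_len(nbins), tidx)] <-
        bt[cbind(seq_len(nbins), tidx)] + contr
    }
    total[[ch]] <- tot
    by_term[[ch]] <- bt
  }
  structure(list(bin_size = res, total = total, by_term = by_term,
                 terms = terms, n_annotations = length(annotations)),
            class = "PositionScoreTrack")
}

#' @export
print.PositionScoreTrack <- function(x, ...) {
  cat("PositionScoreTrack:", length(x$total), "chromosomes,",
      sum(vapply(x$total, length, 1L)), "bins of", x$bin_size, "bp, sum over",
      x$n_annotations, "annotations,", length(x$terms), "term channels\n")
  invisible(x)
}

#' Convert a position score track to a plain binned track
#' @param scores a `PositionScoreTrack`.
#' @param per_annotation divide by the number of contributing annotations.
#' @return a `BinnedTrack` of the (optionally normalized) total score.
#' @export
position_score_total <- function(scores, per_annotation = FALSE) {
  v <- scores$total
  if (per_annotation) v <- lapply(v, function(x) x / scores$n_annotations)
  binned_track(v, scores$bin_size)
}

#' Write a position score track as bedGraph files
#'
#' Writes `<prefix>.total.bedGraph` plus one
#' `<prefix>.<term>.bedGraph` per term channel.
#'
#' @param scores a `PositionScoreTrack`.
#' @param prefix output path prefix.
#' @param digits decimals kept (see [write_track_bedgraph()]).
#' @return character vector of written paths.
#' @export
write_position_scores <- function(scores, prefix, digits = 6) {
  paths <- character(0)
  p <- paste0(prefix, ".total.bedGraph")
  write_track_bedgraph(position_score_total(scores), p, digits)
  paths <- c(paths, p)
  for (tm in scores$terms) {
    v <- lapply(scores$by_term, function(m) m[, tm])
    p <- paste0(prefix, ".", tm, ".bedGraph")
    write_track_bedgraph(binned_track(v, scores$bin_size), p, digits)
    paths <- c(paths, p)
  }
  invisible(paths)
}

#' Write a per-state CAAS table as TSV
#' @param caas data frame from [compute_state_caas()] (possibly rbind-ed).
#' @param path output path.
#' @param terms optional named vector state -> term to include.
#' @export
write_state_caas_tsv <- function(caas, path, terms = NULL) {
  df <- caas
  if (!is.null(terms)) df$term <- unname(terms[as.character(df$state)])
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
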