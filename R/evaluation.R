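# Evaluation procedures: meta-gene term profiles, annotation-overlap
# enrichment matrices, expression predictiveness by ridge regression over
# one-hot promoter-window state features, and SNP enrichment curves.

#' Meta-gene (idealized gene) enrichment profile
#'
#' Genes are length-normalized onto a fixed axis: an upstream flank sampled
#' at the annotation resolution, a scaled gene body, and a downstream flank
#' (strand-aware). Each cell is `log2(observed term frequency at the
#' position / genome-wide term frequency)`.
#'
#' @param ann an `Annotation`.
#' @param terms named character vector mapping state (as character) to term.
#' @param genes a `GeneModels`.
#' @param n_body_bins number of positions across the scaled gene body.
#' @param flank_bp flank span sampled on each side.
#' @param cap floor for `log2(0)` cells (`NULL` keeps `-Inf`).
#' @return matrix `terms x positions` of log2 enrichments, with a
#'   `positions` attribute giving the axis labels.
#' @export
metagene_profile <- function(ann, terms, genes, n_body_bins = 40,
                             flank_bp = 5000, cap = -8) {
  stopifnot(inherits(ann, "Annotation"), inherits(genes, "GeneModels"))
  res <- ann$resolution
  nf <- flank_bp / res
  gt <- gene_table(genes)
  lev <- unique(unname(terms))
  lev <- c(intersect(interpretation_terms(), lev),
           setdiff(lev, interpretation_terms()))
  npos <- nf + n_body_bins + nf
  counts <- matrix(0, nrow = length(lev), ncol = npos,
                   dimnames = list(lev, NULL))
  used <- 0
  for (g in seq_len(nrow(gt))) {
    ch <- gt$chrom[g]; plus <- gt$strand[g] == "+"
    glen <- gt$end[g] - gt$start[g]
    up <- (seq_len(nf) - 0.5) * res
    body <- (seq_len(n_body_bins) - 0.5) / n_body_bins * glen
    down <- (seq_len(nf) - 0.5) * res
    pos <- if (plus)
      c(gt$start[g] - rev(up), gt$start[g] + body, gt$end[g] + down)
    else
      c(gt$end[g] + rev(up), gt$end[g] - body, gt$start[g] - down)
    bins <- floor(pos / res)
    seg <- ann$segments[ann$segments$chrom == ch, , drop = FALSE]
    if (nrow(seg) == 0) next
    maxbin <- max(seg$end) / res
    if (any(bins < 0) || any(bins >= maxbin)) next
    lab <- bin_labels(ann, ch, 0, maxbin * res)[bins + 1]
    tm <- unname(terms[as.character(lab)])
    counts[cbind(match(tm, lev), seq_len(npos))] <-
      counts[cbind(match(tm, lev), seq_len(npos))] + 1
    used <- used + 1
  }
  if (used == 0) stop("no gene fully inside annotated territory")
  obs <- counts / used
  # genome-wide term frequency from base coverage
  segterm <- unname(terms[as.character(ann$segments$state)])
  wid <- ann$segments$end - ann$segments$start
  gfreq <- vapply(lev, function(tm) sum(wid[segterm == tm]) / sum(wid), 1.0)
  enr <- log2(sweep(obs, 1, gfreq, "/"))
  if (!is.null(cap)) enr[enr == -Inf] <- cap
  attr(enr, "positions") <- c(paste0("up", rev(seq_len(nf))),
                              paste0("body", seq_len(n_body_bins)),
                              paste0("down", seq_len(nf)))
  attr(enr, "n_genes") <- used
  enr
}

#' Term-by-term overlap enrichment between two annotations
#'
#' `cell(t_a, t_b) = log2((overlap + 1) / (expected + 1))` with
#' `expected = n_a * n_b / n`: the bases annotated `t_a` in `a` and `t_b`
#' in `b`, relative to independence over a genome of `n` bases (same
#' pseudocount as the state enrichment formula).
#'
#' @param a,b `Annotation` objects on the same genome.
#' @param terms_a,terms_b named vectors mapping state (as character) to
#'   term.
#' @param layout a `GenomeLayout`.
#' @return matrix `terms(a) x terms(b)` of log2 enrichments.
#' @export
annotation_overlap_matrix <- function(a, terms_a, b, terms_b, layout) {
  n <- genome_size(layout)
  term_iv <- function(ann, terms) {
    tl <- unique(unname(terms))
    tl <- c(intersect(interpretation_terms(), tl),
            setdiff(tl, interpretation_terms()))
    ivs <- lapply(tl, function(tm) {
      st <- as.integer(names(terms)[terms == tm])
      df <- ann$segments[ann$segments$state %in% st,
                         c("chrom", "start", "end"), drop = FALSE]
      .as_interval_df(GenomicRanges::reduce(.intervals_to_gr(df)))
    })
    stats::setNames(ivs, tl)
  }
  iva <- term_iv(a, terms_a); ivb <- term_iv(b, terms_b)
  out <- matrix(NA_real_, length(iva), length(ivb),
                dimnames = list(names(iva), names(ivb)))
  for (ta in names(iva)) for (tb in names(ivb)) {
    ov <- overlap_bases(iva[[ta]], ivb[[tb]])
    expd <- covered_bases(iva[[ta]]) * covered_bases(ivb[[tb]]) / n
    out[ta, tb] <- log2((ov + 1) / (expd + 1))
  }
  out
}

# ---- expression predictiveness --------------------------------------------

#' Promoter-window position offsets
#'
#' The 38 sampled positions of the regression feature layout: 20 positions
#' over the 2 kbp centered on the promoter at 100-bp steps (half-open,
#' `-1000` to `+900`), plus 9 upstream and 9 downstream positions over
#' 10-2 kbp at 1-kbp steps.
#'
#' @param resolution annotation resolution in bp.
#' @return integer vector of 38 offsets in bp relative to the TSS (plus
#'   strand; mirrored on minus).
#' @export
promoter_window_offsets <- function(resolution = 100) {
  c(seq(-10000, -2000, by = 1000),
    seq(-1000, 1000 - resolution, by = resolution),
    seq(2000, 10000, by = 1000))
}

.one_hot_features <- function(ann, genes) {
  res <- ann$resolution
  offs <- promoter_window_offsets(res)
  gt <- gene_table(genes)
  n_states <- ann$n_states
  # per-chromosome label vectors
  labs <- list()
  for (ch in unique(ann$segments$chrom)) {
    seg <- ann$segments[ann$segments$chrom == ch, , drop = FALSE]
    labs[[ch]] <- bin_labels(ann, ch, 0, max(seg$end))
  }
  keep <- logical(nrow(gt))
  X <- matrix(0L, nrow = nrow(gt), ncol = length(offs) * n_states)
  for (g in seq_len(nrow(gt))) {
    ch <- gt$chrom[g]
    o <- if (gt$strand[g] == "+") offs else -offs
    pos <- gt$tss[g] + o
    bins <- floor(pos / res)
    lv <- labs[[ch]]
    if (is.null(lv) || any(bins < 0) || any(bins >= length(lv))) next
    st <- lv[bins + 1]
    X[g, (seq_along(offs) - 1) * n_states + st + 1] <- 1L
    keep[g] <- TRUE
  }
  if (any(!keep))
    warning(sum(!keep), " gene(s) dropped: promoter window out of bounds")
  list(X = X[keep, , drop = FALSE], gene_id = gt$gene_id[keep],
       offsets = offs)
}

.ridge_fit_r2 <- function(X, y, train, lambda) {
  Xtr <- X[train, , drop = FALSE]; ytr <- y[train]
  Xte <- X[-train, , drop = FALSE]; yte <- y[-train]
  cx <- colMeans(Xtr); cy <- mean(ytr)
  Xc <- sweep(Xtr, 2, cx); yc <- ytr - cy
  p <- ncol(X)
  beta <- solve(crossprod(Xc) + lambda * diag(p), crossprod(Xc, yc))
  pred <- sweep(Xte, 2, cx) %*% beta + cy
  1 - sum((yte - pred)^2) / sum((yte - mean(yte))^2)
}

#' Expression predictiveness of an annotation
#'
#' How well gene expression can be predicted from the annotation states
#' around the promoter. Each gene contributes a one-hot feature vector of
#' length `38 * n_states` (1 iff the sampled position carries the state);
#' genes are split into quintiles by their variance of `log(x + 1)`
#' expression across cell types, and a separate L2-regularized linear
#' regressor is fit per quintile on a train split and scored as fraction of
#' variance explained on the held-out genes.
#'
#' @param ann an `Annotation`.
#' @param genes a `GeneModels`.
#' @param expression numeric matrix genes x cell types (raw scale;
#'   `log(x+1)` applied internally), rownames = gene ids, one column named
#'   after the annotation's cell type.
#' @param lambda ridge penalty (penalized-RSS parameterization).
#' @param n_quintiles number of variance groups.
#' @param train_frac fraction of each quintile used for training.
#' @param seed RNG seed for the split.
#' @param permute permute expression labels across genes first (negative
#'   control).
#' @return data frame with one row per quintile (`quintile` 1 = lowest
#'   variance): `r2`, `n_train`, `n_test`; the position layout is attached
#'   as attribute `offsets`.
#' @export
expression_predictiveness <- function(ann, genes, expression, lambda = 1000,
                                      n_quintiles = 5, train_frac = 0.8,
                                      seed = 1, permute = FALSE) {
  stopifnot(inherits(ann, "Annotation"))
  ct <- ann$cell_type
  if (!ct %in% colnames(expression))
    stop("expression matrix lacks cell type ", ct)
  feats <- .one_hot_features(ann, genes)
  ids <- feats$gene_id
  if (!all(ids %in% rownames(expression)))
    stop("expression matrix lacks some genes")
  lx <- log(expression[ids, , drop = FALSE] + 1)
  y <- lx[, ct]
  set.seed(seed)
  if (permute) y <- y[sample(length(y))]
  v <- apply(lx, 1, stats::var)
  qs <- stats::quantile(v, probs = seq(0, 1, length.out = n_quintiles + 1))
  grp <- cut(v, breaks = unique(qs), include.lowest = TRUE, labels = FALSE)
  # collapse if variance ties reduced the group count
  rows <- lapply(sort(unique(grp)), function(q) {
    idx <- which(grp == q)
    if (length(idx) < 10)
      stop("fewer than 10 genes in variance group ", q)
    ntr <- floor(train_frac * length(idx))
    tr <- sort(sample(length(idx), ntr))
    r2 <- .ridge_fit_r2(feats$X[idx, , drop = FALSE], y[idx], tr, lambda)
    data.frame(quintile = q, r2 = r2, n_train = ntr,
               n_test = length(idx) - ntr)
  })
  out <- do.call(rbind, rows)
  attr(out, "offsets") <- feats$offsets
  out
}

# ---- SNP enrichment --------------------------------------------------------

#' SNP enrichment over score-ranked genome fractions
#'
#' Orders genome bins by descending position score and reports, for each
#' genome fraction `X`, the cumulative fraction of SNPs falling in the top
#' `X` of that ordering, plus the fraction of the genome scoring strictly
#' below the median SNP score.
#'
#' @param scores a `PositionScoreTrack`.
#' @param snps data frame with `chrom`, `pos` (0-based).
#' @param grid genome fractions at which the curve is evaluated.
#' @return list with `curve` (data frame `x`, `captured`; non-decreasing,
#'   ends at 1), `median_genome_percentile`, `n_snps`, `n_dropped`.
#' @export
snp_enrichment_curve <- function(scores, snps,
                                 grid = seq(0, 1, by = 0.005)) {
  stopifnot(inherits(scores, "PositionScoreTrack"))
  bs <- scores$bin_size
  chroms <- names(scores$total)
  all_scores <- unlist(scores$total, use.names = FALSE)
  offsets <- cumsum(c(0, head(vapply(scores$total, length, 1L), -1)))
  names(offsets) <- chroms
  bin_of <- function(ch, pos) {
    b <- floor(pos / bs) + 1
    ok <- ch %in% chroms & b >= 1 &
      b <= vapply(ch, function(c_) length(scores$total[[c_]]), 1L)
    ifelse(ok, offsets[ch] + b, NA_real_)
  }
  sb <- bin_of(as.character(snps$chrom), snps$pos)
  n_dropped <- sum(is.na(sb))
  sb <- sb[!is.na(sb)]
  if (length(sb) == 0) stop("no SNP within scored territory")
  nb <- length(all_scores)
  # rank 1 = highest score; ties resolved by genomic order (stable)
  ord <- order(-all_scores)
  rank_of <- integer(nb); rank_of[ord] <- seq_len(nb)
  snp_frac <- rank_of[sb] / nb
  captured <- vapply(grid, function(x) mean(snp_frac <= x), 1.0)
  med <- stats::median(all_scores[sb])
  list(curve = data.frame(x = grid, captured = captured),
       median_genome_percentile = mean(all_scores < med),
       n_snps = length(sb), n_dropped = n_dropped)
}

#' Average single-annotation SNP enrichment curve
#'
#' Runs [snp_enrichment_curve()] once per contributing annotation (each
#' annotation's own CAAS painted along the genome) and averages the curves.
#'
#' @param annotations list of `Annotation` objects.
#' @param caas_list parallel list of [compute_state_caas()] tables.
#' @param snps data frame with `chrom`, `pos`.
#' @param grid genome fractions.
#' @return data frame `x`, `captured` (mean), `captured_sd`.
#' @export
snp_curve_single_average <- function(annotations, caas_list, snps,
                                     grid = seq(0, 1, by = 0.005)) {
  curves <- vapply(seq_along(annotations), function(i) {
    sc <- compute_position_scores(annotations[i], caas_list[i])
    snp_enrichment_curve(sc, snps, grid)$curve$captured
  }, numeric(length(grid)))
  data.frame(x = grid, captured = rowMeans(curves),
             captured_sd = apply(curves, 1, stats::sd))
}
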