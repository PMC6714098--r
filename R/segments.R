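# Encyclopedia segment extraction: maximal contiguous segments of high
# baseline-subtracted conservation-associated activity, plus an exhaustive
# brute-force oracle used for testing.
#
# Scores are per position (per bp); a bin of width b with position score f
# contributes b * (f - Z) to a segment's total, so the thresholds S (total),
# M (mean per bp), L (length in bp) and D (valley depth) are all on the
# per-base scale of the published parameters.

#' Segmentation parameters
#'
#' @param Z baseline subtracted from the per-position score.
#' @param D valley threshold: an internal subsegment with total score at or
#'   below `-D` splits a candidate (rule `"split"`); rule `"literal"`
#'   instead rejects candidates containing an internal subsegment scoring at
#'   or above `D`.
#' @param S minimum total baseline-subtracted score of a segment.
#' @param M_min minimum mean score per bp.
#' @param L_min minimum segment length in bp.
#' @return an object of class `SegmentationParams`.
#' @export
segmentation_params <- function(Z = 0.775, D = 1, S = 5, M_min = 0.02,
                                L_min = 500) {
  stopifnot(is.finite(Z), is.finite(D), is.finite(S), is.finite(M_min),
            is.finite(L_min), S > 0, L_min > 0)
  structure(list(Z = Z, D = D, S = S, M_min = M_min, L_min = L_min),
            class = "SegmentationParams")
}

#' Named segmentation presets
#' @param name preset name; `"paper-2019"` is `Z=0.775, D=1, S=5, M=0.02,
#'   L=500 bp`, defined on the per-annotation (mean) score scale.
#' @return a `SegmentationParams`.
#' @export
preset_params <- function(name = "paper-2019") {
  switch(name,
         "paper-2019" = segmentation_params(Z = 0.775, D = 1, S = 5,
                                            M_min = 0.02, L_min = 500),
         stop("unknown preset: ", name))
}

# shared candidate filters + greedy overlap resolution ----------------------

# interior min (or max) subarray total of bins strictly inside [u, v-1],
# in prefix-sum index space: pairs x < y within P-indices [u+1, v-1].
.interior_extreme <- function(P, u, v, maximum = FALSE) {
  l <- u + 1; r <- v - 1
  if (r - l < 1) return(if (maximum) -Inf else Inf)
  run <- P[l]; m <- if (maximum) -Inf else Inf
  for (y in (l + 1):r) {
    d <- P[y] - run
    if (maximum) {
      if (d > m) m <- d
      if (P[y] < run) run <- P[y]
    } else {
      if (d < m) m <- d
      if (P[y] > run) run <- P[y]
    }
  }
  m
}

.valley_ok <- function(P, u, v, D, rule) {
  if (rule == "split") .interior_extreme(P, u, v, FALSE) > -D
  else .interior_extreme(P, u, v, TRUE) < D
}

# first index of non-increasing vector x with x[idx] < thr (binary search)
.first_less <- function(x, thr) {
  lo <- 1L; hi <- length(x) + 1L
  while (lo < hi) {
    mid <- (lo + hi) %/% 2L
    if (x[mid] < thr) hi <- mid else lo <- mid + 1L
  }
  lo
}

.greedy_select <- function(cand, n) {
  if (nrow(cand) == 0) return(cand)
  cand <- cand[order(-cand$score, cand$start_bin, cand$end_bin), ,
               drop = FALSE]
  occ <- logical(n)
  keep <- logical(nrow(cand))
  for (k in seq_len(nrow(cand))) {
    b <- cand$start_bin[k]:cand$end_bin[k]
    if (!any(occ[b])) { occ[b] <- TRUE; keep[k] <- TRUE }
  }
  out <- cand[keep, , drop = FALSE]
  out[order(out$start_bin), , drop = FALSE]
}

.empty_segments <- function() {
  data.frame(start_bin = integer(), end_bin = integer(), score = numeric(),
             mean_bp = numeric(), length_bp = numeric())
}

# maximal-candidate search via prefix-sum structure: an interval is maximal
# (no strict super-interval with strictly larger total) iff its left
# boundary attains the running prefix minimum and its right boundary the
# running suffix maximum of the prefix sums.
.maximal_segments <- function(s, params, bin_size,
                              valley_rule = c("split", "literal")) {
  valley_rule <- match.arg(valley_rule)
  n <- length(s)
  if (n == 0) return(.empty_segments())
  L_bins <- params$L_min / bin_size
  if (L_bins != floor(L_bins))
    stop("L_min must be a multiple of the bin size")
  P <- c(0, cumsum(s))
  A <- which(P == cummin(P)); A <- A[A <= n]
  B <- which(P == rev(cummax(rev(P)))); B <- B[B >= 2]
  PA <- P[A]
  rows <- list(); nr <- 0
  for (v in B) {
    # prefilter with slack; the exact strict test on the score follows
    thr <- P[v] - params$S
    j <- .first_less(PA, thr + 1e-9 * (1 + abs(thr)))
    if (j > length(A)) next
    for (u in A[j:length(A)]) {
      if (u > v - L_bins) break
      score <- P[v] - P[u]
      if (!(score > params$S)) next
      len_bp <- (v - u) * bin_size
      if (score / len_bp < params$M_min) next
      if (!.valley_ok(P, u, v, params$D, valley_rule)) next
      nr <- nr + 1
      rows[[nr]] <- c(u, v - 1, score, score / len_bp, len_bp)
    }
  }
  if (nr == 0) return(.empty_segments())
  m <- do.call(rbind, rows)
  cand <- data.frame(start_bin = as.integer(m[, 1]),
                     end_bin = as.integer(m[, 2]), score = m[, 3],
                     mean_bp = m[, 4], length_bp = m[, 5])
  .greedy_select(cand, n)
}

#' Brute-force encyclopedia segment oracle
#'
#' Exhaustively enumerates every interval of a (short) per-bin score
#' sequence, filters by every constraint (total score, mean, length, valley
#' rule), checks maximality against all super-intervals, and resolves
#' overlaps highest-score-first (ties by leftmost start) — the same rule as
#' the production extractor. Intended as an independent testing oracle.
#'
#' @param s numeric vector of per-bin baseline-subtracted scores, already
#'   weighted per base (bin contribution = `bin_size * (f - Z)`); `Z` of
#'   `params` is therefore not applied here.
#' @param params a `SegmentationParams`.
#' @param bin_size bin width in bp.
#' @param valley_rule `"split"` or `"literal"` (see
#'   [segmentation_params()]).
#' @param max_bins refuse longer inputs (enumeration is quadratic).
#' @return data frame of segments: `start_bin`, `end_bin` (1-based,
#'   inclusive), `score`, `mean_bp`, `length_bp`.
#' @export
brute_force_segments <- function(s, params, bin_size = 100,
                                 valley_rule = c("split", "literal"),
                                 max_bins = 500) {
  valley_rule <- match.arg(valley_rule)
  n <- length(s)
  if (n == 0) return(.empty_segments())
  if (n > max_bins)
    stop("brute-force oracle capped at ", max_bins, " bins")
  L_bins <- params$L_min / bin_size
  if (L_bins != floor(L_bins))
    stop("L_min must be a multiple of the bin size")
  P <- c(0, cumsum(s))
  # all interval totals: sc[i, j] = sum of bins i..j = P[j+1] - P[i]
  sc <- outer(-P[1:n], P[2:(n + 1)], "+")
  # max total over all super-intervals (i' <= i, j' >= j)
  M2 <- sc
  if (n > 1) {
    for (j in (n - 1):1) M2[, j] <- pmax(M2[, j], M2[, j + 1])
    for (i in 2:n) M2[i, ] <- pmax(M2[i, ], M2[i - 1, ])
  }
  # K[l, r]: extreme subarray total within bins l..r (min for "split",
  # max for "literal")
  K <- matrix(if (valley_rule == "split") Inf else -Inf, n, n)
  for (l in 1:n) {
    if (valley_rule == "split") {
      me <- P[(l + 1):(n + 1)] - cummax(P[l:n])
      K[l, l:n] <- cummin(me)
    } else {
      me <- P[(l + 1):(n + 1)] - cummin(P[l:n])
      K[l, l:n] <- cummax(me)
    }
  }
  rows <- list(); nr <- 0
  for (i in 1:n) for (j in i:n) {
    score <- sc[i, j]
    if (!(score > params$S)) next
    len_bp <- (j - i + 1) * bin_size
    if (len_bp < params$L_min) next
    if (score / len_bp < params$M_min) next
    if (M2[i, j] > score) next                     # a super-interval beats it
    if (j - 1 >= i + 1) {
      kk <- K[i + 1, j - 1]
      if (valley_rule == "split") { if (kk <= -params$D) next }
      else if (kk >= params$D) next
    }
    nr <- nr + 1
    rows[[nr]] <- c(i, j, score, score / len_bp, len_bp)
  }
  if (nr == 0) return(.empty_segments())
  m <- do.call(rbind, rows)
  cand <- data.frame(start_bin = as.integer(m[, 1]),
                     end_bin = as.integer(m[, 2]), score = m[, 3],
                     mean_bp = m[, 4], length_bp = m[, 5])
  .greedy_select(cand, n)
}

#' Extract encyclopedia segments from a position score track
#'
#' A segment is a contiguous genomic interval whose total baseline-
#' subtracted score `s([i,j]) = sum_k bin_size * (f_k - Z)` exceeds `S`, is
#' maximal (no strict super-interval scores strictly higher), has mean score
#' per bp at least `M_min` and length at least `L_min`, and contains no
#' internal valley per the valley rule. Overlapping maximal candidates are
#' resolved highest score first (ties by leftmost start). The shipped
#' `"paper-2019"` preset is defined on the per-annotation mean score, hence
#' the default `normalize = "per_annotation"`.
#'
#' @param scores a `PositionScoreTrack`.
#' @param params a `SegmentationParams` (see [preset_params()]).
#' @param normalize `"per_annotation"` (divide the total by the number of
#'   contributing annotations before subtracting `Z`) or `"none"`.
#' @param valley_rule `"split"` (default) or `"literal"`.
#' @return data frame of segments, sorted and non-overlapping: `chrom`,
#'   `start`, `end` (bp, 0-based half-open), `score`, `mean_bp`,
#'   `length_bp`, `dominant_term`, plus one `frac_<term>` column per term
#'   channel giving the share of the raw position score attributable to the
#'   term within the segment.
#' @export
extract_encyclopedia_segments <- function(scores, params = preset_params(),
                                          normalize = c("per_annotation",
                                                        "none"),
                                          valley_rule = c("split",
                                                          "literal")) {
  stopifnot(inherits(scores, "PositionScoreTrack"),
            inherits(params, "SegmentationParams"))
  normalize <- match.arg(normalize)
  valley_rule <- match.arg(valley_rule)
  bs <- scores$bin_size
  out <- list()
  for (ch in names(scores$total)) {
    f <- scores$total[[ch]]
    if (normalize == "per_annotation") f <- f / scores$n_annotations
    s <- (f - params$Z) * bs
    seg <- .maximal_segments(s, params, bs, valley_rule)
    if (nrow(seg) == 0) next
    bt <- scores$by_term[[ch]]
    frv <- vapply(seq_len(nrow(seg)), function(k) {
      b <- seg$start_bin[k]:seg$end_bin[k]
      tot <- sum(scores$total[[ch]][b])
      if (tot > 0) colSums(bt[b, , drop = FALSE]) / tot
      else rep(NA_real_, ncol(bt))
    }, numeric(ncol(bt)))
    fr <- if (is.matrix(frv)) t(frv) else matrix(frv, ncol = ncol(bt))
    colnames(fr) <- paste0("frac_", scores$terms)
    dom <- scores$terms[max.col(fr, ties.method = "first")]
    out[[ch]] <- cbind(
      data.frame(chrom = ch, start = (seg$start_bin - 1) * bs,
                 end = seg$end_bin * bs, score = seg$score,
                 mean_bp = seg$mean_bp, length_bp = seg$length_bp,
                 dominant_term = dom, stringsAsFactors = FALSE),
      as.data.frame(fr))
  }
  if (length(out) == 0)
    return(cbind(data.frame(chrom = character(), start = numeric(),
                            end = numeric(), score = numeric(),
                            mean_bp = numeric(), length_bp = numeric(),
                            dominant_term = character()),
                 stats::setNames(as.data.frame(
                   matrix(numeric(), 0, length(scores$terms))),
                   paste0("frac_", scores$terms))))
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res[order(res$chrom, res$start), , drop = FALSE]
}

#' Write encyclopedia segments as BED6+
#'
#' Columns: chrom, start, end, dominant term, total score, strand (`.`),
#' then mean score and the per-term fractions.
#'
#' @param segments data frame from [extract_encyclopedia_segments()].
#' @param path output path.
#' @export
write_encyclopedia_bed <- function(segments, path) {
  fr <- segments[, grep("^frac_", names(segments)), drop = FALSE]
  df <- data.frame(segments$chrom,
                   format(segments$start, scientific = FALSE, trim = TRUE),
                   format(segments$end, scientific = FALSE, trim = TRUE),
                   segments$dominant_term, round(segments$score, 6), ".",
                   round(segments$mean_bp, 6), round(fr, 6))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     col.names = FALSE)
  invisible(path)
}
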