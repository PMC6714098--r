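# Per-state feature vectors for the interpretation classifier: mean
# normalized histone-mark signal plus log2 enrichment in nine gene
# components.

#' Canonical histone marks used as signal-mean features
#'
#' Five core marks plus a configurable sixth slot (default H3K9ac, the
#' second characteristic promoter mark).
#'
#' @param include_sixth include the sixth mark (default `TRUE`).
#' @param sixth name of the sixth mark.
#' @return character vector of assay names.
#' @export
canonical_marks <- function(include_sixth = TRUE, sixth = "H3K9ac") {
  m <- c("H3K27me3", "H3K4me3", "H3K36me3", "H3K4me1", "H3K9me3")
  if (include_sixth) m <- c(m, sixth)
  m
}

#' Names of the nine gene components
#' @return character vector in canonical feature order.
#' @export
gene_component_names <- function() {
  c("flank5_far", "flank5_near", "initial_exon", "initial_intron",
    "internal_exons", "internal_introns", "terminal_exon",
    "flank3_near", "flank3_far")
}

#' Derive the nine gene components from gene models
#'
#' Strand-aware decomposition of each gene into: 1-10 kbp 5' flank, 1 bp -
#' 1 kbp 5' flank, initial exon, initial intron, internal exons, internal
#' introns, terminal exon, 1 bp - 1 kbp 3' flank, and 1-10 kbp 3' flank.
#' Single-exon genes contribute only the initial exon and the flanks.
#' Flanks are clipped at chromosome boundaries; the intervals of each
#' component are merged across genes.
#'
#' @param genes a `GeneModels`.
#' @param layout a `GenomeLayout` (for boundary clipping).
#' @return named list of merged interval data frames, one per component.
#' @export
derive_gene_components <- function(genes, layout) {
  stopifnot(inherits(genes, "GeneModels"), inherits(layout, "GenomeLayout"))
  comp <- stats::setNames(
    rep(list(list()), length(gene_component_names())), gene_component_names())
  add <- function(comp, name, chrom, start, end, maxlen) {
    start <- max(0, start); end <- min(maxlen, end)
    if (end > start)
      comp[[name]] <- c(comp[[name]],
                        list(data.frame(chrom = chrom, start = start,
                                        end = end)))
    comp
  }
  for (d in split(genes$exons, genes$exons$gene_id)) {
    d <- d[order(d$exon_rank), , drop = FALSE]
    ch <- d$chrom[1]; plus <- d$strand[1] == "+"
    maxlen <- layout$lengths[[ch]]
    if (is.null(maxlen)) stop("gene on unknown chromosome ", ch)
    gstart <- min(d$start); gend <- max(d$end)
    k <- nrow(d)
    # flanks (5' upstream of TSS, 3' downstream of TES, strand-aware)
    if (plus) {
      comp <- add(comp, "flank5_near", ch, gstart - 1000, gstart, maxlen)
      comp <- add(comp, "flank5_far", ch, gstart - 10000, gstart - 1000,
                  maxlen)
      comp <- add(comp, "flank3_near", ch, gend, gend + 1000, maxlen)
      comp <- add(comp, "flank3_far", ch, gend + 1000, gend + 10000, maxlen)
    } else {
      comp <- add(comp, "flank5_near", ch, gend, gend + 1000, maxlen)
      comp <- add(comp, "flank5_far", ch, gend + 1000, gend + 10000, maxlen)
      comp <- add(comp, "flank3_near", ch, gstart - 1000, gstart, maxlen)
      comp <- add(comp, "flank3_far", ch, gstart - 10000, gstart - 1000,
                  maxlen)
    }
    # exons by transcription-order rank
    comp <- add(comp, "initial_exon", ch, d$start[1], d$end[1], maxlen)
    if (k >= 2)
      comp <- add(comp, "terminal_exon", ch, d$start[k], d$end[k], maxlen)
    if (k >= 3)
      for (i in 2:(k - 1))
        comp <- add(comp, "internal_exons", ch, d$start[i], d$end[i], maxlen)
    # introns between consecutive ranked exons
    if (k >= 2) {
      dg <- d[order(d$start), , drop = FALSE]
      istart <- dg$end[-k]; iend <- dg$start[-1]
      # intron rank in transcription order
      irank <- if (plus) seq_len(k - 1) else rev(seq_len(k - 1))
      for (i in seq_len(k - 1)) {
        nm <- if (irank[i] == 1) "initial_intron" else "internal_introns"
        comp <- add(comp, nm, ch, istart[i], iend[i], maxlen)
      }
    }
  }
  lapply(comp, function(lst) {
    if (length(lst) == 0)
      return(data.frame(chrom = character(), start = numeric(),
                        end = numeric()))
    df <- do.call(rbind, lst)
    gr <- GenomicRanges::reduce(.intervals_to_gr(df))
    .as_interval_df(gr)
  })
}

#' Log2 overlap enrichment
#'
#' `log2((n_overlap + 1) / (n_l * n_c / n + 1))`: the observed overlap of a
#' state with a component, relative to the overlap expected if both were
#' distributed independently over a genome of `n` bases, with a pseudocount
#' of one base on each side.
#'
#' @param n_overlap bases covered by both state and component.
#' @param n_l bases covered by the state.
#' @param n_c bases covered by the component.
#' @param n total genome size in bases.
#' @return numeric enrichment (0 when observed equals expected).
#' @export
overlap_enrichment <- function(n_overlap, n_l, n_c, n) {
  stopifnot(n > 0, n_overlap >= 0, n_l >= 0, n_c >= 0,
            all(n_overlap <= pmin(n_l, n_c) + 1e-9))
  log2((n_overlap + 1) / (n_l * n_c / n + 1))
}

#' Mean signal of a track over a state
#'
#' Base-weighted mean of unmasked track values over the bins labeled with
#' the state.
#'
#' @param ann an `Annotation`.
#' @param state integer state label.
#' @param track a `BinnedTrack` with `bin_size` equal to the annotation
#'   resolution.
#' @return numeric mean.
#' @export
state_mean_signal <- function(ann, state, track) {
  stopifnot(inherits(ann, "Annotation"), inherits(track, "BinnedTrack"))
  if (track$bin_size != ann$resolution)
    stop("track bin size must equal the annotation resolution")
  iv <- state_intervals(ann, state)
  if (nrow(iv) == 0) stop("state ", state, " absent from annotation")
  v <- track_values_over(track, iv)
  if (length(v) == 0) stop("state ", state, " fully masked in track")
  mean(v)
}

# per-bin base coverage of an interval set (bases of the set inside each
# bin), for fast state-by-component overlap counting
.component_bin_cover <- function(df, nbins_by_chrom, bin_size) {
  cov <- lapply(nbins_by_chrom, numeric)
  for (i in seq_len(nrow(df))) {
    ch <- df$chrom[i]
    n <- nbins_by_chrom[[ch]]
    if (is.null(n)) next
    s <- df$start[i]; e <- min(df$end[i], n * bin_size)
    if (e <= s) next
    b <- (floor(s / bin_size)):(ceiling(e / bin_size) - 1)
    lo <- pmax(b * bin_size, s); hi <- pmin((b + 1) * bin_size, e)
    cov[[ch]][b + 1] <- cov[[ch]][b + 1] + (hi - lo)
  }
  cov
}

#' Build the state x feature matrix for one annotation
#'
#' One row per state present in the annotation; columns are the mean
#' normalized signal of each canonical mark followed by the nine
#' gene-component enrichments. Marks missing from the catalog for this cell
#' type are computed on the track substituted from the most-similar cell
#' type and flagged.
#'
#' @param ann an `Annotation`.
#' @param catalog a `TrackCatalog` of normalized tracks.
#' @param components output of [derive_gene_components()].
#' @param layout a `GenomeLayout`.
#' @param marks assay names used as signal-mean features.
#' @param min_shared_bins passed to [select_substitute()].
#' @return numeric matrix `states x features` with rownames
#'   `cell_type.stateN`; attributes `substituted` (named logical per mark)
#'   and `donors` (named character) record provenance.
#' @export
build_feature_matrix <- function(ann, catalog, components, layout,
                                 marks = canonical_marks(),
                                 min_shared_bins = 1000) {
  stopifnot(inherits(ann, "Annotation"), inherits(catalog, "TrackCatalog"))
  ct <- ann$cell_type
  tracks <- list()
  substituted <- stats::setNames(rep(FALSE, length(marks)), marks)
  donors <- stats::setNames(rep(NA_character_, length(marks)), marks)
  for (m in marks) {
    tr <- catalog_get(catalog, ct, m)
    if (is.null(tr)) {
      sub <- select_substitute(catalog, ct, m, min_shared_bins)
      tr <- sub$track
      substituted[m] <- TRUE
      donors[m] <- sub$donor
    }
    tracks[[m]] <- tr
  }
  states <- sort(unique(ann$segments$state))
  n <- genome_size(layout)
  comp_bases <- vapply(components, covered_bases, 1.0)
  res <- ann$resolution
  feat <- matrix(NA_real_, nrow = length(states),
                 ncol = length(marks) + length(components),
                 dimnames = list(paste0(ct, ".state", states),
                                 c(paste0("mean_", marks),
                                   paste0("enr_", names(components)))))
  # per-chromosome label vectors over the annotated territory
  chroms <- unique(ann$segments$chrom)
  nbins <- stats::setNames(lapply(chroms, function(ch)
    max(ann$segments$end[ann$segments$chrom == ch]) / res), chroms)
  labs <- stats::setNames(lapply(chroms, function(ch)
    bin_labels(ann, ch, 0, nbins[[ch]] * res)), chroms)
  lab_all <- unlist(labs, use.names = FALSE)
  sidx <- match(lab_all, states)
  # signal means: base-weighted mean of unmasked bins per state
  for (m in marks) {
    v <- unlist(tracks[[m]]$values[chroms], use.names = FALSE)
    if (tracks[[m]]$bin_size != res)
      stop("track bin size must equal the annotation resolution")
    ok <- !is.na(v)
    sums <- rowsum(v[ok], sidx[ok])
    cnts <- rowsum(rep(1, sum(ok)), sidx[ok])
    if (nrow(sums) < length(states))
      stop("a state is fully masked in track ", m)
    feat[as.integer(rownames(sums)), paste0("mean_", m)] <-
      sums[, 1] / cnts[, 1]
  }
  # gene-component enrichments via per-bin component coverage
  n_l <- rowsum(rep(res, length(sidx)), sidx)[, 1]
  for (cn in names(components)) {
    cov <- .component_bin_cover(components[[cn]], nbins, res)
    cv <- unlist(cov[chroms], use.names = FALSE)
    novl <- numeric(length(states))
    nz <- cv > 0
    if (any(nz)) {
      tab <- rowsum(cv[nz], sidx[nz])
      novl[as.integer(rownames(tab))] <- tab[, 1]
    }
    feat[, paste0("enr_", cn)] <-
      overlap_enrichment(novl, n_l, comp_bases[[cn]], n)
  }
  if (any(!is.finite(feat))) stop("non-finite feature values")
  attr(feat, "substituted") <- substituted
  attr(feat, "donors") <- donors
  feat
}

#' Write a feature matrix as TSV
#'
#' Rows are `cell_type.stateN`; columns are named features plus one
#' `sub_<mark>` flag column per substituted-capable mark.
#'
#' @param feat matrix from [build_feature_matrix()] (or several stacked with
#'   `rbind`).
#' @param path output path.
#' @export
write_feature_tsv <- function(feat, path) {
  df <- data.frame(state = rownames(feat), as.data.frame(feat),
                   check.names = FALSE)
  sub <- attr(feat, "substituted")
  if (!is.null(sub))
    for (m in names(sub)) df[[paste0("sub_", m)]] <- as.integer(sub[[m]])
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a feature matrix from TSV
#' @param path TSV written by [write_feature_tsv()].
#' @return numeric matrix with state rownames (flag columns dropped).
#' @export
read_feature_tsv <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = TRUE,
                          check.names = FALSE, stringsAsFactors = FALSE)
  rn <- df$state
  df <- df[, setdiff(names(df), c("state", grep("^sub_", names(df),
                                                value = TRUE))), drop = FALSE]
  m <- as.matrix(df)
  rownames(m) <- rn
  m
}
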