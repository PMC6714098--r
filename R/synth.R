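# Synthetic-data generators.
#
# Architecture: a latent genome-level element map fixes where each kind of
# activity lives (promoters at and beyond TSSs, enhancers, repressed
# domains, ...); conservation is a property of the genome, drawn per bin
# from the latent term's distribution; each simulated cell type activates
# each element independently (constitutive heterochromatin always, genic
# elements via one per-gene activity draw), so regulatory positions are
# shared across cell types while activity is cell type-specific — the
# structure the cross-cell-type score aggregation assumes. Everything is
# reproducible from (config, seed).

#' Marks simulated by the generator
#' @return character vector of assay names.
#' @export
synth_marks <- function() {
  c("H3K4me3", "H3K27me3", "H3K36me3", "H3K4me1", "H3K9me3", "H3K9ac",
    "H3K27ac")
}

#' Default per-term signature table
#'
#' One row per interpretation term: target per-cell-type genome fraction,
#' mean element length (bp), the planted 75th percentile of absolute
#' conservation, and the mean raw signal level of each simulated mark
#' (characteristic activities: Promoter = H3K4me3/H3K9ac, Enhancer =
#' H3K4me1/H3K27ac, Transcribed = H3K36me3, FacultativeHet = H3K27me3,
#' ConstitutiveHet = H3K9me3, Bivalent = H3K4me3 + H3K27me3, RegPermissive
#' = H3K4me1 only, Quiescent = none). The `Unclassified` row carries an
#' artifact-like uniform elevation over all marks and a zero default
#' fraction; reference-corpus generation raises it.
#'
#' @return data frame with columns `term`, `fraction`, `mean_len_bp`,
#'   `cons_q75`, and one column per mark.
#' @export
default_signature_table <- function() {
  tab <- data.frame(
    term = c("Quiescent", "ConstitutiveHet", "FacultativeHet", "Transcribed",
             "Promoter", "Enhancer", "RegPermissive", "Bivalent",
             "Unclassified"),
    fraction = c(0.60, 0.10, 0.15, 0.07, 0.02, 0.02, 0.03, 0.01, 0),
    mean_len_bp = c(5000, 5000, 4000, 3000, 800, 600, 600, 600, 1000),
    cons_q75 = c(0.37, 0.40, 0.45, 0.70, 1.20, 1.00, 0.60, 1.10, 0.50),
    stringsAsFactors = FALSE)
  sig <- rbind(
    Quiescent       = c(0.0, 0.0, 0.0, 0.0, 0.0, 0.0, 0.0),
    ConstitutiveHet = c(0.0, 0.0, 0.0, 0.0, 4.0, 0.0, 0.0),
    FacultativeHet  = c(0.0, 4.0, 0.0, 0.0, 0.0, 0.0, 0.0),
    Transcribed     = c(0.0, 0.0, 4.0, 0.0, 0.0, 0.0, 0.0),
    Promoter        = c(4.0, 0.0, 0.0, 0.5, 0.0, 3.0, 1.0),
    Enhancer        = c(0.5, 0.0, 0.0, 4.0, 0.0, 0.5, 4.0),
    RegPermissive   = c(0.0, 0.0, 0.0, 2.0, 0.0, 0.0, 0.0),
    Bivalent        = c(3.0, 3.0, 0.0, 0.5, 0.0, 0.5, 0.5),
    Unclassified    = c(1.5, 1.5, 1.5, 1.5, 1.5, 1.5, 1.5))
  colnames(sig) <- synth_marks()
  cbind(tab, as.data.frame(sig[tab$term, , drop = FALSE],
                           row.names = seq_len(nrow(tab))))
}

#' Default per-term element activity probabilities
#'
#' Probability that a latent element is active (carries its own term rather
#' than appearing quiescent) in any one cell type. Constitutive
#' heterochromatin is always active; genic promoter/body elements follow
#' the per-gene activity draw instead.
#'
#' @return named numeric vector.
#' @export
default_activity_probs <- function() {
  c(ConstitutiveHet = 1.0, FacultativeHet = 0.5, Transcribed = 0.6,
    Promoter = 0.6, Enhancer = 0.5, RegPermissive = 0.5, Bivalent = 0.5,
    Unclassified = 0.7)
}

#' Default toy genome layout
#' @return a `GenomeLayout` of two 1-Mbp chromosomes.
#' @export
default_genome_layout <- function() {
  genome_layout(c("chrS1", "chrS2"), c(1e6, 1e6))
}

#' Simulate gene models on a layout
#'
#' Genes of 2-6 kbp with 1-5 exons, random strand, spaced so that every
#' promoter window (+-10 kbp) stays inside its chromosome.
#'
#' @param layout a `GenomeLayout`.
#' @param n_genes total gene count (allocated to chromosomes by length).
#' @param seed RNG seed.
#' @return a `GeneModels`.
#' @export
simulate_genes <- function(layout, n_genes = 60, seed = 1) {
  set.seed(seed)
  margin <- 12000
  rows <- list(); gi <- 0
  alloc <- round(n_genes * layout$lengths / genome_size(layout))
  for (ch in layout$chroms) {
    n_c <- alloc[[ch]]
    if (n_c < 1) next
    usable <- layout$lengths[[ch]] - 2 * margin
    slot <- usable / n_c
    if (slot < 8000) stop("too many genes for layout")
    for (k in seq_len(n_c)) {
      gi <- gi + 1
      glen <- sample(seq(2000, 6000, by = 100), 1)
      gstart <- round(margin + (k - 1) * slot +
                        runif(1, 0, max(1, slot - glen - 2000)))
      nex <- sample(1:5, 1)
      parts <- 2 * nex - 1
      repeat {
        w <- runif(parts)
        lens <- floor(w / sum(w) * glen)
        lens[parts] <- glen - sum(lens[-parts])
        if (all(lens >= 50)) break
      }
      bounds <- gstart + cumsum(c(0, lens))
      ex_idx <- seq(1, parts, by = 2)
      rows[[gi]] <- data.frame(
        gene_id = sprintf("gene%03d", gi), chrom = ch,
        strand = sample(c("+", "-"), 1),
        start = bounds[ex_idx], end = bounds[ex_idx + 1],
        stringsAsFactors = FALSE)
    }
  }
  gene_models(do.call(rbind, rows))
}

# chop a bin budget into geometric-length pieces summing exactly to it
.chop_budget <- function(target_bins, mean_len_bins) {
  if (target_bins <= 0) return(integer(0))
  lens <- integer(0); tot <- 0
  p <- 1 / max(1, mean_len_bins)
  while (tot < target_bins) {
    l <- 1 + stats::rgeom(1, p)
    if (tot + l > target_bins) l <- target_bins - tot
    lens <- c(lens, l); tot <- tot + l
  }
  lens
}

#' Simulate the latent element map of a genome
#'
#' Lays down the genome-level architecture every downstream generator
#' shares: gene bodies (Transcribed) and TSS windows (Promoter) are fixed
#' by the gene models; the remaining per-term element budgets — the
#' per-cell-type target fraction divided by the term's activity
#' probability — are chopped into geometric-length elements and interleaved
#' at random over the remaining territory; everything else is latent
#' Quiescent.
#'
#' @param layout a `GenomeLayout`.
#' @param signatures signature table (see [default_signature_table()]).
#' @param genes a `GeneModels`, or `NULL` for a gene-free genome.
#' @param activity per-term activity probabilities (see
#'   [default_activity_probs()]).
#' @param tss_halfwidth half-width of the genic promoter element in bp.
#' @param resolution bin size in bp.
#' @param seed RNG seed.
#' @return an object of class `SyntheticGenome`: `layout`, `genes`,
#'   `signatures`, `activity`, `resolution`, `elements` (data frame:
#'   `chrom`, `start_bin`, `end_bin` 1-based inclusive, `term`, `gene_id`),
#'   `latent` (per-chromosome character vector of latent terms per bin),
#'   `seed`.
#' @export
simulate_genome <- function(layout = default_genome_layout(),
                            signatures = default_signature_table(),
                            genes = NULL,
                            activity = default_activity_probs(),
                            tss_halfwidth = 300, resolution = 100,
                            seed = 1) {
  set.seed(seed)
  res <- resolution
  nb <- stats::setNames(floor(layout$lengths / res), layout$chroms)
  total_bins <- sum(nb)
  # genic elements
  gel <- list()
  if (!is.null(genes)) {
    gt <- gene_table(genes)
    for (g in seq_len(nrow(gt))) {
      ch <- gt$chrom[g]
      pw0 <- max(0, floor((gt$tss[g] - tss_halfwidth) / res))
      pw1 <- min(nb[[ch]] - 1, ceiling((gt$tss[g] + tss_halfwidth) / res) - 1)
      b0 <- max(0, floor(gt$start[g] / res))
      b1 <- min(nb[[ch]] - 1, ceiling(gt$end[g] / res) - 1)
      gel[[length(gel) + 1]] <- data.frame(
        chrom = ch, start_bin = pw0 + 1, end_bin = pw1 + 1,
        term = "Promoter", gene_id = gt$gene_id[g],
        stringsAsFactors = FALSE)
      # body minus promoter window (may split in two)
      left <- c(b0, pw1 + 1); right <- c(pw0 - 1, b1)
      for (k in 1:2) if (left[k] <= right[k])
        gel[[length(gel) + 1]] <- data.frame(
          chrom = ch, start_bin = left[k] + 1, end_bin = right[k] + 1,
          term = "Transcribed", gene_id = gt$gene_id[g],
          stringsAsFactors = FALSE)
    }
  }
  gel <- if (length(gel) > 0) do.call(rbind, gel) else
    data.frame(chrom = character(), start_bin = integer(),
               end_bin = integer(), term = character(),
               gene_id = character())
  # free runs (bins not claimed by genic elements), genomic order
  occ <- lapply(nb, function(k) logical(k))
  for (i in seq_len(nrow(gel)))
    occ[[gel$chrom[i]]][gel$start_bin[i]:gel$end_bin[i]] <- TRUE
  runs <- list()
  for (ch in layout$chroms) {
    r <- rle(occ[[ch]])
    e <- cumsum(r$lengths); s <- c(1, e[-length(e)] + 1)
    free <- which(!r$values)
    if (length(free) > 0)
      runs[[ch]] <- data.frame(chrom = ch, start_bin = s[free],
                               len = r$lengths[free])
  }
  runs <- do.call(rbind, runs)
  # per-term latent budgets over the free territory
  sig <- signatures[signatures$term != "Quiescent" & signatures$fraction > 0,
                    , drop = FALSE]
  genic_bins <- vapply(sig$term, function(tm)
    sum(gel$end_bin[gel$term == tm] - gel$start_bin[gel$term == tm] + 1),
    1.0)
  lat_frac <- sig$fraction / activity[sig$term]
  if (anyNA(lat_frac)) stop("activity probability missing for some term")
  budget <- pmax(0, round(lat_frac * total_bins) - genic_bins)
  free_total <- sum(runs$len)
  if (sum(budget) > 0.9 * free_total)
    stop("latent element budgets exceed available territory")
  piece_term <- character(0); piece_len <- integer(0)
  for (ti in seq_len(nrow(sig))) {
    lens <- .chop_budget(budget[ti], sig$mean_len_bp[ti] / res)
    piece_term <- c(piece_term, rep(sig$term[ti], length(lens)))
    piece_len <- c(piece_len, lens)
  }
  # quiescent spacers fill the remainder
  qlens <- .chop_budget(free_total - sum(piece_len),
                        signatures$mean_len_bp[signatures$term ==
                                                 "Quiescent"] / res)
  piece_term <- c(piece_term, rep("Quiescent", length(qlens)))
  piece_len <- c(piece_len, qlens)
  ord <- sample(length(piece_len))
  piece_term <- piece_term[ord]; piece_len <- piece_len[ord]
  # lay pieces over the concatenated free space, splitting at run borders
  rel <- list(); ri <- 1; run_used <- 0
  for (k in seq_along(piece_len)) {
    remn <- piece_len[k]
    while (remn > 0) {
      avail <- runs$len[ri] - run_used
      take <- min(remn, avail)
      rel[[length(rel) + 1]] <- data.frame(
        chrom = runs$chrom[ri], start_bin = runs$start_bin[ri] + run_used,
        end_bin = runs$start_bin[ri] + run_used + take - 1,
        term = piece_term[k], gene_id = NA_character_,
        stringsAsFactors = FALSE)
      run_used <- run_used + take; remn <- remn - take
      if (run_used == runs$len[ri]) { ri <- ri + 1; run_used <- 0 }
    }
  }
  elements <- rbind(gel, do.call(rbind, rel))
  elements <- elements[order(elements$chrom, elements$start_bin), ,
                       drop = FALSE]
  rownames(elements) <- NULL
  elements$element_id <- seq_len(nrow(elements))
  latent <- lapply(nb, function(k) character(k))
  for (i in seq_len(nrow(elements)))
    latent[[elements$chrom[i]]][elements$start_bin[i]:elements$end_bin[i]] <-
      elements$term[i]
  structure(list(layout = layout, genes = genes, signatures = signatures,
                 activity = activity, resolution = res, elements = elements,
                 latent = latent, seed = seed),
            class = "SyntheticGenome")
}

#' @export
print.SyntheticGenome <- function(x, ...) {
  cat("SyntheticGenome:", length(x$latent), "chromosomes,",
      nrow(x$elements), "latent elements, resolution", x$resolution, "bp\n")
  invisible(x)
}

#' Latent element map as an annotation
#'
#' The genome's true element map, one state per latent term — handy as the
#' ground-truth annotation for per-term conservation checks.
#'
#' @param genome a `SyntheticGenome`.
#' @return list with `annotation` (`Annotation`) and `terms` (named vector
#'   state -> term).
#' @export
latent_annotation <- function(genome) {
  terms <- unique(unlist(genome$latent, use.names = FALSE))
  terms <- c(intersect(interpretation_terms(), terms),
             setdiff(terms, interpretation_terms()))
  res <- genome$resolution
  segs <- list()
  for (ch in names(genome$latent)) {
    r <- rle(match(genome$latent[[ch]], terms) - 1L)
    e <- cumsum(r$lengths) * res
    segs[[ch]] <- data.frame(chrom = ch, start = c(0, e[-length(e)]),
                             end = e, state = r$values,
                             stringsAsFactors = FALSE)
  }
  ann <- annotation(do.call(rbind, segs), cell_type = "latent",
                    resolution = res, n_states = length(terms))
  list(annotation = ann,
       terms = stats::setNames(terms, as.character(seq_along(terms) - 1)))
}

#' Simulate one cell type: annotation plus normalized signal tracks
#'
#' Activates each latent element independently (genic elements follow one
#' per-gene Bernoulli draw; constitutive heterochromatin is always active);
#' inactive elements appear quiescent in this cell type. Each term owns one
#' or more states (subtypes); the active state is drawn per element, and
#' quiescent territory is chopped into segments distributed over the
#' quiescent states. Each (state, mark) signal level is the term's
#' signature mean plus a state-level jitter; per-bin values add Gaussian
#' noise, then asinh + Z-score normalization.
#'
#' @param genome a `SyntheticGenome`.
#' @param n_states number of states (>= number of terms present).
#' @param seed RNG seed.
#' @param noise_sd per-bin Gaussian noise sd on the raw signal scale.
#' @param state_jitter_sd sd of the per-(state, mark) offset from the term
#'   signature.
#' @param p_gene_active probability a gene is active in this cell type.
#' @param cell_type identifier (default derived from the seed).
#' @return list with `annotation` (`Annotation`), `tracks` (named list of
#'   normalized `BinnedTrack`s, one per mark), and `truth`
#'   (`SyntheticTruth`: state -> term map, per-state mark means, per-gene
#'   and per-element activity, config, seed).
#' @export
simulate_cell_type <- function(genome, n_states = NULL, seed = 1,
                               noise_sd = 0.5, state_jitter_sd = 0.3,
                               p_gene_active = 0.6, cell_type = NULL) {
  stopifnot(inherits(genome, "SyntheticGenome"))
  set.seed(seed)
  if (is.null(cell_type)) cell_type <- paste0("synth_ct_seed", seed)
  res <- genome$resolution
  el <- genome$elements
  terms_present <- unique(c("Quiescent", el$term))
  terms_present <- c(intersect(interpretation_terms(), terms_present),
                     setdiff(terms_present, interpretation_terms()))
  if (is.null(n_states)) n_states <- num_states_for(length(synth_marks()))
  if (n_states < length(terms_present))
    stop("n_states must be >= number of terms present (",
         length(terms_present), ")")
  # state -> term
  frac <- stats::setNames(genome$signatures$fraction,
                          genome$signatures$term)[terms_present]
  frac[is.na(frac) | frac <= 0] <- 0.01
  extra <- if (n_states > length(terms_present))
    sample(terms_present, n_states - length(terms_present), replace = TRUE,
           prob = frac) else character(0)
  state_term <- c(terms_present, extra)
  names(state_term) <- as.character(seq_along(state_term) - 1)
  states_of_term <- split(as.integer(names(state_term)), state_term)
  # activity
  gene_active <- NULL
  if (!is.null(genome$genes)) {
    gt <- gene_table(genome$genes)
    gene_active <- stats::setNames(stats::runif(nrow(gt)) < p_gene_active,
                                   gt$gene_id)
  }
  p_act <- genome$activity[el$term]
  element_active <- stats::runif(nrow(el)) < p_act
  genic <- !is.na(el$gene_id)
  if (any(genic)) element_active[genic] <- gene_active[el$gene_id[genic]]
  element_active[el$term == "Quiescent"] <- FALSE
  # per-bin state
  state_bins <- lapply(genome$latent, function(v) rep(NA_integer_,
                                                      length(v)))
  for (i in seq_len(nrow(el))) {
    tm <- if (element_active[i]) el$term[i] else "Quiescent"
    if (tm == "Quiescent") next  # filled below
    cand <- states_of_term[[tm]]
    state_bins[[el$chrom[i]]][el$start_bin[i]:el$end_bin[i]] <-
      cand[sample.int(length(cand), 1)]
  }
  qstates <- states_of_term[["Quiescent"]]
  qmean <- genome$signatures$mean_len_bp[
    genome$signatures$term == "Quiescent"] / res
  for (ch in names(state_bins)) {
    miss <- is.na(state_bins[[ch]])
    nmiss <- sum(miss)
    if (nmiss == 0) next
    lens <- .chop_budget(nmiss, qmean)
    st <- rep(qstates[sample.int(length(qstates), length(lens),
                                 replace = TRUE)], times = lens)
    state_bins[[ch]][miss] <- st
  }
  segs <- list()
  for (ch in names(state_bins)) {
    r <- rle(state_bins[[ch]])
    e <- cumsum(r$lengths) * res
    segs[[ch]] <- data.frame(chrom = ch, start = c(0, e[-length(e)]),
                             end = e, state = r$values,
                             stringsAsFactors = FALSE)
  }
  ann <- annotation(do.call(rbind, segs), cell_type = cell_type,
                    resolution = res, n_states = n_states)
  # tracks
  marks <- synth_marks()
  sigmat <- as.matrix(
    genome$signatures[match(state_term, genome$signatures$term), marks])
  state_mark_mean <- sigmat +
    matrix(stats::rnorm(length(state_term) * length(marks),
                        sd = state_jitter_sd), nrow = length(state_term))
  dimnames(state_mark_mean) <- list(names(state_term), marks)
  tracks <- list()
  for (m in marks) {
    vals <- lapply(names(state_bins), function(ch) {
      sb <- state_bins[[ch]]
      state_mark_mean[sb + 1, m] + stats::rnorm(length(sb), sd = noise_sd)
    })
    names(vals) <- names(state_bins)
    tracks[[m]] <- zscore_normalize(asinh_transform(
      binned_track(vals, res)))
  }
  truth <- structure(
    list(state_term = state_term, state_mark_mean = state_mark_mean,
         gene_active = gene_active, element_active = element_active,
         config = list(noise_sd = noise_sd,
                       state_jitter_sd = state_jitter_sd,
                       p_gene_active = p_gene_active, n_states = n_states),
         seed = seed),
    class = "SyntheticTruth")
  list(annotation = ann, tracks = tracks, truth = truth)
}

#' Simulate a conservation (phyloP-like) track
#'
#' One signed value per bin: the magnitude is drawn uniformly over the
#' latent term's band `[0.4 q, 1.2 q]`, whose 75th percentile is exactly
#' the term's planted `cons_q75 = q`; the sign is random. The generator
#' works at bin resolution (the bin is the aggregate unit of every
#' downstream statistic), so the planted quantile is directly recoverable
#' by [compute_state_caas()].
#'
#' @param genome a `SyntheticGenome`.
#' @param seed RNG seed.
#' @return a `BinnedTrack` of signed conservation values.
#' @export
simulate_conservation <- function(genome, seed = 1) {
  stopifnot(inherits(genome, "SyntheticGenome"))
  set.seed(seed)
  q75 <- stats::setNames(genome$signatures$cons_q75, genome$signatures$term)
  vals <- lapply(genome$latent, function(tm) {
    q <- unname(q75[tm])
    q * stats::runif(length(tm), 0.4, 1.2) *
      sample(c(-1, 1), length(tm), replace = TRUE)
  })
  binned_track(vals, genome$resolution)
}

#' Simulate an expression matrix coupled to promoter activity
#'
#' On the log scale, the expression of gene `g` in cell type `c` is
#' `alpha * active(g, c) + N(0, sigma)`, where `active` is the per-gene
#' activity drawn by [simulate_cell_type()] (an active gene carries a
#' Promoter-term state at its TSS). The returned matrix is inverse-
#' transformed (`exp(x) - 1`, floored at 0), matching the `log(x + 1)`
#' transform applied by the evaluation.
#'
#' @param truths named list of `SyntheticTruth` objects (name = cell type)
#'   from a genome with genes.
#' @param genes the genome's `GeneModels`.
#' @param alpha effect size of promoter activity on log expression.
#' @param sigma log-scale noise sd.
#' @param seed RNG seed.
#' @return numeric matrix genes x cell types.
#' @export
simulate_expression <- function(truths, genes, alpha = 1.5, sigma = 0.5,
                                seed = 1) {
  set.seed(seed)
  gt <- gene_table(genes)
  out <- matrix(NA_real_, nrow = nrow(gt), ncol = length(truths),
                dimnames = list(gt$gene_id, names(truths)))
  for (ct in names(truths)) {
    act <- truths[[ct]]$gene_active
    if (is.null(act))
      stop("truth for ", ct, " lacks gene activity (genome without genes)")
    y <- alpha * as.numeric(act[gt$gene_id]) +
      stats::rnorm(nrow(gt), sd = sigma)
    out[, ct] <- pmax(exp(y) - 1, 0)
  }
  out
}

#' Simulate a reference corpus of interpreted states
#'
#' Emulates a collection of manually interpreted reference annotations on a
#' shared genome: a share of latent elements carries an artifact-like
#' `Unclassified` signature, `n_annotations` synthetic cell types are
#' generated, and the feature matrix of every annotation is built with the
#' production feature extractor on the annotation's own synthetic tracks.
#' Curated terms are the generative truth.
#'
#' @param layout a `GenomeLayout`.
#' @param n_annotations number of reference annotations.
#' @param states_range inclusive range the per-annotation state count is
#'   drawn from.
#' @param signatures signature table; its `Unclassified` fraction is raised
#'   to `unclassified_fraction` (carved from Quiescent) so the placeholder
#'   class is populated.
#' @param unclassified_fraction per-cell-type genome share of
#'   artifact-like states.
#' @param n_genes gene count for the shared genome.
#' @param noise_sd,state_jitter_sd passed to [simulate_cell_type()].
#' @param seed RNG seed.
#' @return list with `features` (stacked matrix), `terms` (curated term per
#'   row), `groups` (source annotation per row), `genome`, and
#'   `annotations` (the per-cell-type simulation results).
#' @export
simulate_reference_corpus <- function(layout = default_genome_layout(),
                                      n_annotations = 14,
                                      states_range = c(19, 23),
                                      signatures = default_signature_table(),
                                      unclassified_fraction = 0.03,
                                      n_genes = 60, noise_sd = 0.5,
                                      state_jitter_sd = 0.3, seed = 1) {
  set.seed(seed)
  sig <- signatures
  iq <- which(sig$term == "Quiescent")
  iu <- which(sig$term == "Unclassified")
  sig$fraction[iu] <- unclassified_fraction
  sig$fraction[iq] <- sig$fraction[iq] - unclassified_fraction
  seeds <- sample.int(1e6, n_annotations + 1)
  genes <- simulate_genes(layout, n_genes = n_genes, seed = seeds[1])
  genome <- simulate_genome(layout, sig, genes = genes, seed = seeds[1])
  components <- derive_gene_components(genes, layout)
  feats <- list(); terms <- list(); groups <- list(); anns <- list()
  for (i in seq_len(n_annotations)) {
    ns <- sample(seq(states_range[1], states_range[2]), 1)
    sim <- simulate_cell_type(genome, n_states = ns, seed = seeds[i + 1],
                              noise_sd = noise_sd,
                              state_jitter_sd = state_jitter_sd,
                              cell_type = sprintf("ref%02d", i))
    cat <- track_catalog()
    for (m in canonical_marks())
      cat <- catalog_add(cat, sim$annotation$cell_type, m, sim$tracks[[m]])
    fm <- build_feature_matrix(sim$annotation, cat, components, layout)
    st <- sort(unique(sim$annotation$segments$state))
    feats[[i]] <- fm
    terms[[i]] <- unname(sim$truth$state_term[as.character(st)])
    groups[[i]] <- rep(sprintf("ref%02d", i), length(st))
    anns[[i]] <- sim
  }
  list(features = do.call(rbind, feats), terms = unlist(terms),
       groups = unlist(groups), genome = genome, annotations = anns)
}

#' Simulate SNP positions with score-dependent enrichment
#'
#' Bins are sampled with probability proportional to
#' `exp(enrichment * z(score))` (z = genome-wide standardization of the
#' total position score); `enrichment = 0` gives uniform positions. One
#' uniform base offset is drawn within each sampled bin.
#'
#' @param scores a `PositionScoreTrack`.
#' @param enrichment log-linear enrichment coefficient.
#' @param n_snps number of SNPs.
#' @param seed RNG seed.
#' @return data frame with columns `chrom`, `pos` (0-based).
#' @export
simulate_snps <- function(scores, enrichment = 0, n_snps = 1000, seed = 1) {
  set.seed(seed)
  bs <- scores$bin_size
  chroms <- names(scores$total)
  nb <- vapply(scores$total, length, 1L)
  all_scores <- unlist(scores$total, use.names = FALSE)
  z <- (all_scores - mean(all_scores)) /
    max(stats::sd(all_scores), .Machine$double.eps)
  w <- exp(enrichment * z)
  idx <- sample.int(length(w), n_snps, replace = TRUE, prob = w / sum(w))
  cum <- cumsum(nb)
  ci <- rep(seq_along(chroms), times = nb)[idx]
  bin <- idx - c(0, cum[-length(cum)])[ci]
  data.frame(chrom = chroms[ci],
             pos = (bin - 1) * bs + sample.int(bs, n_snps, replace = TRUE) - 1,
             stringsAsFactors = FALSE)
}
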