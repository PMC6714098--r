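# Shared fixtures, built once per test run and cached.

.fix <- new.env(parent = emptyenv())

fix_layout <- function() {
  if (is.null(.fix$layout)) .fix$layout <- default_genome_layout()
  .fix$layout
}

fix_genes <- function() {
  if (is.null(.fix$genes))
    .fix$genes <- simulate_genes(fix_layout(), n_genes = 60, seed = 101)
  .fix$genes
}

fix_genome <- function() {
  if (is.null(.fix$genome))
    .fix$genome <- simulate_genome(fix_layout(), genes = fix_genes(),
                                   seed = 101)
  .fix$genome
}

fix_conservation <- function() {
  if (is.null(.fix$cons))
    .fix$cons <- simulate_conservation(fix_genome(), seed = 102)
  .fix$cons
}

# three simulated cell types on the shared genome
fix_cells <- function() {
  if (is.null(.fix$cells))
    .fix$cells <- lapply(1:3, function(i)
      simulate_cell_type(fix_genome(), seed = 200 + i,
                         cell_type = paste0("ct", i)))
  .fix$cells
}

fix_scores <- function() {
  if (is.null(.fix$scores)) {
    cells <- fix_cells()
    anns <- lapply(cells, `[[`, "annotation")
    caas <- lapply(anns, compute_state_caas, phylop = fix_conservation())
    terms <- lapply(cells, function(s) s$truth$state_term)
    .fix$caas <- caas
    .fix$scores <- compute_position_scores(anns, caas, terms)
  }
  .fix$scores
}

fix_caas <- function() {
  fix_scores()
  .fix$caas
}

# a small interpreted reference corpus (shared by interpreter tests and the
# classifier-recovery acceptance check)
fix_corpus <- function() {
  if (is.null(.fix$corpus))
    .fix$corpus <- simulate_reference_corpus(fix_layout(), seed = 42)
  .fix$corpus
}

# tiny hand-built annotation: two chromosomes, 4 states, 100-bp bins
toy_annotation <- function() {
  seg <- data.frame(
    chrom = c("c1", "c1", "c1", "c2", "c2"),
    start = c(0, 200, 300, 0, 400),
    end = c(200, 300, 600, 400, 800),
    state = c(3L, 1L, 0L, 2L, 3L))
  annotation(seg, cell_type = "toy", resolution = 100, n_states = 4)
}

toy_layout <- function() genome_layout(c("c1", "c2"), c(600, 800))

# a track with the given per-bin values on the toy layout
toy_track <- function(c1, c2, bin_size = 100) {
  binned_track(list(c1 = c1, c2 = c2), bin_size)
}

# synthetic position-score track wrapper for a single raw score vector
score_track_from <- function(f, bin_size = 100, n_annotations = 1) {
  structure(list(
    bin_size = bin_size, total = list(chrT = f),
    by_term = list(chrT = matrix(f, ncol = 1,
                                 dimnames = list(NULL, "All"))),
    terms = "All", n_annotations = n_annotations),
    class = "PositionScoreTrack")
}

# random bursty score tracks for oracle-equivalence tests: mostly
# sub-baseline background with occasional high-scoring runs
random_score_track <- function(n, Z = 0.775) {
  f <- pmax(stats::rnorm(n, 0.45, 0.15), 0)
  k <- stats::rpois(1, n / 40)
  if (k > 0) for (j in seq_len(k)) {
    w <- sample(3:15, 1)
    at <- sample(n - w, 1)
    f[at:(at + w)] <- f[at:(at + w)] + stats::runif(1, 0.2, 0.8)
  }
  f
}
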