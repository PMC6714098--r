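# stateatlas

Semi-automated genome annotation (SAGA) methods such as Segway and ChromHMM
partition a genome into segments carrying integer state labels, one
annotation per cell type, from histone-mark ChIP-seq, accessibility, and
related signal tracks. The labels themselves are anonymous: a human
normally inspects each state's signal pattern and assigns it a biological
*interpretation term* ("Promoter", "Transcribed", ...). That manual step is
the bottleneck when annotating a hundred or more cell types.

**stateatlas** implements the downstream, fully automated half of such a
workflow:

- **State features** — for each integer state, the mean normalized signal
  of the canonical histone marks plus its log2 enrichment in nine gene
  components (5′/3′ near and far flanks, initial/internal/terminal exons,
  initial/internal introns), with enrichment of state *l* in component *c*
  defined as

  ```
  log2( (n_overlap + 1) / (n_l · n_c / n + 1) )
  ```

  where `n_l`, `n_c` count the bases covered by state and component and
  `n` is the genome size. Missing marks are substituted from the most
  similar cell type (mean Pearson correlation over shared assay types).
- **State interpretation** — a random-forest classifier (500 trees, at
  least 10 training examples per leaf) maps each state's feature vector
  into a unified vocabulary of eight terms (Quiescent, ConstitutiveHet,
  FacultativeHet, Transcribed, Promoter, Enhancer, RegPermissive,
  Bivalent) plus the placeholders *Unclassified* (reference states that fit
  no term) and *LowConfidence* (new states whose top class is Unclassified
  or has probability ≤ 0.25). Leave-one-out evaluation and a synonym table
  for curating raw interpretation strings are included.
- **Conservation-associated activity score (CAAS)** — per state, the 75th
  percentile of absolute phyloP conservation over the bases the state
  covers; per genomic position, the sum of the CAAS of every covering
  state across cell types, with a per-term decomposition. The score
  separates activity that tends to be conserved (promoters, enhancers)
  from non-functional biochemical signal, while remaining attributable to
  a specific activity in specific cell types.
- **Encyclopedia** — maximal contiguous segments of high
  baseline-subtracted score: `s([i,j]) = Σ_k bin_size·(f_k − Z) > S`, no
  strict super-interval scoring higher, mean ≥ M per bp, length ≥ L, and
  no internal valley of depth ≥ D. The shipped preset `"paper-2019"`
  (Z = 0.775, D = 1, S = 5, M = 0.02, L = 500 bp) operates on the
  per-annotation mean score. An exhaustive brute-force oracle
  (`brute_force_segments`) verifies the production extractor exactly.
- **Evaluation** — meta-gene (idealized gene) term-enrichment profiles,
  term-by-term annotation overlap matrices, expression predictiveness by
  L2-regularized regression on one-hot state features at 38 promoter-window
  positions, and SNP enrichment curves over score-ranked genome fractions.
- **Synthetic data** — a generator that lays down a latent genome-level
  element map (promoters at TSSs, enhancers, repressed domains, ...),
  draws conservation from each element's term, and activates elements
  cell-type-specifically, so every stage of the pipeline is testable
  end-to-end with no downloads.
- **Visualization** — conservation-associated activity plots: stacked
  per-term score areas with encyclopedia segment bars, a |phyloP| lane,
  and gene pictograms.

## Worked example

```r
library(stateatlas)

# a toy genome with shared regulatory architecture, three cell types
layout <- default_genome_layout()
genes  <- simulate_genes(layout, n_genes = 60, seed = 1)
genome <- simulate_genome(layout, genes = genes, seed = 1)
phylop <- simulate_conservation(genome, seed = 2)
cells  <- lapply(1:3, function(i)
  simulate_cell_type(genome, seed = 10 + i, cell_type = paste0("ct", i)))

# per-state conservation-associated activity scores
ann1  <- cells[[1]]$annotation
caas1 <- compute_state_caas(ann1, phylop)
head(caas1, 4)
#>   cell_type state      caas  bases
#> 1       ct1     0 0.4285688 249700
#> 2       ct1     1 0.4016761 200000
#> 3       ct1     2 0.4527628 258400
#> 4       ct1     3 0.7013482 186400
```

Each row is one annotation state: `caas` is the 75th percentile of
|phyloP| over the `bases` it covers — quiescent/repressed states sit near
0.4, transcribed regions near 0.7, regulatory states above 1.

```r
# train the interpretation classifier on a synthetic reference corpus,
# then classify cell type 1's states from its own tracks
corpus <- simulate_reference_corpus(layout, seed = 3)
model  <- train_interpreter(corpus$features, corpus$terms, seed = 1)
cat1   <- track_catalog()
for (m in canonical_marks())
  cat1 <- catalog_add(cat1, "ct1", m, cells[[1]]$tracks[[m]])
comps <- derive_gene_components(genes, layout)
fm    <- build_feature_matrix(ann1, cat1, comps, layout)
pred  <- predict_terms(model, fm)
head(pred[, 1:3], 5)
#>                 state            term confidence
#> ct1.state0 ct1.state0       Quiescent      1.000
#> ct1.state1 ct1.state1 ConstitutiveHet      0.922
#> ct1.state2 ct1.state2  FacultativeHet      0.984
#> ct1.state3 ct1.state3     Transcribed      1.000
#> ct1.state4 ct1.state4        Promoter      0.854

mean(pred$term == unname(cells[[1]]$truth$state_term[
  sub(".*state", "", pred$state)]))
#> [1] 0.9333333    # 14 of 15 states match the generative truth
```

```r
# aggregate the score across cell types and extract the encyclopedia
anns   <- lapply(cells, `[[`, "annotation")
caasl  <- lapply(anns, compute_state_caas, phylop = phylop)
termsl <- lapply(cells, function(x) x$truth$state_term)
scores <- compute_position_scores(anns, caasl, termsl)
enc    <- extract_encyclopedia_segments(scores, preset_params())
nrow(enc)
#> [1] 102
sum(enc$length_bp) / genome_size(layout)
#> [1] 0.04485     # the encyclopedia covers ~4.5% of the toy genome
head(enc[, c("chrom", "start", "end", "score", "dominant_term")], 4)
#>   chrom start   end     score dominant_term
#> 1 chrS1     0  1100 109.76389      Bivalent
#> 2 chrS1 11000 11800 129.03757      Promoter
#> 3 chrS1 13200 14900 104.93719      Enhancer
#> 4 chrS1 39000 39500  15.01111      Enhancer
```

`build_caa_plot(scores, "chrS1", 100000, 160000, segments = enc,
genes = genes, phylop = phylop)` renders the corresponding
conservation-associated activity plot.

## Command line

A thin wrapper over the same functions ships at
`inst/cli/stateatlas-cli.R`:

```sh
Rscript $(Rscript -e 'cat(system.file("cli/stateatlas-cli.R",
                                      package="stateatlas"))') \
    synth --out-dir fixtures --seed 7
# then: features / train / predict / loo / caas-states / encyclopedia
```

All commands are byte-reproducible given `--seed`.

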