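---
title: "Methods: automated state interpretation and the conservation-associated activity score"
author: "stateatlas"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: automated state interpretation and the conservation-associated activity score}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(stateatlas)
```

# The problem

Semi-automated genome annotation (SAGA) methods label each segment of a
genome with an integer state per cell type, such that positions sharing a
state show similar patterns across the input signal tracks. The states are
anonymous; turning them into biology traditionally requires a human to
assign each state an interpretation term. stateatlas automates everything
downstream of the segmentation: feature extraction per state, supervised
interpretation, conservation-based scoring, and the construction of a cell
type-agnostic encyclopedia of regulatory and transcriptional elements.

All coordinates are 0-based half-open (BED convention); GTF input is
converted at the parser boundary. Annotations live on a fixed resolution
grid (default 100 bp), and all real-valued tracks are carried as binned
vectors with an explicit missing-data mask; masked bins are excluded from
every statistic.

# Signal preparation

Signal tracks are transformed with the inverse hyperbolic sine,
`asinh(x) = ln(x + sqrt(x^2 + 1))`, which compresses large values like a
log transform but is defined at zero, and then Z-score normalized by the
genome-wide mean and standard deviation. We use the population (not
sample) standard deviation; the difference is immaterial at genome scale
but fixing it makes results exactly reproducible. Z-scoring a constant
track is an error rather than a silent zero division.

When a cell type lacks one of the canonical marks, the track is borrowed
from the most similar cell type that has it. Similarity is the mean
Pearson correlation over all assay types present in both cell types,
computed on the normalized tracks over jointly unmasked bins (at least
1000 shared bins required, configurable; this guards degenerate toy
inputs). Ties are broken by lexicographic donor name for reproducibility.
Borrowed tracks are too noisy for position-level claims but preserve the
genome-wide association patterns that state-level features summarize,
which is the only use made of them here.

The number of states for an annotation scales with data availability as
`round(10 + 2 * sqrt(n_tracks))`, rounding half to even; over plausible
track counts (2–121) this spans 13–32 states.

# State features

Each state is summarized by 15 features: the mean normalized value of six
marks — H3K27me3, H3K4me3, H3K36me3, H3K4me1, H3K9me3, and a configurable
sixth slot defaulting to H3K9ac, the second characteristic promoter
mark — plus the log2 enrichment of the state in nine gene components
derived strand-aware from gene models: 1–10 kbp 5′ flank, 1 bp–1 kbp 5′
flank, initial exon, initial intron, internal exons, internal introns,
terminal exon, 1 bp–1 kbp 3′ flank, 1–10 kbp 3′ flank. Enrichment of
state $l$ in component $c$ is

$$\log_2 \frac{n_{\mathrm{overlap}} + 1}{n_l n_c / n + 1}$$

with a pseudocount of one base on both sides, so empty states and empty
components sit at 0 rather than $-\infty$.

Component construction choices where the convention was open: when a gene
has several transcripts the longest is used; single-exon genes contribute
only the initial exon and the flanks; flanking regions may overlap
neighboring genes' components (no de-overlap rule is imposed) and each
component's intervals are merged before counting; flanks are clipped at
chromosome ends.

# The interpretation classifier

A random forest maps the feature vector to one of the curated terms.
Training data are reference states from previously interpreted
annotations, with raw interpretation strings curated into the unified
vocabulary by a shipped synonym table (`unify_vocabulary()`): synonyms for
one activity collapse ("Polycomb repressed region" → FacultativeHet,
"Weak transcription" → Transcribed — strength-annotated variants denote
model artifacts, not biology), and strings that fit no term ("Artifact",
"Insulator", "FAIRE") become *Unclassified*. We deliberately avoid
strength vocabulary such as "weak enhancer"; regions with H3K4me1 but
without H3K27ac are called *RegPermissive*.

Hyperparameters: 500 trees, Gini impurity, and at least 10 training
examples per leaf (the regularization that matters at ~300 training
states); the RNG seed is stored in the model, making training
deterministic. Features are fed unstandardized — forests are
scale-invariant — and standardization (per-feature standard-deviation
units) is applied only in the reporting table `term_feature_table()`.

New states receive the term *LowConfidence* exactly when the classifier's
top class is Unclassified or no class exceeds 25% probability
(`lowconfidence_rule()`); Unclassified itself is reserved for reference
states.

Leave-one-out evaluation leaves out one *state* per fit (a configurable
alternative leaves out one source annotation, a stricter protocol since
states from one annotation share noise). By default predictions are the
raw argmax class, so Unclassified participates as a class and a reference
state predicted Unclassified is counted correct iff its curated term is
Unclassified; a second mode applies the LowConfidence rule before
scoring.

# Conservation-associated activity score

For state $\ell$, the CAAS is the 75th percentile of the absolute phyloP
values over all bases annotated $\ell$. An upper quantile is used because
active regulatory regions are enriched for conservation without every
base being conserved, so an upper quantile is a sharper signal of
regulatory or transcriptional activity than the mean or median. The score
is defined on the original integer states, which isolates it from any
imprecision in the interpretation step. Numerical choices: the percentile
uses linear interpolation between order statistics (type 7, recorded in
the output metadata); conservation is binned to the annotation grid by
averaging base values; a state with zero unmasked coverage is an error
naming the state.

The score of a genomic position is the sum of the CAAS of every covering
state across all provided annotations, with each contribution also routed
into the channel of that state's term — the per-term decomposition sums
to the total at every bin by construction, and removing an annotation can
only lower the total (all scores are non-negative).

# Encyclopedia segments

With per-position score $f_k$ and baseline $Z$, a position scores
$s(k) = f_k - Z$ and an interval scores
$s([i,j]) = \sum_{k=i}^{j} s(k)$, evaluated per base: a bin of width $b$
contributes $b\,(f_{\mathrm{bin}} - Z)$. An encyclopedia segment must
satisfy:

* total score $s([i,j]) > S$;
* maximality: no strict super-interval scores strictly higher;
* mean score per bp at least $M$, length at least $L$;
* no internal valley: no subsegment strictly inside with total $\le -D$
  (the published inequality direction would forbid any well-scoring
  internal subsegment and contradict $S$; that literal behavior remains
  available as `valley_rule = "literal"`).

Overlapping maximal candidates are resolved highest score first, ties by
leftmost start then shortest extent. The preset `"paper-2019"`
($Z = 0.775$, $D = 1$, $S = 5$, $M = 0.02$/bp, $L = 500$ bp) is defined
on the per-annotation *mean* score: $Z$ sits inside the range of
realistic per-state scores, whereas the raw sum over many annotations is
bounded below by (number of annotations) × (minimum state score) and
would exceed any fixed baseline everywhere. `extract_encyclopedia_segments()`
therefore normalizes by the number of contributing annotations by
default (`normalize = "per_annotation"`); the raw-sum behavior is one
argument away.

Two semantic corners deserve note. First, maximality is quantified over
*all* super-intervals, including ones that themselves fail a constraint;
this is what the exhaustive oracle checks and what the fast extractor
reproduces exactly. A consequence is that when crossing a deep valley
between two peaks would *raise* the total score, the merged interval is
the maximal one and is rejected by the valley filter, and the flanking
peaks — being non-maximal — are not reported either. On realistic tracks
this corner is rare: background positions score well below the baseline,
so crossing a valley almost always lowers the total and nearby peaks
remain maximal individually. Second, scores are compared exactly
(including ties), so both implementations must and do share identical
floating-point expressions on the same prefix sums.

The production extractor finds maximal candidates through a prefix-sum
characterization — an interval is maximal iff its left boundary attains
the running minimum and its right boundary the running suffix maximum of
the prefix sums — then applies the remaining filters; the testing oracle
(`brute_force_segments`, capped at 500 bins) enumerates every interval
and checks maximality by dynamic programming over super-intervals. The
oracle-equivalence tests compare the two exactly over random tracks under
the shipped preset and random parameter sets, for both valley rules.

# Evaluation procedures

**Meta-gene profiles.** Genes are length-normalized onto an idealized
axis: an upstream flank sampled at the annotation resolution, a scaled
body, a downstream flank, strand-aware. A cell is the log2 ratio of the
observed term frequency at that position to the term's genome-wide base
frequency; cells with zero observed frequency are floored at a display
cap (default −8), with the raw values preserved when the cap is disabled.

**Overlap matrices.** For two annotations with terms, each cell is
`log2((overlap + 1) / (expected + 1))` with `expected = n_a·n_b/n`,
mirroring the feature-enrichment pseudocount.

**Expression predictiveness.** For each gene, one-hot features encode the
state at 38 positions in a 10-kbp promoter window: 20 positions covering
the 2 kbp centered on the TSS at 100-bp steps (half-open, −1000 to
+900 — the printed total of 38 forces the 20 + 9 + 9 reading; exact
offsets are a convention emitted in the output metadata) plus 9 upstream
and 9 downstream positions at 1-kbp steps over 10–2 kbp. Genes are split
into five quintiles by their variance of `log(x+1)` expression across
cell types; per quintile, an L2-regularized linear regression
($\lambda = 10^3$, penalized-RSS parameterization, solved in closed form
with an unpenalized intercept so the published $\lambda$ keeps its exact
meaning) is fit on a per-quintile 80/20 gene split (fixed seed) and
scored as fraction of variance explained on the held-out genes. Genes
whose window leaves annotated territory are dropped with a warning.
Note $\lambda = 10^3$ presumes thousands of training genes; with few
genes the ridge shrinkage dominates and the attainable $R^2$ drops, which
is why the shipped tests evaluate this on a ~2000-gene synthetic genome.

**SNP enrichment.** Genome bins are ordered by descending score (ties by
genomic order) and the curve reports, for each genome fraction $X$, the
fraction of SNPs whose bin ranks in the top $X$; also reported is the
fraction of the genome scoring strictly below the median SNP score. An
option computes the curve per annotation and averages, for comparing the
aggregate score against single-cell-type orderings.

# The synthetic-data generator

The generator exists so that every stage is testable without downloads,
and its architecture mirrors the assumptions the pipeline makes about
real data:

* **A latent element map is a property of the genome, not of a cell
  type.** `simulate_genome()` fixes where each kind of activity lives:
  gene bodies (Transcribed) and TSS windows (Promoter) come from the gene
  models; the remaining per-term budgets are chopped into
  geometric-length elements and interleaved at random. Latent budgets are
  the per-cell-type target fractions divided by each term's activity
  probability, so realized per-cell-type fractions match their targets
  (defaults follow the prevalences a large annotation compendium shows:
  ~60% Quiescent, 15% FacultativeHet, 10% ConstitutiveHet, 7%
  Transcribed, with regulatory terms at 1–3%).
* **Activity is cell-type-specific.** Each cell type activates each
  element independently (ConstitutiveHet always; genic promoter and body
  elements follow one per-gene Bernoulli draw, coupling annotation,
  expression, and gene models); inactive elements appear quiescent in
  that cell type. Regulatory positions are therefore shared across cell
  types — the structure the cross-cell-type score sum exploits.
* **Conservation follows the latent term.** One signed value per bin: the
  magnitude is uniform over the band $[0.4q, 1.2q]$, whose 75th
  percentile is exactly the term's planted $q$; the sign is random.
  Uniform bands are a stylized choice: they put high density at the
  target quantile, so the planted value is sharply identified by the
  estimator, while magnitudes still vary over a threefold range.
  Conservation is simulated at bin resolution — the bin is the aggregate
  unit of every downstream statistic — because averaging many per-base
  draws into a bin would shrink the distribution and decouple the planted
  quantile from anything recoverable.
* **Marks follow the state's term.** Signature levels per Table-style
  characteristic activities (Promoter = H3K4me3/H3K9ac, Enhancer =
  H3K4me1/H3K27ac, Bivalent = H3K4me3 + H3K27me3, RegPermissive = H3K4me1
  only, ...), with a per-(state, mark) jitter (default sd 0.3) that makes
  same-term subtypes similar but not identical, plus per-bin Gaussian
  noise (default sd 0.5) before asinh + Z-scoring. The *Unclassified*
  class is generated with a uniform moderate elevation across all marks —
  an artifact-like signature, reflecting that real unclassifiable
  reference states ("Artifact", "Insulator", "FAIRE") carry
  characteristic non-random signal rather than pure noise.
* **Reference corpora** stack ~14 annotations (19–23 states each, ~294
  states total) on one shared genome, with features built by the
  production extractor on each annotation's own tracks.
* **SNPs** are drawn with probability proportional to
  `exp(enrichment · z(score))`; enrichment 0 is the uniform null.

What the generator does *not* emulate — and hence what passing tests do
not show about real data: read-level sequencing noise, mappability and
copy-number artifacts, biased gene conversion, correlated assay noise
across marks, unassembled or blacklisted regions (an exclusion mask can
be applied via `mask_track()`), overlapping transcripts, and any
mismatch between the mark vocabulary of the reference corpora and the
new annotations. Classifier recovery on this corpus demonstrates that
the pipeline learns and applies planted signatures through the full
feature path; it does not bound accuracy on real reference annotations,
where term boundaries are genuinely fuzzy.

# Problem sizes used in the shipped checks

The default toy genome is two 1-Mbp chromosomes at 100-bp resolution, on
which the full pipeline runs in seconds. The shipped end-to-end checks
use: 100+ random tracks of 50–200 bins for oracle equivalence; a 14-
annotation corpus (~294 states) for leave-one-out recovery; 3–12 cell
types on the default genome for CAAS, encyclopedia, and SNP analyses
(pooled per-term coverage then far exceeds the 10⁴-base floor at which
quantile recovery is assessed); and a two-chromosome 2×20-Mbp genome
with 2000 genes for expression predictiveness, sized so that the fixed
$\lambda = 10^3$ ridge operates in the regime it was calibrated for.

# Known limitations

* The classifier cannot discover new activity classes; states that fit no
  learned pattern surface only as LowConfidence.
* The CAAS inherits phyloP's blind spots: recently acquired regulatory
  activity is scored by association, not by direct conservation, and no
  statistical correction is applied for mappability or biased gene
  conversion.
* Segment extraction reports one encyclopedia at one parameter setting;
  multi-resolution variants are out of scope.
* The interval layer assumes one assembly throughout; there is no
  liftover.
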