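---
title: "Scoring variant deleteriousness by contrasting proxy-neutral and simulated variants"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Scoring variant deleteriousness by contrasting proxy-neutral and simulated variants}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The model

Most variant classifiers are trained on the small set of variants with
curated clinical labels. `proxyscore` implements the alternative strategy of
combined annotation-dependent depletion: variants that arose on the human
lineage and survived natural selection are treated as *proxy-neutral*
(negative class), and a size-matched set of *proxy-deleterious* variants
(positive class) is simulated from the mutational expectation alone —
context-dependent substitution frequencies, CpG-specific rates, local rate
multipliers and an empirical indel-length distribution, all estimated from
the proxy-neutral set itself. Because simulated de novo variants have never
been filtered by selection, annotations that track functional importance
(conservation, regulatory activity, coding consequence) are systematically
shifted between the two classes, and a logistic regression on those
annotations learns a genome-wide deleteriousness score.

Concretely, for a feature vector $x$ (standardized, median-imputed, with
missingness indicators and feature-by-consequence crossed terms) the model
fits $\Pr(\text{proxy-deleterious} \mid x) = \sigma(\beta_0 + \beta^T x)$
with an L2 penalty. The **raw score** is the linear predictor
$\beta_0 + \beta^T x$: it has only relative meaning, with positive values
leaning proxy-deleterious. To make scores comparable across model versions,
raw scores of *all* possible SNVs of the reference are ranked and each value
is mapped to a **PHRED-scaled score** $-10\log_{10}(r)$, where $r$ is its
relative rank from the top (ties share the rank of their worst member).
A scaled score of 20 therefore always marks the top 1% of reference SNVs
and 30 the top 0.1%, regardless of the annotation set or tuning.

## Pipeline

```{r}
library(proxyscore)
library(dplyr)

fx <- make_fixtures(fixture_config(), seed = 7)

mm  <- estimate_mutation_model(fx$neutral, fx$reference)
del <- simulate_variants(fx$reference, mm,
                         n_snv = sum(fx$neutral$vclass == "SNV"),
                         n_indel = sum(fx$neutral$vclass != "SNV"), seed = 1)

train_set <- bind_rows(fx$neutral, del)
y <- rep(0:1, c(nrow(fx$neutral), nrow(del)))

fm <- train_set |>
  annotate_consequence(fx$genes, fx$reference) |>
  build_features(tracks = list(cons = fx$conservation, act = fx$activity))
model <- train_deleteriousness(fm, y)

all_snvs <- enumerate_snvs(fx$reference) |>
  annotate_consequence(fx$genes, fx$reference) |>
  build_features(tracks = list(cons = fx$conservation, act = fx$activity),
                 template = model)
conv <- build_conversion_table(raw_score(model, all_snvs))

scored <- score_variants(fm, model, conv)
```

## Tunable parameters

* **Trinucleotide contexts, CpG override.** Substitution rates are keyed by
  the strand-collapsed (pyrimidine-centered) trinucleotide; the four
  contexts whose collapsed center C is followed by G form a separate CpG
  table, honoring the hypermutability and asymmetry of methylated CpG
  sites. Contexts never observed mutated fall back to a uniform prior over
  the three alternative bases so that no site has probability zero.
* **`window_size` (bp, default 100 000).** Width of the windows carrying
  local mutation-rate multipliers. Multipliers are per-window SNV densities
  normalized to mean 1; empty windows are floored at the smallest observed
  nonzero multiplier. The local adjustment enters site selection (where a
  simulated variant lands), not the substitution distribution.
* **`reg_strength` (inverse regularization, default grid 0.01–10).**
  Selected by AUROC on a 10% holdout, then the model is refit on all data.
  Standardization parameters, imputation medians and the column order are
  frozen into the model; scoring-time matrices must match exactly.
* **`flank` (bp, default 5000).** Upstream/downstream annotation distance.
  Consequence labels use a fixed severity order (canonical splice site,
  then nonsense > frameshift > missense > inframe indel > synonymous, then
  UTRs, intronic, non-coding transcript, flanks, intergenic); when several
  transcripts are hit, the most severe label wins.
* **Protein scores.** Missense: ensemble-mean log odds
  $\tfrac1M \sum_m \log(p_m[i,\text{alt}]/p_m[i,\text{ref}])$ over
  per-residue likelihood matrices supplied for a 350-residue window.
  Inframe indels: length-normalized difference of per-member sequence
  log-likelihoods in a 250-residue context; without the length
  normalization the score would be dominated by the sequence-length
  difference itself. Truncations: median over lost residues of the log
  ratio between a worst-case substitute probability and the reference
  residue's likelihood; "worst case" defaults to each member's minimum
  matrix probability (`strategy = "floor"`), with a uniform-1/20 numerator
  (`strategy = "uniform"`) as the alternative reading, since the effect of
  an absent residue is otherwise undefined. All probabilities are floored
  at $10^{-12}$ before any logarithm.
* **RegSeq.** A multitask CNN over one-hot DNA (three valid convolutions
  with leaky-ReLU and max-pooling, one dense layer, one sigmoid head per
  cell type plus a GC-matched-background head). `regseq_config()` defaults
  to the production geometry (500 bp, 64/64/32 filters of width 8, pooling
  4, dense 64). Training uses minibatch Adam with decoupled weight decay
  and optional dropout; a leaky rectifier (slope 0.1) is used because plain
  ReLU lets the first convolutional layer die wholesale early in training.
  Variant effects are probability deltas between the alternative and
  reference 500 bp windows (indel windows re-centered on the edit), with
  derived features: cell-type agnostic mean, maximum positive and minimum
  negative delta over cell-type heads, and the background-head delta.

## The synthetic mini-genome

All tests run against a generated world (`make_fixtures()`): 2 contigs of
500 kb, 20 toy genes with clean planted open reading frames on both
strands, constrained elements tiled to cover about half the genome,
regulatory elements a quarter, per-base conservation $N(3, 0.7)$ inside
constrained regions against an $N(0, 1.3)$ background, and an analogous
regulatory-activity track. The proxy-neutral set is drawn from a known
generating mutation model (transition-biased, CpG rates elevated 8-fold,
sinusoid-free stepped local multipliers) and then subjected to purifying
selection: a candidate at conservation $x$ and activity $a$ survives with
probability $\exp(-s\,\max(x+1,0) - 0.5\,s\,\max(a+1,0))$, where $s$ is set
so that the rejection probability at element-level conservation ($x = 3$)
equals the configured `rejection_fraction` (default 0.99).

The graded exponential survival (rather than a flat rejection fraction at
"conserved sites") is deliberate: a design-stage power analysis showed that
binary rejection caps the achievable held-out AUROC near 0.76 no matter how
large the constrained fraction is, because the classifier can then only
distinguish two site classes. The exponential form mimics selection
intensity proportional to constraint, grades the depletion signal across
the conservation range, and puts the default world at a held-out AUROC of
about 0.88 — comfortably above the 0.85 the planted-signal recovery test
requires, which the test suite verifies end to end.

What the fixture world does *not* emulate: realistic human base
composition, linked selection or demography (candidates are accepted or
rejected independently), dependence between conservation and local mutation
rate, annotation errors, or element classes beyond the two planted tracks.
Passing the planted-signal test therefore shows that the estimator,
annotator, feature crossing, trainer and scaler interlock correctly — not
that the defaults would be optimal on real data.

For the open-chromatin net, positives are homotypic clusters (ten copies of
a cell-type 8-mer motif per 200 bp sequence at test scale) and negatives
are either motif-free or "decoy" clusters of one-mismatch motif copies.
Both choices are deliberate: a single planted copy is not learnable by a
three-layer net from a few hundred sequences (every configuration tried
stays at chance on held-out data), and without composition-matched decoys
the net solves the task through base composition rather than base-resolved
motif recognition, which would make it insensitive to single-nucleotide
variant effects. The test suite trains a compact configuration
(200 bp window, 16/16/8 filters, dense 16): at the problem sizes the suite
uses — 150 positives per head, 30–40 epochs — the compact net reliably
reaches per-head AUROC above 0.9 while the production geometry does not,
and it trains in a fraction of the time.

## Numerical choices

* Conversion tables store one breakpoint per unique raw value; an optional
  quantile-compressed mode (`max_breaks`) reports its maximum scaled-score
  error. Queries between breakpoints take the scaled score of the largest
  breakpoint at or below them; queries above every breakpoint are capped at
  the table maximum (relevant for indels, which can score beyond any
  reference SNV); queries below every breakpoint map to 0.
* Ties: average ranks for Spearman correlation, tie-corrected
  Mann–Whitney for AUROC, block processing for average precision, and
  worst-member ranks in the conversion table so ties never inflate scores.
* The ridge logistic fit runs at convergence threshold $10^{-10}$; raw
  scores are computed from the frozen coefficients by a plain dot product,
  so scoring the same matrix twice is bit-identical.
* The per-element bootstrap subsamples 80% of pairs *without* replacement
  (the protocol is a subsample bootstrap, not the classical resample); the
  choice is switchable by fraction.
* Seeds: every stochastic stage takes an explicit integer seed and derives
  any internal seeds additively, so reruns are byte-identical; the fixture
  generator's manifest records the configuration and seed needed for exact
  regeneration.

## Known limitations

* The consequence annotator is deliberately minimal: no splice-region
  effects beyond the canonical ±2 intronic bases, no NMD logic, one
  transcript per toy gene. Unlisted consequence categories collapse into
  the nearest implemented label.
* The protein-level scores operate on pluggable likelihood matrices; the
  synthetic provider plants conservation through softmax concentration and
  is a stand-in for a trained protein language model, labelled as such.
* The compact open-chromatin net responds weakly to single-base edits:
  its per-variant prediction jitter on motif-free windows is of the same
  order as a single motif disruption, so locality is asserted in aggregate
  (sign test over 50 fixtures plus an aggregate magnitude comparison)
  rather than per variant.
* Genome-scale training (tens of millions of rows) is out of scope; the
  implementation targets mini-genomes up to a few megabases.
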