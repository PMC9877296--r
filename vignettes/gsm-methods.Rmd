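---
title: "Grouping-Scoring-Modeling for miRNA biomarker discovery: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Grouping-Scoring-Modeling for miRNA biomarker discovery}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gsmir)
```

## The problem and the model

Single-miRNA differential-expression rankings ignore what is already
known: curated databases record which miRNAs are experimentally
associated with which diseases. `gsmir` treats each such *disease
group* as the unit of feature selection. The premise is that if a
disease's associated miRNAs jointly discriminate cases (`pos`) from
controls (`neg`) in an expression study, that disease — and its
miRNAs — are relevant to the condition under study.

Three components act on a two-class expression matrix `D` (samples ×
miRNAs, non-negative RPM-like values) and a group table `R` (disease →
miRNA set):

1. **G** builds, for every group, the two-class sub-dataset of its
   member columns (intersected with `D`'s features; all samples and
   labels kept). Groups with no members in `D` are dropped.
2. **S** scores each sub-dataset by mean random-forest accuracy over
   `inner_reps` stratified Monte-Carlo splits and dense-ranks the
   groups.
3. **M** accumulates the top-k groups' member unions for k = 1…`max_k`,
   refits a fresh forest per k on the training partition, and evaluates
   accuracy, sensitivity, specificity and AUC on samples never touched
   by S.

The cycle runs inside an outer Monte-Carlo cross-validation
(`outer_iters` stratified 90/10 splits). Under-sampling and the t-test
noise filter are applied to each iteration's training partition only;
the held-out 10% is used exclusively by M's evaluation. Per-iteration
disease orderings (S's output) and miRNA orderings (each miRNA
inheriting the best score among the top-`max_k` groups containing it)
are aggregated across iterations with the order-statistic method below.

## Robust rank aggregation

For an entity with normalized ranks `r = (r(1) <= ... <= r(L))` across
`L` lists (rank = position / universe size when present, 1 when
absent), the k-th beta score is the binomial tail
`beta_k = P[Bin(L, r(k)) >= k]` — the probability that at least k of L
independent uniform ranks would be at most `r(k)`. The statistic
`rho = min_k beta_k` is Bonferroni-corrected over the L order
statistics inspected: `p = min(1, rho * L)`. The implementation uses
`pbinom`, which is numerically stable for hundreds of lists, and is
verified in the tests against exhaustive enumeration of all `2^L` hit
patterns for small `L` and against a 10^4-draw uniform null
(empirically conservative at alpha = 0.01, 0.05, 0.1).

Treating absence as worst-rank (1.0) is deliberate: under-sampling and
filtering change which groups are scorable per iteration, and an entity
that only occasionally appears should not profit from the iterations it
missed.

## Parameters

| parameter | default | meaning / rationale |
|---|---|---|
| `outer_iters` | 100 | outer 90/10 MCCV repetitions; averages in the cumulative table use exactly this denominator (degenerate iterations are re-drawn, not dropped) |
| `outer_train_frac` | 0.9 | outer training share |
| `inner_reps` | 5 | scoring repetitions per group |
| `inner_train_frac` | 0.7 | inner training share |
| `n_keep` | 1000 | top features kept by the Welch t-test filter, computed on the balanced training partition only |
| `max_k` | 10 | groups accumulated by M |
| `trees` | 100 | forest size; conventional default |
| `threshold` | 0.5 | probability cutoff for the confusion matrix (AUC is threshold-free) |
| `min_group_size` | 1 | smallest intersected group scored — curated tables legitimately contain two-member groups |
| `group_cap` | off | optional equalization: truncate every group to its top-m members by training t-test rank, removing the advantage of very large groups |

## Numerical and procedural choices

* **t-test variant.** Welch (unequal variances), two-sided — the safe
  default for expression data; ranking by p ascending with ties broken
  by |t| descending, then name. Features constant in both classes get
  t = 0, p = 1 instead of an error.
* **Rounding.** Stratified splits use round-half-up per class on the
  training side; score ties are detected after rounding to 4 decimals,
  matching the precision at which accuracies are conventionally
  reported (raw doubles would never tie and dense ranks would be
  meaningless).
* **Classifier.** No random-forest package is assumed: the package
  ships a compiled CART/bagging forest with gini splits,
  `mtry = floor(sqrt(p))`, bootstrap per tree, and a private
  xorshift64* RNG. Probabilities are across-tree means of leaf
  positive-class frequencies (smooth scores benefit AUC estimation);
  this differs from hard per-tree voting by a small amount of
  smoothing and is documented behavior, not an accident.
* **Determinism.** Every stochastic step draws its seed from the master
  seed through a counter-based affine derivation modulo 2^31 − 1;
  identical seeds give byte-identical result bundles, and nothing
  disturbs the caller's `.Random.seed`.
* **Order of balancing and filtering.** Under-sample first, then
  t-test: the filter sees equal class sizes, so its statistics are not
  driven by the majority class.
* **Tie-breaks.** Equal-rank groups are accumulated in ascending name
  order; tied AUC score pairs contribute ½.
* **Degenerate iterations.** An iteration whose partition loses a class
  is re-drawn with the next derived seed (bounded at 32 attempts) so
  the averaging denominator stays fixed.

## What the synthetic generator does and does not emulate

`synthetic_gsm()` draws expression as `exp(N(3, 1))` — lognormal,
non-negative, heavy-right-tailed, a reasonable stand-in for RPM-scale
normalized expression. Differentially expressed (DE) miRNAs receive a
`effect_size`-pooled-SD shift of the log signal in the `pos` class.
Group sizes come from a right-skewed truncated gamma (most groups
small, a few large, mirroring curated association tables); enriched
groups draw `ceiling(purity × size)` members from the DE pool,
background groups only from nulls. Defaults (60 samples, 200 miRNAs,
20 DE, 5 enriched of 50 groups, effect 2, purity 0.9) are the stated
conditions of the recovery benchmark in the acceptance suite.

Not emulated: count noise (negative binomial), library-size artifacts,
batch effects, correlated co-expression modules, miRNAs shared between
enriched and background groups. A green recovery test therefore
establishes that the pipeline machinery ranks and aggregates correctly
under clean planted signal — not that real cohorts of this size yield
similar power.

## A deliberate red flag: aggregated p-values on a fixed null dataset

With `effect_size = 0`, group scores average 0.5 as they must. But the
aggregated p-values are *not* uniform: all outer iterations resample
one finite dataset, training partitions overlap heavily, and a group
whose members separate the classes by dataset-level chance does so
consistently across iterations. Rank aggregation rewards exactly this
consistency, so a few null groups reach small p-values far more often
than the nominal rate (measured: ≈5–7% of groups below p = 0.01 versus
1% nominal at n = 60). The acceptance suite keeps the nominal-rate
assertion and it fails by design; the aggregation statistic itself is
conservative under its own null of independent uniform lists, which the
same suite verifies. Practically: the p-values rank entities within a
study; they are consistency measures, not dataset-level significance
tests, and should not be compared to a uniform null without a
dataset-level permutation calibration (out of scope here).

## Known limitations

* Scoring cost grows linearly in groups × inner repetitions × outer
  iterations; the compiled forest keeps full-scale runs (100 iterations,
  hundreds of groups) in the minutes-to-hours range on one CPU.
* Group equalization (`group_cap`) uses t-test rank truncation; other
  selection rules (random, expression-magnitude) are not offered.
* No alternative scorers (F1, recall) for ranking, no SMOTE-style
  balancing, no exact (non-Bonferroni) aggregation correction — each is
  a deliberate non-goal.
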