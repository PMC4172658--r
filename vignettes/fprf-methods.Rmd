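---
title: "Fuzzy-pattern constrained random forests: model and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Fuzzy-pattern constrained random forests: model and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fprf)
```

## The problem

Multi-class transcriptomic studies (tumour subtypes, cell populations,
disease stages) routinely need a *small, stable* set of marker genes with
high joint predictive power. Univariate filters ignore feature
interactions; wrapper methods built on standard random forests inherit two
well-known weaknesses: Gini-style split selection is biased toward
features with many distinct values, and the selected lists fluctuate
strongly between resampling runs. `fprf` implements a two-step procedure
that addresses both:

1. **Fuzzy-pattern discovery** — an unsupervised-per-gene, supervised-per-
   class discretization that nominates, for every class, the genes whose
   expression is consistently "Low", "Medium" or "High" (or an adjacent
   blend) within that class.
2. **Constrained forest ranking** — a random forest of unbiased
   (association-test based) classification trees in which the candidate
   set at every node is drawn *one feature per class pattern*, ranked by
   out-of-bag permutation accuracy importance.

An evaluation harness measures post-selection classification performance
(accuracy, macro F-score, G-mean) and selection stability
(self-consistency) under a stratified bootstrap.

## Membership functions and discretization

For each gene \(g\) the center \(c_g\) is the across-sample mean and the
spread \(s_g\) the across-sample standard deviation, always computed on
the data handed to the selector (inside the harness that is the training
split only, so no test information leaks into selection). The default
membership family is

\[
\mu_\mathrm{M}(x) = e^{-(x-c)^2 / 2s^2},\qquad
\mu_\mathrm{L}(x) = \frac{1}{1+e^{2(x-c)/s}},\qquad
\mu_\mathrm{H}(x) = \frac{1}{1+e^{-2(x-c)/s}} .
\]

The Gaussian bell models the range of typical expression; the two
sigmoids model low and high expression and cross \(1/2\) exactly at the
gene center. The family is a plug-in (`membership_family()`), so
alternative curves — e.g. polynomial approximations of these targets —
can be substituted without touching discretization, pattern discovery or
the forest.

A value is labelled by thresholding the membership triple at the
activation level `zeta`: the active set \(A=\{L:\mu_L(x)\ge\zeta\}\) maps
to its label when it is a singleton, to the combined labels *Low-Medium*
or *Medium-High* for the two adjacent pairs, to the arg-max label when
empty (ties resolved Low, Medium, High), and to *Medium* in the
measure-zero non-adjacent cases — so labelling is total. The non-adjacent
combination Low-High is never produced.

### Why the default is `zeta = 0.6`

Because both sigmoids equal \(1/2\) at the center, `zeta = 0.5` leaves at
least one sigmoid active *everywhere*: the singleton "Medium" label is
then unreachable and each gene's axis collapses into four combined-label
bands. Any `zeta` slightly above \(1/2\) restores the intended five-band
partition

\[
\mathrm{Low}\;|\;\mathrm{Low\!-\!Medium}\;|\;\mathrm{Medium}\;|\;
\mathrm{Medium\!-\!High}\;|\;\mathrm{High}
\]

with band edges (in spread units around the center) at
\(\pm\tfrac{s}{2}\log\frac{\zeta}{1-\zeta}\) and
\(\pm s\sqrt{2\log(1/\zeta)}\). At `zeta = 0.6` the five bands of a
Gaussian-distributed null gene carry probabilities of roughly
0.16 / 0.26 / 0.16 / 0.26 / 0.16, so the modal-label frequency of an
uninformative gene concentrates near 0.26–0.32 at class sizes around 30,
while a gene shifted by two noise standard deviations in one class pushes
55–60 % of that class into a single band. This separation between the
null and shifted modal frequencies is what pattern discovery exploits.

### Why the default is `piVal = 0.45`

`piVal` is the minimal modal-label frequency for a gene to enter a class
pattern. It must sit between the null modal frequency (~0.32 on average,
95th percentile ~0.43 for 30-sample classes under the five-band
partition) and the modal frequency of genuinely shifted genes (~0.57 on
average at a two-standard-deviation shift). The default 0.45 admits a few
percent of null genes per class — deliberately so: the method prefers
generous patterns because the forest ranking demotes uninformative
entries, whereas a gene excluded from every pattern can never be ranked.
Both parameters are ordinary config entries (`fp_config()`), and smaller
class sizes or weaker effects warrant lowering `piVal`.

Pattern counting uses exact label matches by default; setting
`count_constituents = TRUE` lets the combined labels also count toward
their constituent single labels, which is useful when a class straddles a
band edge.

## The constrained forest

Each of `ntree` (default 1000) trees is grown on an independent bootstrap
(sampling with replacement) of the training samples. At every node the
candidate set is one feature drawn uniformly from each class's fuzzy
pattern, deduplicated — so a node sees at most one candidate per class,
and every split feature provably belongs to the pattern union. This
raises the density of relevant candidates far above the \(\sqrt{m}\)
random draw of a standard forest when patterns are much smaller than the
feature universe.

Split selection is deliberately two-stage, in the spirit of conditional
inference trees: the split *variable* is chosen first, as the candidate
with the smallest one-way ANOVA F-test p-value against the node's class
labels (Bonferroni-adjusted over the candidates), and only then is the
split *threshold* sought, maximizing the Pearson chi-square association
between the binary partition and the class over midpoints of consecutive
distinct values. Separating variable choice from threshold search removes
the cardinality bias of exhaustive impurity search (the suite checks this
on a 2-distinct-value vs 32-distinct-value noise pair), which is also why
Gini importance is not offered at all. The full conditional-inference
machinery (linear statistics, quadratic forms, multiplicity-adjusted
permutation distributions) is approximated by this F-test gate; the split
selector sits behind an internal function boundary so a different test
can replace it without touching tree growth.

Stopping rules: a node becomes a leaf when it is pure, smaller than
`min_node` (default 5), or when the adjusted p-value exceeds
`alpha_split` (default 0.05). The significance gate doubles as built-in
pre-pruning: on pure-noise candidate sets most nodes refuse to split, so
trees stay honest rather than memorizing noise.

**Importance.** For every tree with a non-empty out-of-bag set, OOB
accuracy is compared with the accuracy after permuting one feature's
values across that tree's OOB samples (one fresh permutation per tree and
feature). The importance of a feature is the mean drop over trees.
Features a tree never splits on cannot change its predictions, so only
used features are permuted — and a feature used by no tree has importance
exactly zero. The ranking sorts by importance with ties broken by feature
ID in C-locale order, making the full pipeline bit-reproducible under a
fixed master seed (every stage derives its own sub-seed from it).

## Evaluation harness

The protocol mirrors standard feature-selection assessment: in each of
`n_boot` iterations (default 30) the data are stratified-split into
`train_fraction` (default 0.70) training and 0.30 test; selection and
ranking run on the training split only; for each cut point `n` (default
2, 3, 4, 5, 10, 20, 30, 50, 100, 150, 200, 250) a standard random forest
(1000 trees, `mtry = ceiling(sqrt(m))`, via the *randomForest* package)
is trained on the top-`n` features and scored on the test split. Per-class
allocation uses `round(train_fraction * N_c)` clamped so both splits
retain at least one sample of every class. The post-selection classifier
is deliberately *unconstrained* so that the evaluation measures the
quality of the selected features, not of the constrained sampler; a
`classifier = "constrained"` switch scores with the pattern-constrained
forest instead for probing the sampler itself. `bootstrap_evaluate()`
also accepts externally produced per-iteration lists, so any other
selector can be scored under the identical protocol.

Metrics are the overall accuracy, the macro F-score
\(F=\frac1k\sum_i 2R_iP_i/(R_i+P_i)\), and the G-mean
\((\prod_i R_i)^{1/k}\) over per-class recalls \(R_i\) and precisions
\(P_i\). Zero-denominator conventions: \(R_i\), \(P_i\) and \(F_i\) are 0
whenever their denominator is 0; these conventions are pinned by tests.
The G-mean is the imbalance diagnostic: a classifier that ignores a small
class can keep high accuracy but is annihilated by the zero recall.

**Stability.** Over the `B` per-iteration selections, a feature selected
`s` times is *self-consistent* when `s` is implausibly large under a null
in which an iteration that selected \(m_b\) of \(P\) features includes
any given feature independently with probability \(m_b/P\). The count is
then Poisson-binomial (exact binomial when all \(m_b\) are equal); the
test is one-sided at level `alpha / P` (Bonferroni over the universe,
default `alpha = 0.01`). The stability statistic is `ns/tot`: the number
of self-consistent features over the number of distinct features selected
across all iterations. On uniformly random selections the expected number
of flagged features stays below `alpha` family-wise, which the suite
verifies over 200 simulated replicates.

## The synthetic generator

`generate_dataset()` emulates an RMA-preprocessed, log2-scale expression
matrix: background cells are \(N(\mu_0,\sigma_0^2)\) (defaults 7 and 1),
and each class owns a disjoint set of planted features shifted by
\(\pm\delta\sigma_0\) in that class's samples only. Shifts are pure
location effects because the Low/Medium/High semantics are
location-based. What the generator deliberately does *not* emulate:
gene–gene correlation, heavy tails, batch effects, or probe-level
artifacts — so passing benchmarks demonstrate correctness of the
machinery and behaviour under the stated noise model, not performance on
real microarray data.

Two fixed benchmarks anchor the tests: `standard_benchmark()` (4 balanced
classes of 30 samples, 2 000 features, 10 planted per class at
\(\delta = 2\)) and `imbalanced_benchmark()` (5 classes of 60/40/20/10/6
samples, otherwise identical). The sizes are chosen to resemble a small
multi-class microarray study while keeping the full test suite in the
minutes range; the evaluation-harness checks run at `n_boot = 10` and the
ranking checks at 10 forest seeds for the same reason.

## Behaviour on the standard benchmark

With the defaults, pattern discovery on the standard benchmark selects a
union of roughly 200–230 features containing all 40 planted ones, and the
permutation ranking places essentially all planted features in the top
40. Ten selected features already classify at roughly 0.90 accuracy, 20
at about 0.98, and the curve joins the full-feature forest (1.00 on this
easy design) between cut points 20 and 40. Notably, ten features are
*not* enough to match the full matrix here — even an oracle handed ten
truly planted features scores about 0.91 — because each feature carries
only a two-standard-deviation shift for a single class; the accuracy
plateau genuinely begins around 20 features on this benchmark. The
constrained pipeline's top-20 lists are also markedly more
self-consistent across bootstrap iterations than a ranking of all 2 000
features by unconstrained random-forest importance (stability ratios
around 0.75 vs 0.65 at comparable list sizes); `scripts/acceptance.R`
recomputes all of these numbers from scratch.

## Numerical and degenerate-input choices

- Genes with zero spread make the membership family undefined; the
  membership fit refuses them and points to `filter_low_variance()`. The
  filter's default `min_sd = 0` removes only constant genes — the common
  microarray practice of stronger variance filtering is available by
  raising it, but the forest tolerates noisy features, so no stronger
  default is imposed.
- ANOVA degeneracies inside tree growth: nodes with no between-group
  variation get p-value 1 (no split); perfect within-group constancy with
  group separation gets p-value 0 (split).
- All tie-breaks are fixed and documented: label ties in the order Low <
  Low-Medium < Medium < Medium-High < High; arg-max membership ties Low,
  Medium, High; importance ties by feature ID; prediction vote ties by
  class order. Determinism across platforms relies on radix (C-locale)
  ordering for character sorts.
- `round()` in the stratified split follows R's IEEE round-half-to-even;
  the clamping rule, not rounding, guarantees non-empty splits.
- Empty fuzzy patterns warn (per class) and error only when *every*
  pattern is empty, with the advice to lower `piVal`.

## Known limitations

- The F-test split gate assumes roughly location-shift alternatives;
  purely scale- or shape-differentiated classes can escape both the
  discretization (whose labels are location bands) and the split test.
- Permutation importance is marginal: correlated informative features
  share credit, and the conditional variant is out of scope.
- Single-threaded by design; the per-stage seed derivation would allow
  parallel tree growth without changing results, but no worker pool is
  shipped.
- The self-consistency null treats iterations as independent inclusion
  draws; overlapping bootstrap training sets violate this mildly, making
  the test slightly conservative in practice.
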