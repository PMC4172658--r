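# fprf — fuzzy-pattern constrained random forests for multi-class expression data

`fprf` selects and prioritizes class-specific marker genes from a
multi-class expression matrix (genes × samples, log2 scale) in two steps:

1. **Fuzzy-pattern discovery.** Each gene's values are fuzzified through a
   Gaussian membership curve for "Medium" expression,
   µ_M(x) = exp(−(x−c)²/2s²), and two sigmoids for "Low"/"High",
   µ_L(x) = 1/(1+e^{2(x−c)/s}) and µ_H(x) = 1/(1+e^{−2(x−c)/s}), where c
   and s are the gene's mean and standard deviation. Thresholding the
   memberships at the activation level ζ labels every value Low,
   Low-Medium, Medium, Medium-High or High. The *fuzzy pattern* of class
   k collects the genes whose modal label within class k reaches the
   frequency πVal — one pattern per class, and the pattern union is the
   candidate set.
2. **Constrained forest ranking.** A random forest of unbiased
   classification trees is grown on the candidate set; at every node the
   candidate features are drawn **one per class pattern** (deduplicated),
   the split variable is chosen by a Bonferroni-adjusted one-way ANOVA
   F-test (variable choice separated from threshold search, avoiding the
   cardinality bias of impurity-based splitting), and features are ranked
   by out-of-bag permutation accuracy importance — Gini importance is
   deliberately not offered.

An evaluation harness measures what selection methods are actually used
for: post-selection classification performance (accuracy, macro F-score
F = (1/k) Σ 2R·P/(R+P), G-mean (Π Rᵢ)^{1/k}) under a stratified 70/30
bootstrap, and selection *stability* as the ratio ns/tot of significantly
self-consistent features (Poisson-binomial null, Bonferroni-corrected)
over all distinct features selected across iterations. A synthetic-data
module generates multi-class matrices with planted class-specific
features so everything is testable without downloads.

Intended users: bioinformaticians prioritizing biomarker candidates from
bulk or single-cell expression matrices, and methodologists comparing
feature-selection stability.

## Worked example

```r
library(fprf)

# 3 classes x 20 samples, 500 genes, 5 planted markers per class
gen <- generate_dataset(synthetic_spec(
  n_classes = 3, samples_per_class = c(20, 20, 20), n_features = 500,
  informative_per_class = 5, effect_size = 2.5, seed = 7))
ds  <- gen$dataset
cfg <- fp_config(seed = 42)          # zeta = 0.6, piVal = 0.45, ntree = 1000

sel <- fprf_select(ds, cfg)          # fuzzify, label, discover patterns
sel$patterns
#> FuzzyPatternSet (piVal = 0.45 ):
#>   C1: 64 features
#>   C2: 54 features
#>   C3: 66 features

ranked <- fprf_rank(sel$dataset, sel$patterns, cfg)
head(ranked, 5)
#>   rank feature_id importance
#> 1    1     g00362 0.02185155
#> 2    2     g00455 0.01854307
#> 3    3     g00243 0.01773731
#> 4    4     g00471 0.01645417
#> 5    5     g00081 0.01596329
```

The pattern union (152 of 500 genes) contains the planted markers, and
the permutation ranking concentrates them at the top — here all 15
planted features occupy the first 15 ranks. `importance` is the mean drop
in a tree's out-of-bag accuracy when that feature is permuted; 0 means a
feature no tree relies on.

```r
ev  <- fp_config(n_boot = 5, cut_points = c(5L, 15L), seed = 42)
res <- bootstrap_evaluate(ds, fprf_selector(ev), ev)
evaluation_summary(res)
#>   cut_point accuracy_mean f_score_mean g_mean_mean accuracy_sd ...
#> 1         5         0.922        0.919       0.915      0.0497
#> 2        15         0.989        0.989       0.988      0.0248

lists <- lapply(res$selections, function(s) top_n(s, 15))
stability_ratio(lists, self_consistent_features(lists, nrow(ds$values)))
#> StabilityResult: ns/tot = 15/16 = 93.8%
```

Five features already classify held-out samples at 92 % accuracy, fifteen
at 99 %, and 15 of the 16 distinct top-15 features selected across the
five bootstrap iterations are self-consistent (selected far more often
than a random-selection null allows).

## Command line

A thin CLI over the same functions ships in `inst/cli/`:

```sh
Rscript "$(Rscript -e 'cat(system.file("cli","fprf.R",package="fprf"))')" \
  simulate --out-dir data --seed 11
# then: select / rank / evaluate, e.g.
... select --matrix data/matrix.tsv --annotation data/annotation.tsv \
    --seed 11 --out-dir sel
```

Subcommands `simulate`, `select`, `rank`, `evaluate`; global flags
`--config` (YAML), `--seed`, `--zeta`, `--piVal`, `--ntree`,
`--cut-points`, `--out-dir`. Every stage writes TSV artifacts plus a JSON
run manifest (config snapshot, seed, input digests, timings), and reruns
with the same seed are byte-identical apart from manifest timestamps.

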