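#' Stratified train/test split
#'
#' Per class with `N_c` samples, `round(train_fraction * N_c)` samples
#' (clamped so both splits keep at least one sample of the class) are
#' drawn without replacement into the training split; the rest form the
#' test split. Splits are disjoint and exhaustive. Consumes the current R
#' random stream.
#'
#' @param ds An [expression_dataset()]; every class needs >= 2 samples.
#' @param train_fraction Fraction in (0, 1).
#' @return List with elements `train` and `test` (ExpressionDatasets; a
#'   test class may hold a single sample) and the id vectors `train_ids`,
#'   `test_ids`.
#' @export
stratified_split <- function(ds, train_fraction = 0.7) {
  stopifnot(inherits(ds, "ExpressionDataset"),
            train_fraction > 0, train_fraction < 1)
  sizes <- class_sizes(ds)
  if (any(sizes < 2))
    stop("class(es) with a single sample cannot be split: ",
         paste(names(sizes)[sizes < 2], collapse = ", "))
  train_ids <- character(0)
  for (cl in ds$classes) {
    ids <- colnames(ds$values)[ds$class_of == cl]
    n_tr <- min(max(round(train_fraction * length(ids)), 1L),
                length(ids) - 1L)
    train_ids <- c(train_ids, sample(ids, n_tr))
  }
  all_ids <- colnames(ds$values)
  train_ids <- all_ids[all_ids %in% train_ids]  # keep column order
  test_ids <- setdiff(all_ids, train_ids)
  list(train = subset_samples(ds, train_ids),
       test = subset_samples(ds, test_ids),
       train_ids = train_ids, test_ids = test_ids)
}

#' Run fuzzy-pattern discovery on a dataset
#'
#' Convenience wrapper chaining [filter_low_variance()],
#' [fit_membership_model()], [discretize()] and
#' [discover_fuzzy_patterns()] under one configuration.
#'
#' @param ds An [expression_dataset()].
#' @param config An [fp_config()].
#' @return List with the filtered dataset (`dataset`), the fitted
#'   `model`, the label matrix (`labels`), the `patterns`, and the
#'   selected-feature union (`features`).
#' @export
fprf_select <- function(ds, config = fp_config()) {
  ds <- filter_low_variance(ds, config$min_sd)
  model <- fit_membership_model(ds)
  labels <- discretize(ds, model, config$zeta)
  patterns <- discover_fuzzy_patterns(labels, ds, config$piVal,
                                      config$count_constituents)
  list(dataset = ds, model = model, labels = labels, patterns = patterns,
       features = selected_features(patterns))
}

#' Rank fuzzy-pattern features with the constrained forest
#'
#' Fits the pattern-constrained forest and ranks the pattern-feature union
#' by out-of-bag permutation importance.
#'
#' @param ds An [expression_dataset()] containing the pattern features.
#' @param patterns A [discover_fuzzy_patterns()] result.
#' @param config An [fp_config()].
#' @param seed Seed for forest growth and permutation (defaults to
#'   `config$seed`).
#' @return A `RankedFeatureList` (see [rank_features()]).
#' @export
fprf_rank <- function(ds, patterns, config = fp_config(),
                      seed = config$seed) {
  if (is.null(seed)) stop("a seed is required (config$seed or `seed`)")
  seeds <- derive_seeds(seed, 2)
  forest <- fit_fp_forest(ds, patterns, config, seed = seeds[1])
  keep <- subset_features(ds, forest$feature_ids)
  imp <- permutation_importance(forest, keep, seed = seeds[2])
  rank_features(imp)
}

#' Selector: the full fuzzy-pattern random-forest pipeline
#'
#' Builds a selector function for [bootstrap_evaluate()]: given a training
#' dataset and a seed it runs pattern discovery and forest ranking and
#' returns the ranked list. Membership statistics are fitted on the
#' training split only.
#'
#' @param config An [fp_config()].
#' @return A function `(train, seed) -> RankedFeatureList`.
#' @export
fprf_selector <- function(config = fp_config()) {
  force(config)
  function(train, seed) {
    sel <- fprf_select(train, config)
    fprf_rank(sel$dataset, sel$patterns, config, seed = seed)
  }
}

#' Selector: unconstrained random-forest permutation importance
#'
#' Baseline selector ranking *all* features of the training split by the
#' mean-decrease-accuracy importance of a standard random forest
#' (\pkg{randomForest}), for comparison with the constrained pipeline.
#'
#' @param ntree Number of trees.
#' @return A function `(train, seed) -> RankedFeatureList`.
#' @export
rf_importance_selector <- function(ntree = 1000L) {
  force(ntree)
  function(train, seed) {
    set.seed(as.integer(seed))
    fit <- randomForest::randomForest(
      x = t(train$values),
      y = factor(train$class_of, levels = train$classes),
      ntree = ntree, importance = TRUE)
    imp <- fit$importance[, "MeanDecreaseAccuracy"]
    rank_features(imp)
  }
}

# Train a standard RF on the given features and predict the test split.
post_selection_predict <- function(train, test, features, ntree, seed) {
  set.seed(as.integer(seed))
  fit <- randomForest::randomForest(
    x = t(train$values[features, , drop = FALSE]),
    y = factor(train$class_of, levels = train$classes),
    ntree = ntree, mtry = ceiling(sqrt(length(features))))
  as.character(stats::predict(fit, t(test$values[features, , drop = FALSE])))
}

# Pattern-constrained alternative: rediscover patterns on the restricted
# training matrix and classify with the constrained forest. Falls back to
# the standard classifier (with a warning) when discovery finds nothing.
post_selection_predict_constrained <- function(train, test, features,
                                               config, ntree, seed) {
  sub <- subset_features(train, features)
  sel <- tryCatch(suppressWarnings(fprf_select(sub, config)),
                  error = function(e) NULL)
  if (is.null(sel)) {
    warning("constrained classifier: empty patterns on the selected ",
            "features; falling back to the standard forest",
            call. = FALSE)
    return(post_selection_predict(train, test, features, ntree, seed))
  }
  cfg <- config
  cfg$ntree <- as.integer(ntree)
  forest <- fit_fp_forest(sel$dataset, sel$patterns, cfg, seed = seed)
  unname(predict(forest, test$values))
}

#' Stratified bootstrap evaluation of a feature selector
#'
#' The evaluation protocol: in each of `n_boot` iterations the dataset is
#' stratified-split into train/test; the selector runs on the training
#' split only; for each cut point `n` a standard random forest
#' (`ntree` trees, `mtry = ceiling(sqrt(m))`) is trained on the top-`n`
#' features and scored on the test split with accuracy, macro F-score and
#' G-mean. Per-iteration selections are kept for stability analysis. All
#' per-iteration seeds are derived from `config$seed`, so the whole run is
#' reproducible.
#'
#' @param ds An [expression_dataset()].
#' @param selector Either a function `(train, seed)` returning a
#'   `RankedFeatureList` or a plain character vector of features, or a
#'   list of `n_boot` pre-computed per-iteration feature vectors (for
#'   externally produced selections).
#' @param config An [fp_config()]; `seed` must be set.
#' @param classifier_ntree Trees of the post-selection classifier
#'   (defaults to `config$ntree`).
#' @param classifier `"standard"` (default) scores selections with an
#'   unconstrained random forest, so the evaluation measures the selected
#'   features rather than the constrained sampler; `"constrained"`
#'   rediscovers patterns on the restricted training matrix and scores
#'   with the pattern-constrained forest instead.
#' @return An object of class `EvaluationResult`: list with `metrics`
#'   (data frame: iteration, cut_point, n_features, accuracy, f_score,
#'   g_mean), `selections` (per-iteration selector output), `failed`
#'   (iterations whose selection was empty), and `cut_points`.
#' @export
bootstrap_evaluate <- function(ds, selector, config = fp_config(),
                               classifier_ntree = config$ntree,
                               classifier = c("standard", "constrained")) {
  stopifnot(inherits(ds, "ExpressionDataset"))
  classifier <- match.arg(classifier)
  if (is.null(config$seed)) stop("config$seed must be set")
  B <- config$n_boot
  seeds <- matrix(derive_seeds(config$seed, 3L * B), nrow = 3L)
  fixed_lists <- is.list(selector) && !is.function(selector)
  if (fixed_lists && length(selector) < B)
    stop("need ", B, " per-iteration lists, got ", length(selector))

  metrics <- list()
  selections <- vector("list", B)
  failed <- integer(0)
  for (b in seq_len(B)) {
    set.seed(seeds[1, b])
    sp <- stratified_split(ds, config$train_fraction)
    sel <- if (fixed_lists) selector[[b]]
           else if (is.function(selector)) selector(sp$train, seeds[2, b])
           else selector
    selections[[b]] <- sel
    ranked <- is.data.frame(sel)
    ids_all <- if (ranked) sel$feature_id else as.character(sel)
    if (!length(ids_all)) {
      warning("iteration ", b, ": selector returned an empty list",
              call. = FALSE)
      failed <- c(failed, b)
      next
    }
    cuts <- if (ranked) config$cut_points else NA_integer_
    clf_seeds <- derive_seeds(seeds[3, b], length(cuts))
    for (j in seq_along(cuts)) {
      feats <- if (ranked)
        ids_all[seq_len(min(cuts[j], length(ids_all)))]
      else ids_all
      pred <- if (classifier == "constrained")
        post_selection_predict_constrained(sp$train, sp$test, feats,
                                           config, classifier_ntree,
                                           clf_seeds[j])
      else post_selection_predict(sp$train, sp$test, feats,
                                  classifier_ntree, clf_seeds[j])
      cm <- confusion_matrix(sp$test$class_of, pred, ds$classes)
      metrics[[length(metrics) + 1L]] <-
        data.frame(iteration = b, cut_point = cuts[j],
                   n_features = length(feats),
                   accuracy = accuracy(cm), f_score = f_score(cm),
                   g_mean = g_mean(cm))
    }
  }
  metrics <- if (length(metrics)) do.call(rbind, metrics) else
    data.frame(iteration = integer(), cut_point = integer(),
               n_features = integer(), accuracy = numeric(),
               f_score = numeric(), g_mean = numeric())
  structure(list(metrics = metrics, selections = selections,
                 failed = failed, cut_points = config$cut_points,
                 classes = ds$classes),
            class = "EvaluationResult")
}

#' Summarize an evaluation: mean and sd of each metric per cut point
#'
#' @param result A [bootstrap_evaluate()] result.
#' @return Data frame with one row per cut point.
#' @export
evaluation_summary <- function(result) {
  stopifnot(inherits(result, "EvaluationResult"))
  m <- result$metrics
  agg <- function(f, nm) {
    a <- stats::aggregate(m[c("accuracy", "f_score", "g_mean")],
                          by = list(cut_point = m$cut_point), FUN = f)
    colnames(a)[-1] <- paste0(colnames(a)[-1], nm)
    a
  }
  out <- merge(agg(mean, "_mean"), agg(stats::sd, "_sd"),
               by = "cut_point", sort = TRUE)
  out
}

#' @export
print.EvaluationResult <- function(x, ...) {
  cat("EvaluationResult:", length(x$selections), "iterations",
      if (length(x$failed)) paste0("(", length(x$failed), " failed)") else "",
      "\n")
  print(evaluation_summary(x), digits = 3)
  invisible(x)
}

# Poisson-binomial upper-tail probabilities P(X >= s), s = 0..B, for
# inclusion probabilities p (dynamic-programming convolution).
poisson_binomial_tail <- function(p) {
  f <- 1
  for (pb in p) f <- c(f * (1 - pb), 0) + c(0, f * pb)
  rev(cumsum(rev(f)))
}

#' Significantly self-consistent features across bootstrap selections
#'
#' Null model: a selection of `m_b` features out of `P` at iteration `b`
#' includes a given feature independently with probability `m_b / P`; the
#' number of inclusions over the `B` iterations is then Poisson-binomial.
#' A feature with observed selection count `s` is significantly
#' self-consistent when `P(X >= s) <= alpha / P` (Bonferroni over the
#' feature universe).
#'
#' @param selection_lists List of `B >= 2` per-iteration feature vectors.
#' @param P Size of the feature universe (total feature count).
#' @param alpha Family-wise significance level.
#' @return Character vector of self-consistent features, with attributes
#'   `counts` and `p_values` (named, over all selected features).
#' @export
self_consistent_features <- function(selection_lists, P, alpha = 0.01) {
  stopifnot(is.list(selection_lists), length(selection_lists) >= 2,
            P >= 1, alpha > 0, alpha <= 1)
  lists <- lapply(selection_lists, function(l) unique(as.character(l)))
  m <- lengths(lists)
  if (any(m > P))
    stop("a selection list is larger than the feature universe P")
  counts <- table(unlist(lists, use.names = FALSE))
  tail_prob <- poisson_binomial_tail(m / P)
  pv <- stats::setNames(tail_prob[as.integer(counts) + 1L], names(counts))
  sig <- names(pv)[pv <= alpha / P]
  structure(sort(sig),
            counts = stats::setNames(as.integer(counts), names(counts)),
            p_values = pv)
}

#' Selection-stability statistic: self-consistent over total selected
#'
#' @param selection_lists List of per-iteration feature vectors.
#' @param stable_set Self-consistent feature set (subset of the union of
#'   the lists), e.g. from [self_consistent_features()].
#' @return An object of class `StabilityResult`: list with `ns`
#'   (self-consistent count), `tot` (distinct features selected over all
#'   iterations), `ratio = ns/tot`, and per-feature `counts`.
#' @export
stability_ratio <- function(selection_lists, stable_set) {
  stopifnot(is.list(selection_lists))
  all_ids <- unlist(lapply(selection_lists, unique), use.names = FALSE)
  un <- unique(all_ids)
  if (!length(un)) stop("union of selection lists is empty")
  if (length(setdiff(stable_set, un)))
    stop("stable_set contains features never selected")
  counts <- table(all_ids)
  structure(list(ns = length(stable_set), tot = length(un),
                 ratio = length(stable_set) / length(un),
                 counts = stats::setNames(as.integer(counts),
                                          names(counts))),
            class = "StabilityResult")
}

#' @export
print.StabilityResult <- function(x, ...) {
  cat(sprintf("StabilityResult: ns/tot = %d/%d = %.1f%%\n",
              x$ns, x$tot, 100 * x$ratio))
  invisible(x)
}
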