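#' Draw the candidate feature set for one node split
#'
#' Implements the constrained node-sampling rule: from each non-empty
#' fuzzy pattern, one feature is drawn uniformly at random; the union is
#' deduplicated, so the candidate set has at most one feature per class
#' pattern. Consumes the current R random stream.
#'
#' @param patterns A [discover_fuzzy_patterns()] result (at least one
#'   non-empty pattern).
#' @return Character vector of candidate feature IDs.
#' @export
draw_node_candidates <- function(patterns) {
  stopifnot(inherits(patterns, "FuzzyPatternSet"))
  sizes <- vapply(patterns, nrow, integer(1))
  if (all(sizes == 0L))
    stop("all fuzzy patterns are empty; nothing to sample")
  picks <- character(0)
  for (p in patterns) {
    k <- nrow(p)
    if (k > 0L) picks <- c(picks, p$feature_id[sample.int(k, 1L)])
  }
  unique(picks)
}

# One-way ANOVA F-test p-value of x against integer group labels y (levels
# 1..k). Degenerate cases: no within-group variation with between-group
# variation -> 0; no between-group variation (or too few df) -> 1.
anova_f_pvalue <- function(x, y, k) {
  n <- length(x)
  n_g <- tabulate(y, k)
  g <- sum(n_g > 0L)
  if (g < 2L || n - g < 1L) return(1)
  gm <- mean(x)
  sums <- rowsum(x, y)
  means <- sums[, 1] / n_g[n_g > 0L]
  ssb <- sum(n_g[n_g > 0L] * (means - gm)^2)
  sst <- sum((x - gm)^2)
  ssw <- sst - ssb
  if (sst <= 0) return(1)
  if (ssw <= 1e-12 * sst) return(if (ssb > 0) 0 else 1)
  f <- (ssb / (g - 1)) / (ssw / (n - g))
  stats::pf(f, g - 1, n - g, lower.tail = FALSE)
}

# Best binary threshold on x for class labels y (integer, levels 1..k):
# maximizes the Pearson chi-square association between the split and the
# class over midpoints of consecutive distinct values. Ties go to the
# smallest threshold. Returns NULL when x has a single distinct value.
best_threshold <- function(x, y, k) {
  ord <- order(x)
  xs <- x[ord]
  ys <- y[ord]
  n <- length(xs)
  cuts <- which(xs[-n] < xs[-1])
  if (!length(cuts)) return(NULL)
  ind <- matrix(0L, n, k)
  ind[cbind(seq_len(n), ys)] <- 1L
  cum <- apply(ind, 2, cumsum)
  if (n == 1L) cum <- matrix(cum, 1L)
  tot <- cum[n, ]
  keep <- tot > 0L
  nl <- cuts
  nr <- n - nl
  # expected counts under independence; chi-square over both split sides
  stat <- numeric(length(cuts))
  for (j in which(keep)) {
    ol <- cum[cuts, j]
    el <- nl * tot[j] / n
    er <- nr * tot[j] / n
    stat <- stat + (ol - el)^2 / el + ((tot[j] - ol) - er)^2 / er
  }
  i <- cuts[which.max(stat)]
  (xs[i] + xs[i + 1]) / 2
}

# Recursive-partitioning engine. X: features x samples numeric matrix of
# the training node universe; y: integer class labels (1..k); pat_idx:
# per-pattern integer row indices into X. Splitting stops on purity, node
# size < min_node, or Bonferroni-adjusted association p-value > alpha.
grow_tree_impl <- function(X, y, k, pat_idx, alpha_split, min_node) {
  var_idx <- integer(0); thr <- numeric(0)
  left <- integer(0); right <- integer(0)
  counts <- list()
  n_pat <- length(pat_idx)

  new_node <- function() {
    var_idx[[length(var_idx) + 1L]] <<- NA_integer_
    thr[[length(thr) + 1L]] <<- NA_real_
    left[[length(left) + 1L]] <<- 0L
    right[[length(right) + 1L]] <<- 0L
    counts[[length(counts) + 1L]] <<- integer(k)
    length(var_idx)
  }

  build <- function(cols) {
    id <- new_node()
    yn <- y[cols]
    cnt <- tabulate(yn, k)
    counts[[id]] <<- cnt
    if (length(cols) < min_node || sum(cnt > 0L) < 2L) return(id)
    cand <- integer(0)
    for (p in seq_len(n_pat)) {
      v <- pat_idx[[p]]
      if (length(v)) cand <- c(cand, v[sample.int(length(v), 1L)])
    }
    cand <- unique(cand)
    if (!length(cand)) return(id)
    pvals <- vapply(cand, function(fi) anova_f_pvalue(X[fi, cols], yn, k),
                    numeric(1))
    best <- which.min(pvals)
    p_adj <- min(1, pvals[best] * length(cand))
    if (p_adj > alpha_split) return(id)
    fi <- cand[best]
    t0 <- best_threshold(X[fi, cols], yn, k)
    if (is.null(t0)) return(id)
    go_left <- X[fi, cols] <= t0
    if (!any(go_left) || all(go_left)) return(id)
    var_idx[[id]] <<- fi
    thr[[id]] <<- t0
    left[[id]] <<- build(cols[go_left])
    right[[id]] <<- build(cols[!go_left])
    id
  }

  build(seq_len(ncol(X)))
  list(var_idx = var_idx, thr = thr, left = left, right = right,
       counts = matrix(unlist(counts), nrow = k))
}

#' Grow one constrained classification tree
#'
#' Recursive binary partitioning in the style of unbiased (conditional
#' inference) trees: at each node the candidate features are drawn one per
#' fuzzy pattern ([draw_node_candidates()]); the split variable is the
#' candidate with the smallest one-way ANOVA F-test p-value against the
#' node's class labels, Bonferroni-adjusted over the candidates; the
#' binary threshold maximizes the chi-square association between the split
#' and the class over midpoints of consecutive distinct values. Splitting
#' stops on purity, small nodes, or an insignificant adjusted p-value, so
#' variable selection is separated from threshold search (this is what
#' removes the variable-cardinality bias of exhaustive Gini search).
#'
#' @param train An [expression_dataset()] restricted to (at least) the
#'   fuzzy-pattern features.
#' @param patterns A [discover_fuzzy_patterns()] result.
#' @param alpha_split Significance gate for splitting (Bonferroni-adjusted
#'   p-value must be <= this).
#' @param min_node Minimum node size eligible for splitting.
#' @return An object of class `fp_tree`.
#' @export
grow_tree <- function(train, patterns, alpha_split = 0.05, min_node = 5L) {
  stopifnot(inherits(train, "ExpressionDataset"),
            inherits(patterns, "FuzzyPatternSet"))
  X <- train$values
  y <- match(train$class_of, train$classes)
  k <- length(train$classes)
  pat_idx <- lapply(patterns, function(p) {
    idx <- match(p$feature_id, rownames(X))
    if (anyNA(idx))
      stop("pattern feature(s) absent from training data: ",
           paste(utils::head(p$feature_id[is.na(idx)], 5), collapse = ", "))
    idx
  })
  t0 <- grow_tree_impl(X, y, k, pat_idx, alpha_split, min_node)
  structure(c(t0, list(feature_ids = rownames(X), classes = train$classes)),
            class = "fp_tree")
}

# Route the columns of X (features x samples, same feature order as the
# tree was grown with, addressed via `fmap`: tree var index -> X row) down
# a tree; returns the terminal node id per sample.
route_tree <- function(tree, X, fmap = seq_len(nrow(X))) {
  n <- ncol(X)
  node <- rep(1L, n)
  repeat {
    v <- tree$var_idx[node]
    active <- which(!is.na(v))
    if (!length(active)) break
    xv <- X[cbind(fmap[v[active]], active)]
    goes_left <- xv <= tree$thr[node[active]]
    node[active] <- ifelse(goes_left, tree$left[node[active]],
                           tree$right[node[active]])
  }
  node
}

# Majority class (integer code) of the terminal nodes, ties broken by
# class order.
leaf_class <- function(tree, node) {
  max.col(t(tree$counts[, node, drop = FALSE]), ties.method = "first")
}

#' Fit a fuzzy-pattern constrained random forest
#'
#' Grows `ntree` trees with [grow_tree()], each on an independent
#' bootstrap (with replacement) of the training samples, recording per-tree
#' in-bag and out-of-bag sample sets for honest importance estimation.
#' Fully deterministic given `seed`.
#'
#' @param train An [expression_dataset()] containing all fuzzy-pattern
#'   features; the forest is fitted on the pattern-feature union.
#' @param patterns A [discover_fuzzy_patterns()] result.
#' @param config An [fp_config()] (uses `ntree`, `alpha_split`,
#'   `min_node`, `seed`).
#' @param seed Overrides `config$seed` when given.
#' @return An object of class `fp_forest`.
#' @export
fit_fp_forest <- function(train, patterns, config = fp_config(),
                          seed = config$seed) {
  stopifnot(inherits(train, "ExpressionDataset"),
            inherits(patterns, "FuzzyPatternSet"))
  if (is.null(seed)) stop("a seed is required (config$seed or `seed`)")
  feats <- selected_features(patterns)
  train <- subset_features(train, feats)
  X <- train$values
  y <- match(train$class_of, train$classes)
  k <- length(train$classes)
  pat_idx <- lapply(patterns, function(p) match(p$feature_id, feats))
  n <- ncol(X)

  set.seed(as.integer(seed))
  trees <- vector("list", config$ntree)
  inbag <- vector("list", config$ntree)
  oob <- vector("list", config$ntree)
  for (b in seq_len(config$ntree)) {
    idx <- sample.int(n, n, replace = TRUE)
    inbag[[b]] <- idx
    oob[[b]] <- setdiff(seq_len(n), idx)
    trees[[b]] <- grow_tree_impl(X[, idx, drop = FALSE], y[idx], k,
                                 pat_idx, config$alpha_split,
                                 config$min_node)
  }
  structure(list(trees = trees, inbag = inbag, oob = oob,
                 patterns = patterns, feature_ids = feats,
                 classes = train$classes, seed = as.integer(seed),
                 ntree = config$ntree),
            class = "fp_forest")
}

#' @export
print.fp_forest <- function(x, ...) {
  cat("fp_forest:", x$ntree, "trees,", length(x$feature_ids),
      "candidate features,", length(x$classes), "classes\n")
  invisible(x)
}

#' Predict class labels with a constrained forest
#'
#' Per-sample majority vote over the trees; vote ties are broken by class
#' order.
#'
#' @param object An [fit_fp_forest()] result.
#' @param newdata An [expression_dataset()] or a features-by-samples
#'   numeric matrix carrying every feature the forest's trees split on.
#' @param ... Unused.
#' @return Character vector of predicted class labels, named by sample.
#' @export
predict.fp_forest <- function(object, newdata, ...) {
  X <- if (inherits(newdata, "ExpressionDataset")) newdata$values else newdata
  stopifnot(is.matrix(X), is.numeric(X))
  used <- unique(unlist(lapply(object$trees, function(t)
    t$var_idx[!is.na(t$var_idx)])))
  need <- object$feature_ids[used]
  fmap <- match(object$feature_ids, rownames(X))
  miss <- need[is.na(fmap[used])]
  if (length(miss))
    stop("feature(s) required by the forest missing from newdata: ",
         paste(utils::head(miss, 5), collapse = ", "))
  k <- length(object$classes)
  n <- ncol(X)
  votes <- matrix(0L, n, k)
  for (b in seq_along(object$trees)) {
    tr <- object$trees[[b]]
    pred <- leaf_class(tr, route_tree(tr, X, fmap))
    votes[cbind(seq_len(n), pred)] <- votes[cbind(seq_len(n), pred)] + 1L
  }
  stats::setNames(object$classes[max.col(votes, ties.method = "first")],
                  colnames(X))
}

#' Out-of-bag permutation accuracy importance
#'
#' For every feature and every tree with a non-empty out-of-bag set, the
#' drop in that tree's OOB accuracy after permuting the feature's values
#' across the OOB samples is recorded (one fresh permutation per tree and
#' feature); the importance is the mean drop over those trees. Features a
#' tree does not split on cannot change its predictions, so only features
#' used by a tree are permuted; features used by no tree have importance
#' exactly 0.
#'
#' @param forest An [fit_fp_forest()] result.
#' @param train The [expression_dataset()] the forest was fitted on.
#' @param seed Integer seed for the permutations.
#' @return Named numeric vector: feature ID -> mean OOB accuracy decrease.
#' @export
permutation_importance <- function(forest, train, seed = forest$seed) {
  stopifnot(inherits(forest, "fp_forest"),
            inherits(train, "ExpressionDataset"))
  X <- train$values[forest$feature_ids, , drop = FALSE]
  y <- match(train$class_of, forest$classes)
  set.seed(as.integer(seed))
  imp <- stats::setNames(numeric(length(forest$feature_ids)),
                         forest$feature_ids)
  n_used <- 0L
  for (b in seq_along(forest$trees)) {
    ob <- forest$oob[[b]]
    if (!length(ob)) next
    n_used <- n_used + 1L
    tr <- forest$trees[[b]]
    Xo <- X[, ob, drop = FALSE]
    yo <- y[ob]
    base_acc <- mean(leaf_class(tr, route_tree(tr, Xo)) == yo)
    used <- unique(tr$var_idx[!is.na(tr$var_idx)])
    for (fi in used) {
      Xp <- Xo
      Xp[fi, ] <- Xo[fi, sample.int(length(ob))]
      perm_acc <- mean(leaf_class(tr, route_tree(tr, Xp)) == yo)
      imp[fi] <- imp[fi] + (base_acc - perm_acc)
    }
  }
  if (n_used == 0L) stop("no tree has a non-empty out-of-bag set")
  imp / n_used
}

#' Rank features by importance
#'
#' @param imp Named numeric vector of importances (e.g. from
#'   [permutation_importance()]).
#' @return A `RankedFeatureList`: data frame with columns `rank` (1-based),
#'   `feature_id`, `importance`, sorted by importance descending with ties
#'   broken by feature ID (C-locale lexicographic).
#' @export
rank_features <- function(imp) {
  stopifnot(is.numeric(imp), length(imp) > 0, !is.null(names(imp)))
  ord <- order(-imp, names(imp), method = "radix")
  structure(data.frame(rank = seq_along(imp),
                       feature_id = names(imp)[ord],
                       importance = unname(imp)[ord],
                       stringsAsFactors = FALSE),
            class = c("RankedFeatureList", "data.frame"))
}

#' Truncate a ranked list at a cut point
#'
#' @param ranked A [rank_features()] result.
#' @param n Positive cut point; when `n` exceeds the list length the whole
#'   list is returned with a warning.
#' @return Character vector of the first `min(n, length)` feature IDs.
#' @export
top_n <- function(ranked, n) {
  stopifnot(is.data.frame(ranked), n >= 1)
  if (n > nrow(ranked))
    warning("cut point ", n, " exceeds ranked-list length ", nrow(ranked),
            "; returning the full list", call. = FALSE)
  ranked$feature_id[seq_len(min(n, nrow(ranked)))]
}

#' Serialize a constrained forest to a versioned JSON file
#'
#' @param forest An [fit_fp_forest()] result.
#' @param path Output path.
#' @export
write_fp_forest <- function(forest, path) {
  stopifnot(inherits(forest, "fp_forest"))
  box <- jsonlite::unbox
  payload <- list(
    format = box("fprf-forest"), version = box(1L),
    feature_ids = forest$feature_ids, classes = forest$classes,
    seed = box(forest$seed), ntree = box(forest$ntree),
    inbag = forest$inbag, oob = forest$oob,
    patterns = lapply(unclass(forest$patterns), function(p)
      as.list(p)),
    pattern_classes = attr(forest$patterns, "classes"),
    piVal = box(attr(forest$patterns, "piVal")),
    trees = lapply(forest$trees, function(t)
      list(var_idx = t$var_idx, thr = t$thr, left = t$left,
           right = t$right, counts = as.vector(t$counts),
           k = box(nrow(t$counts)))))
  jsonlite::write_json(payload, path, auto_unbox = FALSE, digits = NA,
                       null = "null", na = "null")
}

#' Read a forest written by [write_fp_forest()]
#'
#' @param path Path to the JSON file.
#' @return An `fp_forest`.
#' @export
read_fp_forest <- function(path) {
  p <- jsonlite::read_json(path, simplifyVector = FALSE)
  if (!identical(p$format, "fprf-forest"))
    stop("not a serialized fprf forest: ", path)
  vec <- function(l, mode) {
    na <- switch(mode, integer = NA_integer_, double = NA_real_)
    vapply(l, function(x) if (is.null(x)) na else
      switch(mode, integer = as.integer(x), double = as.numeric(x)),
      na)
  }
  chr <- function(l) vapply(l, as.character, character(1))
  trees <- lapply(p$trees, function(t)
    list(var_idx = vec(t$var_idx, "integer"),
         thr = vec(t$thr, "double"),
         left = vec(t$left, "integer"),
         right = vec(t$right, "integer"),
         counts = matrix(vec(t$counts, "integer"), nrow = t$k)))
  classes <- chr(p$pattern_classes)
  pats <- stats::setNames(lapply(classes, function(cl) {
    q <- p$patterns[[cl]]
    if (is.null(q) || !length(q$feature_id))
      return(data.frame(feature_id = character(), label = character(),
                        frequency = numeric()))
    data.frame(feature_id = chr(q$feature_id), label = chr(q$label),
               frequency = vec(q$frequency, "double"),
               stringsAsFactors = FALSE)
  }), classes)
  patterns <- structure(pats, classes = classes,
                        piVal = if (is.null(p$piVal)) NA_real_ else p$piVal,
                        class = "FuzzyPatternSet")
  structure(list(trees = trees,
                 inbag = lapply(p$inbag, function(l) vec(l, "integer")),
                 oob = lapply(p$oob, function(l) vec(l, "integer")),
                 patterns = patterns,
                 feature_ids = chr(p$feature_ids), classes = chr(p$classes),
                 seed = as.integer(p$seed), ntree = as.integer(p$ntree)),
            class = "fp_forest")
}
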