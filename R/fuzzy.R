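#' The five linguistic labels of the fuzzy discretization
#'
#' Labels are ordered `Low < Low-Medium < Medium < Medium-High < High`;
#' this order is also the deterministic tie-break order used throughout.
#' The non-adjacent combination Low-High is never produced.
#'
#' @return Character vector of the five labels in their fixed order.
#' @export
fuzzy_labels <- function() {
  c("Low", "Low-Medium", "Medium", "Medium-High", "High")
}

#' Define a membership-function family
#'
#' A family supplies the three per-gene membership curves as functions of
#' the expression value `x`, the gene center `c` and spread `s`. This is a
#' plug-in point: alternative families (e.g. polynomial approximations of
#' the same curves) can be substituted without touching the rest of the
#' pipeline.
#'
#' @param mu_low,mu_medium,mu_high Functions `(x, c, s) -> [0,1]`,
#'   vectorized in `x`. `mu_medium` must be unimodal with maximum at `c`,
#'   `mu_low` non-increasing and `mu_high` non-decreasing in `x`.
#' @param name Short identifier for reporting.
#' @return An object of class `MembershipFamily`.
#' @export
membership_family <- function(mu_low, mu_medium, mu_high, name) {
  stopifnot(is.function(mu_low), is.function(mu_medium),
            is.function(mu_high), is.character(name))
  structure(list(mu_low = mu_low, mu_medium = mu_medium,
                 mu_high = mu_high, name = name),
            class = "MembershipFamily")
}

#' Default membership family: Gaussian bell with sigmoidal flanks
#'
#' `mu_Medium(x) = exp(-(x-c)^2 / (2 s^2))` models the range of typical
#' expression of a gene; `mu_Low(x) = 1/(1+exp(+a(x-c)))` and
#' `mu_High(x) = 1/(1+exp(-a(x-c)))` with steepness `a = steepness/s`
#' model low and high expression asymmetrically. Both sigmoids cross 1/2
#' at the gene center.
#'
#' @param steepness Dimensionless sigmoid steepness; the rate constant is
#'   `steepness / s`.
#' @return A [membership_family()].
#' @export
gaussian_sigmoid_family <- function(steepness = 2) {
  stopifnot(is.numeric(steepness), steepness > 0)
  membership_family(
    mu_low = function(x, c, s) 1 / (1 + exp(steepness * (x - c) / s)),
    mu_medium = function(x, c, s) exp(-(x - c)^2 / (2 * s^2)),
    mu_high = function(x, c, s) 1 / (1 + exp(-steepness * (x - c) / s)),
    name = sprintf("gaussian_sigmoid(steepness=%g)", steepness))
}

#' Fit per-gene membership functions
#'
#' For each feature the center `c` is the across-sample mean and the
#' spread `s` the across-sample (sample) standard deviation. Statistics
#' are computed on the matrix handed in — inside the evaluation harness
#' that is always the training split, never test data.
#'
#' @param ds An [expression_dataset()]; every feature must have sd > 0
#'   (apply [filter_low_variance()] first).
#' @param family A [membership_family()].
#' @return An object of class `MembershipModel` with per-feature `center`
#'   and `spread` and the family used.
#' @export
fit_membership_model <- function(ds, family = gaussian_sigmoid_family()) {
  stopifnot(inherits(ds, "ExpressionDataset"),
            inherits(family, "MembershipFamily"))
  center <- rowMeans(ds$values)
  spread <- row_sds(ds$values)
  zero <- names(spread)[spread == 0]
  if (length(zero))
    stop("feature(s) with zero spread (pre-filter with filter_low_variance): ",
         paste(utils::head(zero, 5), collapse = ", "))
  structure(list(feature_ids = rownames(ds$values),
                 center = center, spread = spread, family = family),
            class = "MembershipModel")
}

#' @export
print.MembershipModel <- function(x, ...) {
  cat("MembershipModel:", length(x$feature_ids), "features, family",
      x$family$name, "\n")
  invisible(x)
}

#' Evaluate the three membership functions of one feature
#'
#' @param model A [fit_membership_model()].
#' @param feature_id Feature to evaluate.
#' @param x Expression value(s).
#' @return For scalar `x`, a named numeric vector `(low, medium, high)`;
#'   for vector `x`, a matrix with one row per value and those columns.
#' @export
memberships <- function(model, feature_id, x) {
  stopifnot(inherits(model, "MembershipModel"))
  if (!feature_id %in% model$feature_ids)
    stop("unknown feature: ", feature_id)
  c0 <- model$center[[feature_id]]
  s0 <- model$spread[[feature_id]]
  fam <- model$family
  m <- cbind(low = fam$mu_low(x, c0, s0),
             medium = fam$mu_medium(x, c0, s0),
             high = fam$mu_high(x, c0, s0))
  if (length(x) == 1L) m[1, ] else m
}

#' Convert a membership triple into a linguistic label
#'
#' The active set is `A = {L : mu_L >= zeta}`. A singleton maps to its
#' label; the adjacent pairs {Low, Medium} and {Medium, High} map to the
#' combined labels Low-Medium and Medium-High. An empty active set falls
#' back to the label of the maximum membership (ties broken in the order
#' Low, Medium, High); the non-adjacent set {Low, High} and the full set
#' map to Medium, so the function is total.
#'
#' @param mu Numeric triple `(low, medium, high)`, each in \[0, 1\].
#' @param zeta Activation threshold in (0, 1].
#' @return One of [fuzzy_labels()].
#' @export
assign_label <- function(mu, zeta) {
  stopifnot(length(mu) == 3L, all(mu >= 0 & mu <= 1),
            zeta > 0, zeta <= 1)
  act <- mu >= zeta
  n <- sum(act)
  if (n == 1L) return(c("Low", "Medium", "High")[act])
  if (n == 2L && act[1] && act[2]) return("Low-Medium")
  if (n == 2L && act[2] && act[3]) return("Medium-High")
  if (n == 0L) return(c("Low", "Medium", "High")[which.max(mu)])
  "Medium"  # {Low, High} or all three
}

#' Discretize an expression matrix into linguistic labels
#'
#' Applies [assign_label()] element-wise (vectorized) over all cells.
#'
#' @param ds An [expression_dataset()].
#' @param model A [fit_membership_model()] fitted on (at least) `ds`'s
#'   features.
#' @param zeta Activation threshold in (0, 1].
#' @return A character matrix of labels with the same dimnames as
#'   `ds$values`.
#' @export
discretize <- function(ds, model, zeta) {
  stopifnot(inherits(ds, "ExpressionDataset"),
            inherits(model, "MembershipModel"),
            zeta > 0, zeta <= 1)
  miss <- setdiff(rownames(ds$values), model$feature_ids)
  if (length(miss))
    stop("model not fitted for feature(s): ",
         paste(utils::head(miss, 5), collapse = ", "))
  vals <- ds$values
  c0 <- model$center[rownames(vals)]
  s0 <- model$spread[rownames(vals)]
  fam <- model$family
  muL <- fam$mu_low(vals, c0, s0)
  muM <- fam$mu_medium(vals, c0, s0)
  muH <- fam$mu_high(vals, c0, s0)
  aL <- muL >= zeta; aM <- muM >= zeta; aH <- muH >= zeta
  n_act <- aL + aM + aH

  lab <- matrix("Medium", nrow(vals), ncol(vals), dimnames = dimnames(vals))
  lab[n_act == 1L & aL] <- "Low"
  lab[n_act == 1L & aM] <- "Medium"
  lab[n_act == 1L & aH] <- "High"
  lab[n_act == 2L & aL & aM] <- "Low-Medium"
  lab[n_act == 2L & aM & aH] <- "Medium-High"
  # empty active set: argmax with ties broken Low, Medium, High
  e <- n_act == 0L
  if (any(e)) {
    amax <- matrix("High", nrow(vals), ncol(vals))
    amax[muM >= muH] <- "Medium"
    amax[muL >= muM & muL >= muH] <- "Low"
    lab[e] <- amax[e]
  }
  lab
}

#' Discover the per-class fuzzy patterns
#'
#' For each class and each feature, the modal (most frequent) label among
#' that class's samples is found (ties broken by the fixed label order of
#' [fuzzy_labels()]); the feature enters the class's fuzzy pattern when
#' the modal-label frequency reaches `piVal`. One pattern per class is
#' always returned; empty patterns trigger a warning.
#'
#' @param labels A label matrix from [discretize()].
#' @param ds The source [expression_dataset()] (provides the class map).
#' @param piVal Minimum modal-label frequency in (0, 1].
#' @param count_constituents If `TRUE`, combined labels also count toward
#'   their constituent single labels (Low-Medium toward Low and Medium;
#'   Medium-High toward Medium and High) and the modal label is chosen
#'   among the three single labels with those boosted counts. The default
#'   counts exact label matches only.
#' @return An object of class `FuzzyPatternSet`: a named list (one entry
#'   per class, in class order) of data frames with columns `feature_id`,
#'   `label`, `frequency`, plus attributes `classes` and `piVal`.
#' @export
discover_fuzzy_patterns <- function(labels, ds, piVal,
                                    count_constituents = FALSE) {
  stopifnot(is.matrix(labels), inherits(ds, "ExpressionDataset"),
            piVal > 0, piVal <= 1,
            identical(dim(labels), dim(ds$values)))
  labs <- fuzzy_labels()
  pats <- stats::setNames(vector("list", length(ds$classes)), ds$classes)
  for (cl in ds$classes) {
    cols <- which(ds$class_of == cl)
    n_c <- length(cols)
    sub <- labels[, cols, drop = FALSE]
    counts <- vapply(labs, function(l) rowSums(sub == l),
                     numeric(nrow(sub)))
    if (nrow(sub) == 1L) counts <- matrix(counts, nrow = 1L,
                                          dimnames = list(rownames(sub), labs))
    if (count_constituents) {
      eff <- cbind(Low = counts[, "Low"] + counts[, "Low-Medium"],
                   Medium = counts[, "Medium"] + counts[, "Low-Medium"] +
                     counts[, "Medium-High"],
                   High = counts[, "High"] + counts[, "Medium-High"])
      pick <- max.col(eff, ties.method = "first")
      dom <- c("Low", "Medium", "High")[pick]
      freq <- eff[cbind(seq_len(nrow(eff)), pick)] / n_c
    } else {
      pick <- max.col(counts, ties.method = "first")
      dom <- labs[pick]
      freq <- counts[cbind(seq_len(nrow(counts)), pick)] / n_c
    }
    keep <- freq >= piVal
    pats[[cl]] <- data.frame(feature_id = rownames(labels)[keep],
                             label = dom[keep],
                             frequency = freq[keep],
                             stringsAsFactors = FALSE)
    if (!any(keep))
      warning("fuzzy pattern for class '", cl,
              "' is empty; consider lowering piVal", call. = FALSE)
  }
  structure(pats, classes = ds$classes, piVal = piVal,
            class = "FuzzyPatternSet")
}

#' @export
print.FuzzyPatternSet <- function(x, ...) {
  cat("FuzzyPatternSet (piVal =", attr(x, "piVal"), "):\n")
  for (cl in names(x))
    cat(sprintf("  %s: %d features\n", cl, nrow(x[[cl]])))
  invisible(x)
}

#' Union of all fuzzy-pattern features
#'
#' Deduplicated union over all class patterns, in first-appearance order
#' (class order, then pattern-entry order). This is the candidate feature
#' set handed to the constrained forest.
#'
#' @param patterns A [discover_fuzzy_patterns()] result.
#' @return Character vector of feature IDs.
#' @export
selected_features <- function(patterns) {
  stopifnot(inherits(patterns, "FuzzyPatternSet"), length(patterns) > 0)
  ids <- unique(unlist(lapply(patterns, `[[`, "feature_id"),
                       use.names = FALSE))
  if (!length(ids))
    stop("all fuzzy patterns are empty; lower piVal or revisit zeta")
  ids
}

#' Write a label matrix as TSV for audit
#'
#' Cells are the label strings; layout matches the expression matrix
#' (feature IDs in the first column, sample IDs in the header).
#'
#' @param labels A label matrix from [discretize()].
#' @param path Output path.
#' @export
write_label_matrix <- function(labels, path) {
  stopifnot(is.matrix(labels), is.character(labels))
  df <- data.frame(feature_id = rownames(labels), labels,
                   check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
}

#' Write fuzzy patterns as TSV (class, feature_id, label, frequency)
#'
#' @param patterns A [discover_fuzzy_patterns()] result.
#' @param path Output path.
#' @export
write_fuzzy_patterns <- function(patterns, path) {
  stopifnot(inherits(patterns, "FuzzyPatternSet"))
  rows <- do.call(rbind, lapply(names(patterns), function(cl) {
    p <- patterns[[cl]]
    if (!nrow(p)) return(NULL)
    cbind(class = cl, p)
  }))
  if (is.null(rows))
    rows <- data.frame(class = character(), feature_id = character(),
                       label = character(), frequency = numeric())
  rows$frequency <- format(rows$frequency, digits = 15,
                           scientific = FALSE, trim = TRUE)
  utils::write.table(rows, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
}

#' Read fuzzy patterns written by [write_fuzzy_patterns()]
#'
#' @param path Path to the TSV file.
#' @param classes Optional class order; defaults to first appearance.
#' @return A `FuzzyPatternSet` (its `piVal` attribute is `NA`: the
#'   threshold is a property of the discovery run, not of the file).
#' @export
read_fuzzy_patterns <- function(path, classes = NULL) {
  df <- utils::read.table(path, sep = "\t", header = TRUE,
                          check.names = FALSE,
                          colClasses = c("character", "character",
                                         "character", "numeric"))
  if (!all(c("class", "feature_id", "label", "frequency") %in% colnames(df)))
    stop("malformed fuzzy-pattern file: ", path)
  if (is.null(classes)) classes <- unique(df$class)
  pats <- stats::setNames(lapply(classes, function(cl) {
    sub <- df[df$class == cl, c("feature_id", "label", "frequency")]
    rownames(sub) <- NULL
    sub
  }), classes)
  structure(pats, classes = classes, piVal = NA_real_,
            class = "FuzzyPatternSet")
}
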