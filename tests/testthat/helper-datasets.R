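# Shared builders and brute-force oracles for the test suite.

# Minimal valid dataset: 3 genes x 4 samples, 2 classes of 2.
toy_dataset <- function() {
  m <- matrix(c(1, 2, 3, 4,
                5, 6, 7, 8,
                2, 1, 4, 3), nrow = 3, byrow = TRUE,
              dimnames = list(c("g1", "g2", "g3"),
                              c("s1", "s2", "s3", "s4")))
  expression_dataset(m, c(s1 = "A", s2 = "A", s3 = "B", s4 = "B"))
}

# Dataset from an explicit matrix and class vector; lenient about class
# sizes so tiny fixtures (single-sample classes) are easy to build.
make_ds <- function(values, classes_per_sample, min_class_size = 1L) {
  if (is.null(rownames(values)))
    rownames(values) <- sprintf("g%03d", seq_len(nrow(values)))
  if (is.null(colnames(values)))
    colnames(values) <- sprintf("s%03d", seq_len(ncol(values)))
  expression_dataset(values,
                     stats::setNames(classes_per_sample, colnames(values)),
                     min_class_size = min_class_size)
}

# Hand-built FuzzyPatternSet from a named list of feature-id vectors.
make_patterns <- function(lists, piVal = 0.5) {
  pats <- lapply(lists, function(ids)
    data.frame(feature_id = ids,
               label = rep("High", length(ids)),
               frequency = rep(1, length(ids)),
               stringsAsFactors = FALSE))
  structure(pats, classes = names(lists), piVal = piVal,
            class = "FuzzyPatternSet")
}

# Brute-force fuzzy-pattern oracle: per class and feature, count each of
# the five labels in fixed order, take the first maximum, include when
# freq >= piVal. Independent of the vectorized implementation.
fp_oracle <- function(labels, class_of, classes, piVal) {
  labs <- fuzzy_labels()
  out <- list()
  for (cl in classes) {
    cols <- which(class_of == cl)
    rows <- list()
    for (g in rownames(labels)) {
      cnt <- vapply(labs, function(l) sum(labels[g, cols] == l), 0L)
      dom <- labs[which.max(cnt)]
      freq <- max(cnt) / length(cols)
      if (freq >= piVal)
        rows[[length(rows) + 1L]] <-
          data.frame(feature_id = g, label = dom, frequency = freq,
                     stringsAsFactors = FALSE)
    }
    out[[cl]] <- if (length(rows)) do.call(rbind, rows) else
      data.frame(feature_id = character(), label = character(),
                 frequency = numeric())
    rownames(out[[cl]]) <- NULL
  }
  out
}

# Random label matrix with class assignment, for oracle comparisons.
random_label_case <- function(n_feat, n_samp, n_class) {
  labels <- matrix(sample(fuzzy_labels(), n_feat * n_samp, replace = TRUE),
                   n_feat, n_samp,
                   dimnames = list(sprintf("g%02d", seq_len(n_feat)),
                                   sprintf("s%02d", seq_len(n_samp))))
  cls <- sprintf("K%d", seq_len(n_class))
  class_of <- stats::setNames(
    sample(c(cls, cls, sample(cls, n_samp - 2 * n_class, replace = TRUE))),
    colnames(labels))
  list(labels = labels, class_of = class_of, classes = cls)
}

# A LabelMatrix-compatible ExpressionDataset shell (the values are not
# used by discover_fuzzy_patterns beyond dim/class checks).
shell_ds <- function(labels, class_of, classes) {
  vals <- matrix(seq_len(length(labels)) + 0.5, nrow(labels), ncol(labels),
                 dimnames = dimnames(labels))
  expression_dataset(vals, class_of, classes = classes,
                     min_class_size = 1L)
}

# Random confusion matrix with non-degenerate total.
random_cm <- function(k, max_count = 20L) {
  m <- matrix(sample.int(max_count + 1L, k * k, replace = TRUE) - 1L, k, k)
  if (sum(m) == 0) m[1, 1] <- 1L
  dimnames(m) <- list(true = sprintf("C%d", 1:k),
                      predicted = sprintf("C%d", 1:k))
  m
}
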