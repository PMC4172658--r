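#' Confusion matrix (rows = true class, columns = predicted class)
#'
#' @param y_true,y_pred Equal-length label vectors; every label must be in
#'   `classes`.
#' @param classes Ordered class labels.
#' @return A k x k integer matrix with dimnames `true` / `predicted`.
#' @export
confusion_matrix <- function(y_true, y_pred, classes) {
  if (length(y_true) != length(y_pred))
    stop("y_true and y_pred must have equal length")
  bad <- setdiff(unique(c(y_true, y_pred)), classes)
  if (length(bad))
    stop("label(s) not in `classes`: ", paste(bad, collapse = ", "))
  ft <- factor(y_true, levels = classes)
  fp <- factor(y_pred, levels = classes)
  m <- table(true = ft, predicted = fp)
  matrix(as.integer(m), nrow = length(classes),
         dimnames = list(true = classes, predicted = classes))
}

check_cm <- function(cm, need_k2 = TRUE) {
  if (!is.matrix(cm) || nrow(cm) != ncol(cm) || any(cm < 0))
    stop("confusion matrix must be a square non-negative matrix")
  if (need_k2 && nrow(cm) < 2)
    stop("need at least 2 classes")
}

per_class_recall <- function(cm) {
  rs <- rowSums(cm)
  r <- ifelse(rs > 0, diag(cm) / rs, 0)
  unname(r)
}

per_class_precision <- function(cm) {
  cs <- colSums(cm)
  p <- ifelse(cs > 0, diag(cm) / cs, 0)
  unname(p)
}

#' Overall accuracy
#'
#' @param cm A [confusion_matrix()].
#' @return Trace over total count.
#' @export
accuracy <- function(cm) {
  check_cm(cm, need_k2 = FALSE)
  tot <- sum(cm)
  if (tot == 0) stop("empty confusion matrix")
  sum(diag(cm)) / tot
}

#' Macro F-score
#'
#' Per class `i`, `F_i = 2 R_i P_i / (R_i + P_i)` from the class recall
#' `R_i` (diagonal over row sum) and precision `P_i` (diagonal over column
#' sum); the score is the unweighted mean of the `F_i` over the k classes.
#' Zero-denominator conventions: `R_i`, `P_i` and `F_i` are 0 whenever
#' their denominator is 0.
#'
#' @param cm A [confusion_matrix()] with k >= 2 classes.
#' @return The macro F-score in \[0, 1\].
#' @export
f_score <- function(cm) {
  check_cm(cm)
  r <- per_class_recall(cm)
  p <- per_class_precision(cm)
  f <- ifelse(r + p > 0, 2 * r * p / (r + p), 0)
  mean(f)
}

#' G-mean: geometric mean of the per-class recalls
#'
#' Zero recall in any class annihilates the score, which makes the G-mean
#' sensitive to classifiers that ignore a (small) class even when overall
#' accuracy stays high.
#'
#' @param cm A [confusion_matrix()] with k >= 2 classes.
#' @return `(prod_i R_i)^(1/k)` in \[0, 1\].
#' @export
g_mean <- function(cm) {
  check_cm(cm)
  r <- per_class_recall(cm)
  prod(r)^(1 / length(r))
}
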