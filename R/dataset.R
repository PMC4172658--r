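#' Construct a validated expression dataset
#'
#' An `ExpressionDataset` bundles a features-by-samples numeric matrix
#' (log2-scale expression) with per-sample class labels. Matrix rows are
#' features (genes), columns are samples; this orientation is fixed and is
#' never guessed from the data.
#'
#' @param values Numeric matrix, features in rows (rownames = feature IDs),
#'   samples in columns (colnames = sample IDs). All values must be finite.
#' @param class_of Named character vector mapping sample ID to class label.
#'   Every matrix column must have an entry; extra entries are dropped.
#' @param classes Optional character vector fixing the class order. Defaults
#'   to first-appearance order in `class_of`.
#' @param min_class_size Minimum number of samples required per class.
#'   The default (2) enforces the dataset invariant; internal split
#'   containers relax it to 1.
#'
#' @return An object of class `ExpressionDataset`: a list with elements
#'   `values`, `class_of` (aligned to the columns of `values`), and
#'   `classes`.
#' @export
#' @examples
#' m <- matrix(rnorm(12), 3, 4,
#'             dimnames = list(paste0("g", 1:3), paste0("s", 1:4)))
#' ds <- expression_dataset(m, c(s1 = "A", s2 = "A", s3 = "B", s4 = "B"))
#' ds$classes
expression_dataset <- function(values, class_of, classes = NULL,
                               min_class_size = 2L) {
  if (!is.matrix(values) || !is.numeric(values))
    stop("`values` must be a numeric matrix (features x samples)")
  if (is.null(rownames(values)) || is.null(colnames(values)))
    stop("`values` must carry feature IDs as rownames and sample IDs as colnames")
  if (anyDuplicated(rownames(values)))
    stop("duplicate feature IDs: ",
         paste(unique(rownames(values)[duplicated(rownames(values))]),
               collapse = ", "))
  if (anyDuplicated(colnames(values)))
    stop("duplicate sample IDs: ",
         paste(unique(colnames(values)[duplicated(colnames(values))]),
               collapse = ", "))
  if (any(!is.finite(values)))
    stop("expression values must all be finite (no NA/NaN/Inf)")
  if (is.null(names(class_of)))
    stop("`class_of` must be a named vector (names = sample IDs)")
  missing_ann <- setdiff(colnames(values), names(class_of))
  if (length(missing_ann))
    stop("sample(s) missing from the annotation: ",
         paste(missing_ann, collapse = ", "))
  if (is.null(classes)) classes <- unique(unname(class_of))
  class_of <- class_of[colnames(values)]
  stray <- setdiff(unique(class_of), classes)
  if (length(stray))
    stop("class label(s) not in `classes`: ", paste(stray, collapse = ", "))
  if (min_class_size >= 2L) {
    # full-dataset contract; split containers (min_class_size = 1) keep
    # the parent's class universe and may hold few or no samples of a class
    classes <- classes[classes %in% class_of]
    if (length(classes) < 2)
      stop("need at least 2 classes, got ", length(classes))
    sizes <- table(factor(class_of, levels = classes))
    small <- names(sizes)[sizes < min_class_size]
    if (length(small))
      stop("class(es) with fewer than ", min_class_size, " samples: ",
           paste(small, collapse = ", "))
  }
  structure(list(values = values,
                 class_of = class_of,
                 classes = classes),
            class = "ExpressionDataset")
}

#' @export
print.ExpressionDataset <- function(x, ...) {
  sizes <- table(factor(x$class_of, levels = x$classes))
  cat("ExpressionDataset:", nrow(x$values), "features x",
      ncol(x$values), "samples\n")
  cat("classes:", paste(sprintf("%s (%d)", names(sizes), sizes),
                        collapse = ", "), "\n")
  invisible(x)
}

#' @export
dim.ExpressionDataset <- function(x) dim(x$values)

# Restrict a dataset to a subset of features, preserving order of `ids`.
subset_features <- function(ds, ids) {
  missing <- setdiff(ids, rownames(ds$values))
  if (length(missing))
    stop("feature(s) not in dataset: ", paste(missing, collapse = ", "))
  expression_dataset(ds$values[ids, , drop = FALSE], ds$class_of,
                     classes = ds$classes, min_class_size = 1L)
}

# Restrict a dataset to a subset of samples (split containers may hold a
# single sample of some class, so the >=2 invariant is relaxed here).
subset_samples <- function(ds, ids) {
  missing <- setdiff(ids, colnames(ds$values))
  if (length(missing))
    stop("sample(s) not in dataset: ", paste(missing, collapse = ", "))
  expression_dataset(ds$values[, ids, drop = FALSE], ds$class_of[ids],
                     classes = ds$classes, min_class_size = 1L)
}

class_sizes <- function(ds) {
  tab <- table(factor(ds$class_of, levels = ds$classes))
  stats::setNames(as.integer(tab), names(tab))
}

guess_sep <- function(path) {
  if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
}

#' Read an expression matrix and its sample annotation
#'
#' The matrix file is TSV or CSV (by extension) with feature IDs in the
#' first column and sample IDs in the header. The annotation file is a
#' two-column table with a header naming the columns `sample_id` and
#' `class`. Class order is the first-appearance order in the annotation
#' file; matrix column order is preserved.
#'
#' @param path Path to the expression matrix file.
#' @param annotation_path Path to the sample annotation file.
#' @return An [expression_dataset()].
#' @export
read_expression_matrix <- function(path, annotation_path) {
  sep <- guess_sep(path)
  raw <- utils::read.table(path, sep = sep, header = TRUE,
                           check.names = FALSE, colClasses = "character",
                           quote = "\"", comment.char = "")
  if (ncol(raw) < 2) stop("matrix file has no sample columns: ", path)
  feature_ids <- raw[[1]]
  if (anyDuplicated(feature_ids))
    stop("duplicate feature ID(s) in ", path, ": ",
         paste(unique(feature_ids[duplicated(feature_ids)]), collapse = ", "))
  sample_ids <- colnames(raw)[-1]
  vals <- suppressWarnings(
    vapply(raw[-1], as.numeric, numeric(nrow(raw))))
  if (nrow(raw) == 1L) vals <- matrix(vals, nrow = 1L)
  bad <- which(is.na(vals), arr.ind = TRUE)
  if (nrow(bad))
    stop(sprintf("malformed numeric value at feature '%s', sample '%s' in %s",
                 feature_ids[bad[1, 1]], sample_ids[bad[1, 2]], path))
  dimnames(vals) <- list(feature_ids, sample_ids)

  ann <- utils::read.table(annotation_path, sep = guess_sep(annotation_path),
                           header = TRUE, check.names = FALSE,
                           colClasses = "character")
  if (!all(c("sample_id", "class") %in% colnames(ann)))
    stop("annotation must have columns 'sample_id' and 'class': ",
         annotation_path)
  class_of <- stats::setNames(ann$class, ann$sample_id)
  classes <- unique(ann$class)
  expression_dataset(vals, class_of, classes = classes)
}

#' Drop features with low variability across samples
#'
#' Keeps the features whose across-sample standard deviation is strictly
#' greater than `min_sd`, preserving feature order. With the default
#' `min_sd = 0` only constant features are removed, which is the minimal
#' pre-filter the fuzzy membership fit requires (it needs sd > 0 per gene).
#'
#' @param ds An [expression_dataset()].
#' @param min_sd Non-negative standard-deviation threshold.
#' @return The filtered `ExpressionDataset`.
#' @export
filter_low_variance <- function(ds, min_sd = 0) {
  stopifnot(inherits(ds, "ExpressionDataset"))
  if (!is.numeric(min_sd) || length(min_sd) != 1L || min_sd < 0)
    stop("`min_sd` must be a single non-negative number")
  sds <- row_sds(ds$values)
  keep <- rownames(ds$values)[sds > min_sd]
  if (!length(keep))
    stop("filter_low_variance removed every feature (min_sd = ", min_sd, ")")
  subset_features(ds, keep)
}

# Across-sample sd per matrix row (sample sd, denominator n - 1).
row_sds <- function(m) {
  n <- ncol(m)
  mu <- rowMeans(m)
  sqrt(rowSums((m - mu)^2) / (n - 1))
}

#' Write a ranked feature list as TSV
#'
#' @param ranked A ranked feature list as returned by [rank_features()]:
#'   a data frame with columns `rank`, `feature_id`, `importance`.
#' @param path Output path.
#' @export
write_ranked_list <- function(ranked, path) {
  stopifnot(is.data.frame(ranked), nrow(ranked) > 0,
            all(c("rank", "feature_id", "importance") %in% colnames(ranked)))
  out <- data.frame(rank = ranked$rank,
                    feature_id = ranked$feature_id,
                    importance = format(ranked$importance, digits = 15,
                                        scientific = FALSE, trim = TRUE))
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
}

#' Read a ranked feature list written by [write_ranked_list()]
#'
#' @param path Path to the TSV file.
#' @return Data frame with columns `rank`, `feature_id`, `importance`.
#' @export
read_ranked_list <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = TRUE,
                          check.names = FALSE,
                          colClasses = c("integer", "character", "numeric"))
  structure(df, class = c("RankedFeatureList", "data.frame"))
}

#' Write an expression dataset as matrix + annotation TSV files
#'
#' @param ds An [expression_dataset()].
#' @param matrix_path Output path for the expression matrix.
#' @param annotation_path Output path for the sample annotation.
#' @export
write_expression_matrix <- function(ds, matrix_path, annotation_path) {
  stopifnot(inherits(ds, "ExpressionDataset"))
  vals <- ds$values
  df <- data.frame(feature_id = rownames(vals),
                   apply(vals, 2, format, digits = 15, scientific = FALSE,
                         trim = TRUE),
                   check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(df, matrix_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  ann <- data.frame(sample_id = colnames(vals),
                    class = unname(ds$class_of))
  utils::write.table(ann, annotation_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
}
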