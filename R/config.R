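#' Configuration for the fuzzy-pattern random-forest pipeline
#'
#' Collects and validates every tunable parameter of the pipeline.
#'
#' @param zeta Activation threshold in (0, 1] applied to membership values
#'   when converting them into linguistic labels. Must exceed 0.5 for the
#'   singleton "Medium" label to be reachable with the default membership
#'   family (the Low/High sigmoids cross 1/2 exactly at the gene center);
#'   values in (0, 0.5] are accepted but produce only combined labels.
#' @param piVal Minimum fraction in (0, 1] of a class's samples that must
#'   share a gene's modal label for the gene to enter that class's fuzzy
#'   pattern. Larger values give smaller patterns.
#' @param ntree Number of trees in the constrained forest (and in the
#'   post-selection evaluation forests).
#' @param train_fraction Fraction of each class assigned to the training
#'   split by the stratified bootstrap harness.
#' @param n_boot Number of bootstrap iterations of the evaluation harness.
#' @param cut_points Strictly increasing positive integers at which ranked
#'   lists are truncated during evaluation.
#' @param seed Integer master seed; every random stage derives its own seed
#'   from it.
#' @param min_sd Low-variance pre-filter threshold (see
#'   [filter_low_variance()]).
#' @param alpha_split Significance level for the Bonferroni-adjusted
#'   association test that gates node splitting.
#' @param min_node Minimum node size eligible for splitting.
#' @param sc_alpha Family-wise significance level of the self-consistency
#'   (stability) test.
#' @param count_constituents If `TRUE`, combined labels (Low-Medium,
#'   Medium-High) also count toward the frequency of their constituent
#'   single labels during fuzzy-pattern counting; the default counts exact
#'   label matches only.
#'
#' @return A validated list of class `fp_config`.
#' @export
fp_config <- function(zeta = 0.6,
                      piVal = 0.45,
                      ntree = 1000L,
                      train_fraction = 0.7,
                      n_boot = 30L,
                      cut_points = c(2L, 3L, 4L, 5L, 10L, 20L, 30L, 50L,
                                     100L, 150L, 200L, 250L),
                      seed = NULL,
                      min_sd = 0,
                      alpha_split = 0.05,
                      min_node = 5L,
                      sc_alpha = 0.01,
                      count_constituents = FALSE) {
  chk_num <- function(x, nm, lo, hi, lo_open = TRUE, hi_open = FALSE) {
    if (!is.numeric(x) || length(x) != 1L || is.na(x) ||
        (if (lo_open) x <= lo else x < lo) ||
        (if (hi_open) x >= hi else x > hi))
      stop(sprintf("`%s` must be a single number in %s%s, %s%s",
                   nm, if (lo_open) "(" else "[", lo, hi,
                   if (hi_open) ")" else "]"))
  }
  chk_num(zeta, "zeta", 0, 1)
  chk_num(piVal, "piVal", 0, 1)
  chk_num(train_fraction, "train_fraction", 0, 1, hi_open = TRUE)
  chk_num(alpha_split, "alpha_split", 0, 1)
  chk_num(sc_alpha, "sc_alpha", 0, 1)
  if (!is.numeric(ntree) || length(ntree) != 1L || ntree < 1)
    stop("`ntree` must be a positive integer")
  if (!is.numeric(n_boot) || length(n_boot) != 1L || n_boot < 1)
    stop("`n_boot` must be a positive integer")
  if (!is.numeric(min_node) || length(min_node) != 1L || min_node < 2)
    stop("`min_node` must be an integer >= 2")
  if (!is.numeric(min_sd) || length(min_sd) != 1L || min_sd < 0)
    stop("`min_sd` must be non-negative")
  if (!is.numeric(cut_points) || length(cut_points) < 1L ||
      any(cut_points < 1) || any(diff(cut_points) <= 0))
    stop("`cut_points` must be strictly increasing positive integers")
  if (!is.null(seed) && (!is.numeric(seed) || length(seed) != 1L))
    stop("`seed` must be a single integer (or NULL)")
  structure(list(zeta = zeta, piVal = piVal, ntree = as.integer(ntree),
                 train_fraction = train_fraction,
                 n_boot = as.integer(n_boot),
                 cut_points = as.integer(cut_points),
                 seed = if (is.null(seed)) NULL else as.integer(seed),
                 min_sd = min_sd, alpha_split = alpha_split,
                 min_node = as.integer(min_node), sc_alpha = sc_alpha,
                 count_constituents = isTRUE(count_constituents)),
            class = "fp_config")
}

#' Read a pipeline configuration from a YAML file
#'
#' Fields in the file override the package defaults; arguments passed via
#' `...` (for example command-line flags) override the file in turn.
#'
#' @param path Path to a YAML file whose keys mirror [fp_config()]
#'   arguments, or `NULL` for defaults only.
#' @param ... Overrides applied after the file.
#' @return A validated `fp_config`.
#' @export
read_fp_config <- function(path = NULL, ...) {
  vals <- list()
  if (!is.null(path)) {
    vals <- yaml::read_yaml(path)
    unknown <- setdiff(names(vals), names(formals(fp_config)))
    if (length(unknown))
      stop("unknown config field(s) in ", path, ": ",
           paste(unknown, collapse = ", "))
  }
  overrides <- list(...)
  overrides <- overrides[!vapply(overrides, is.null, logical(1))]
  vals[names(overrides)] <- overrides
  do.call(fp_config, vals)
}

# Deterministically derive `n` sub-seeds from a master seed. Used so every
# random stage (split, selection, forest, permutation) has its own stream.
derive_seeds <- function(seed, n) {
  stopifnot(is.numeric(seed), length(seed) == 1L)
  old <- get0(".Random.seed", envir = globalenv())
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(as.integer(seed) %% .Machine$integer.max)
  sample.int(.Machine$integer.max - 1L, n)
}
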