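#' Specification for a synthetic multi-class expression dataset
#'
#' Describes a Gaussian-background log2-scale expression matrix with
#' class-specific mean-shifted (planted) features, emulating the structure
#' of an RMA-preprocessed multi-class microarray study.
#'
#' @param n_classes Number of classes (>= 2).
#' @param samples_per_class Integer vector of class sizes (length
#'   `n_classes`; imbalance allowed).
#' @param n_features Total feature count.
#' @param informative_per_class Planted features per class;
#'   `informative_per_class * n_classes <= n_features`.
#' @param effect_size Mean shift of planted features in units of the
#'   background sd (`delta >= 0`).
#' @param mu0,sigma0 Background mean and sd on the log2 scale.
#' @param direction `"up"`, `"down"`, or a vector (recycled over planted
#'   features) of shift directions.
#' @param seed Integer seed; generation is fully deterministic given it.
#' @return A validated list of class `SyntheticSpec`.
#' @export
synthetic_spec <- function(n_classes, samples_per_class, n_features,
                           informative_per_class, effect_size,
                           mu0 = 7, sigma0 = 1, direction = "up", seed) {
  stopifnot(n_classes >= 2,
            length(samples_per_class) == n_classes,
            all(samples_per_class >= 2),
            n_features >= 1, informative_per_class >= 0,
            informative_per_class * n_classes <= n_features,
            effect_size >= 0, sigma0 > 0,
            all(direction %in% c("up", "down")),
            is.numeric(seed), length(seed) == 1L)
  structure(list(n_classes = as.integer(n_classes),
                 samples_per_class = as.integer(samples_per_class),
                 n_features = as.integer(n_features),
                 informative_per_class = as.integer(informative_per_class),
                 effect_size = effect_size, mu0 = mu0, sigma0 = sigma0,
                 direction = direction, seed = as.integer(seed)),
            class = "SyntheticSpec")
}

#' Generate a synthetic dataset with planted class-specific features
#'
#' Background cells are `Normal(mu0, sigma0^2)`. For each class, a
#' disjoint set of `informative_per_class` planted features is shifted by
#' `+/- effect_size * sigma0` in that class's samples only. Planted
#' feature positions are drawn (seeded) from the whole feature range.
#'
#' @param spec A [synthetic_spec()].
#' @return List with `dataset` (an [expression_dataset()]) and `truth`,
#'   the ground truth: a named list (per class) of data frames with
#'   columns `feature_id`, `direction`.
#' @export
generate_dataset <- function(spec) {
  stopifnot(inherits(spec, "SyntheticSpec"))
  old <- get0(".Random.seed", envir = globalenv())
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(spec$seed)
  N <- sum(spec$samples_per_class)
  G <- spec$n_features
  feature_ids <- sprintf("g%05d", seq_len(G))
  sample_ids <- sprintf("s%04d", seq_len(N))
  classes <- sprintf("C%d", seq_len(spec$n_classes))
  class_of <- stats::setNames(rep(classes, spec$samples_per_class),
                              sample_ids)
  vals <- matrix(stats::rnorm(G * N, spec$mu0, spec$sigma0), G, N,
                 dimnames = list(feature_ids, sample_ids))
  n_planted <- spec$informative_per_class * spec$n_classes
  truth <- stats::setNames(vector("list", spec$n_classes), classes)
  if (n_planted > 0) {
    planted <- sample.int(G, n_planted)
    dirs <- rep(spec$direction, length.out = n_planted)
    for (ci in seq_len(spec$n_classes)) {
      rows <- planted[seq_len(spec$informative_per_class) +
                        (ci - 1L) * spec$informative_per_class]
      dci <- dirs[seq_len(spec$informative_per_class) +
                    (ci - 1L) * spec$informative_per_class]
      cols <- which(class_of == classes[ci])
      shift <- ifelse(dci == "up", 1, -1) * spec$effect_size * spec$sigma0
      vals[rows, cols] <- vals[rows, cols] + shift
      truth[[classes[ci]]] <- data.frame(feature_id = feature_ids[rows],
                                         direction = dci,
                                         stringsAsFactors = FALSE)
    }
  } else {
    for (ci in seq_len(spec$n_classes))
      truth[[classes[ci]]] <- data.frame(feature_id = character(),
                                         direction = character())
  }
  list(dataset = expression_dataset(vals, class_of, classes = classes),
       truth = truth)
}

# All planted feature IDs of a ground truth, in class order.
planted_features <- function(truth) {
  unique(unlist(lapply(truth, `[[`, "feature_id"), use.names = FALSE))
}

#' The fixed standard benchmark dataset
#'
#' 4 balanced classes of 30 samples, 2 000 features, 10 planted features
#' per class at effect size 2 background sd, background `Normal(7, 1)` on
#' the log2 scale, fixed seed. Two calls return bit-identical data.
#'
#' @return As [generate_dataset()].
#' @export
standard_benchmark <- function() {
  generate_dataset(synthetic_spec(
    n_classes = 4, samples_per_class = rep(30L, 4), n_features = 2000L,
    informative_per_class = 10L, effect_size = 2.0, mu0 = 7, sigma0 = 1,
    seed = 20140923L))
}

#' The fixed imbalanced benchmark dataset
#'
#' 5 classes with sizes 60, 40, 20, 10 and 6; otherwise as
#' [standard_benchmark()]. Exercises the accuracy-versus-G-mean
#' diagnostic for classifiers that ignore small classes.
#'
#' @return As [generate_dataset()].
#' @export
imbalanced_benchmark <- function() {
  generate_dataset(synthetic_spec(
    n_classes = 5, samples_per_class = c(60L, 40L, 20L, 10L, 6L),
    n_features = 2000L, informative_per_class = 10L, effect_size = 2.0,
    mu0 = 7, sigma0 = 1, seed = 20140924L))
}

#' Write a ground truth as TSV (class, feature_id, direction)
#'
#' @param truth Ground truth from [generate_dataset()].
#' @param path Output path.
#' @export
write_ground_truth <- function(truth, path) {
  rows <- do.call(rbind, lapply(names(truth), function(cl) {
    t <- truth[[cl]]
    if (!nrow(t)) return(NULL)
    cbind(class = cl, t)
  }))
  if (is.null(rows))
    rows <- data.frame(class = character(), feature_id = character(),
                       direction = character())
  utils::write.table(rows, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
}
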