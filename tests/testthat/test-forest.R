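# Separable 2-class toy: one informative feature (f_sig), optional noise.
separable_ds <- function(n_per_class = 10, noise = 0, seed = 1) {
  set.seed(seed)
  n <- 2 * n_per_class
  sig <- c(rnorm(n_per_class, 0, 0.3), rnorm(n_per_class, 5, 0.3))
  vals <- rbind(f_sig = sig)
  if (noise > 0)
    vals <- rbind(vals,
                  matrix(rnorm(noise * n), noise, n,
                         dimnames = list(sprintf("n%02d", seq_len(noise)),
                                         NULL)))
  make_ds(vals, rep(c("A", "B"), each = n_per_class))
}

test_that("candidate drawing picks one feature per pattern, deduplicated", {
  pats <- make_patterns(list(A = "g1", B = "g2", C = "g3"))
  set.seed(2)
  for (i in 1:20)
    expect_setequal(draw_node_candidates(pats), c("g1", "g2", "g3"))
  shared <- make_patterns(list(A = "g1", B = "g1"))
  expect_identical(draw_node_candidates(shared), "g1")
  sub <- make_patterns(list(A = c("g1", "g2"), B = c("g2", "g3", "g4")))
  for (i in 1:50)
    expect_true(all(draw_node_candidates(sub) %in%
                      c("g1", "g2", "g3", "g4")))
  empty <- make_patterns(list(A = character(0)))
  expect_error(draw_node_candidates(empty), "empty")
})

test_that("within-pattern sampling is uniform (multinomial check)", {
  pats <- make_patterns(list(A = c("g1", "g2", "g3", "g4")))
  set.seed(3)
  draws <- replicate(4000, draw_node_candidates(pats))
  counts <- table(factor(draws, levels = c("g1", "g2", "g3", "g4")))
  expect_gt(chisq.test(counts)$p.value, 0.001)
  sigma <- sqrt(4000 * 0.25 * 0.75)
  expect_true(all(abs(counts - 1000) < 3 * sigma))
})

test_that("pure nodes and separable features produce the expected trees", {
  # all samples one class -> immediate leaf
  set.seed(4)
  ds_pure <- make_ds(rbind(g1 = rnorm(7), g2 = rnorm(7)),
                     c("A", "A", "A", "A", "A", "B", "B"))
  pure <- fprf:::subset_samples(ds_pure, sprintf("s%03d", 1:5))
  tr <- grow_tree(pure, make_patterns(list(A = c("g1", "g2"))))
  expect_true(is.na(tr$var_idx[1]))
  expect_identical(length(tr$var_idx), 1L)

  # one perfectly separating feature -> one split, two pure leaves
  ds <- separable_ds(10)
  set.seed(5)
  tr2 <- grow_tree(ds, make_patterns(list(A = "f_sig", B = "f_sig")))
  expect_identical(sum(!is.na(tr2$var_idx)), 1L)
  expect_identical(tr2$feature_ids[tr2$var_idx[1]], "f_sig")
  x <- ds$values["f_sig", ]
  cls <- ds$class_of
  expect_gt(tr2$thr[1], max(x[cls == "A"]))
  expect_lt(tr2$thr[1], min(x[cls == "B"]))
  kids <- c(tr2$left[1], tr2$right[1])
  for (k in kids) expect_identical(sum(tr2$counts[, k] > 0), 1L)
})

test_that("split choice matches an exhaustive aov + chi-square scan", {
  # 20-sample, 3-feature node; singleton patterns make candidates
  # deterministic, so only the split choice is under test
  set.seed(6)
  for (rep in 1:5) {
    y <- rep(c("A", "B"), each = 10)
    vals <- rbind(f1 = rnorm(20, ifelse(y == "A", 0, 0.8)),
                  f2 = rnorm(20, ifelse(y == "A", 0, 1.2)),
                  f3 = rnorm(20))
    ds <- make_ds(vals, y)
    pats <- make_patterns(list(A = "f1", B = "f2", C = "f3"))
    tr <- grow_tree(ds, pats, alpha_split = 1, min_node = 20)
    # oracle: smallest one-way ANOVA p-value via stats::aov
    pv <- apply(vals, 1, function(x)
      summary(stats::aov(x ~ factor(y)))[[1]][["Pr(>F)"]][1])
    expect_identical(tr$feature_ids[tr$var_idx[1]],
                     names(which.min(pv)))
    # oracle: threshold maximizing the 2xk chi-square over midpoints
    xb <- vals[which.min(pv), ]
    xs <- sort(unique(xb))
    mids <- (xs[-1] + xs[-length(xs)]) / 2
    stat <- vapply(mids, function(t) {
      tab <- table(xb <= t, y)
      suppressWarnings(stats::chisq.test(tab, correct = FALSE)$statistic)
    }, numeric(1))
    expect_equal(tr$thr[1], mids[which.max(stat)], tolerance = 1e-12)
  }
})

test_that("forest fitting is bootstrap-correct and seed-deterministic", {
  ds <- separable_ds(10, noise = 3)
  pats <- make_patterns(list(A = c("f_sig", "n01"), B = c("n02", "n03")))
  cfg <- fp_config(ntree = 25, seed = 9)
  fo <- fit_fp_forest(ds, pats, cfg)
  expect_length(fo$trees, 25L)
  for (b in seq_len(25)) {
    expect_length(fo$inbag[[b]], ncol(ds$values))
    expect_setequal(fo$oob[[b]],
                    setdiff(seq_len(ncol(ds$values)), fo$inbag[[b]]))
  }
  fo2 <- fit_fp_forest(ds, pats, cfg)
  expect_identical(fo$trees, fo2$trees)
  expect_identical(predict(fo, ds), predict(fo2, ds))
  # ntree = 1 edge
  fo1 <- fit_fp_forest(ds, pats, fp_config(ntree = 1, seed = 10))
  expect_length(fo1$trees, 1L)
})

test_that("out-of-bag fraction matches the bootstrap expectation", {
  N <- 100
  set.seed(20)
  ds <- make_ds(matrix(rnorm(5 * N), 5, N), rep(c("A", "B"), each = N / 2))
  pats <- make_patterns(list(A = rownames(ds$values)[1:2],
                             B = rownames(ds$values)[3:5]))
  fo <- fit_fp_forest(ds, pats, fp_config(ntree = 200, seed = 21))
  fr <- vapply(fo$oob, length, integer(1)) / N
  expected <- (1 - 1 / N)^N
  se <- sd(fr) / sqrt(length(fr))
  expect_lt(abs(mean(fr) - expected), 3 * se + 1e-9)
})

test_that("prediction is order-equivariant and exact on separable data", {
  gen <- generate_dataset(synthetic_spec(2, c(15, 15), 40, 4, 3, seed = 31))
  sel <- fprf_select(gen$dataset, fp_config(seed = 1))
  fo <- fit_fp_forest(sel$dataset, sel$patterns,
                      fp_config(ntree = 100, seed = 32))
  pred <- predict(fo, sel$dataset)
  expect_equal(unname(mean(pred == gen$dataset$class_of)), 1.0)
  perm <- sample(colnames(sel$dataset$values))
  pred_perm <- predict(fo, sel$dataset$values[, perm])
  expect_identical(pred_perm, pred[perm])
  # missing feature column is a named error
  used <- fo$feature_ids[unique(unlist(lapply(fo$trees, function(t)
    t$var_idx[!is.na(t$var_idx)])))]
  dropped <- sel$dataset$values[setdiff(rownames(sel$dataset$values),
                                        used[1]), ]
  expect_error(predict(fo, dropped), used[1], fixed = TRUE)
})

test_that("features unused by every tree have importance exactly zero", {
  ds <- separable_ds(10, noise = 5)
  pats <- make_patterns(list(A = c("f_sig", "n01", "n02"),
                             B = c("n03", "n04", "n05")))
  fo <- fit_fp_forest(ds, pats, fp_config(ntree = 40, seed = 41))
  imp <- permutation_importance(fo, ds, seed = 42)
  used <- fo$feature_ids[unique(unlist(lapply(fo$trees, function(t)
    t$var_idx[!is.na(t$var_idx)])))]
  unused <- setdiff(names(imp), used)
  expect_true(length(unused) > 0)
  expect_identical(unname(imp[unused]), rep(0, length(unused)))
  expect_gt(imp[["f_sig"]], 0)
})

test_that("a planted feature outranks 50 noise features almost surely", {
  hits <- 0L
  for (r in 1:100) {
    set.seed(5000 + r)
    n <- 50
    vals <- matrix(rnorm(51 * n, 7, 1), 51, n)
    vals[26, 26:50] <- vals[26, 26:50] + 2.5   # the one informative feature
    ds <- make_ds(vals, rep(c("A", "B"), each = 25))
    planted_id <- rownames(ds$values)[26]
    ids <- rownames(ds$values)
    pats <- make_patterns(list(A = ids, B = ids))
    fo <- fit_fp_forest(ds, pats, fp_config(seed = 6000 + r))
    imp <- permutation_importance(fo, ds, seed = 7000 + r)
    if (rank_features(imp)$feature_id[1] == planted_id) hits <- hits + 1L
  }
  expect_gte(hits, 95L)
})

test_that("every split feature belongs to some fuzzy pattern", {
  gen <- generate_dataset(synthetic_spec(3, c(12, 12, 12), 300, 5, 2,
                                         seed = 51))
  sel <- fprf_select(gen$dataset, fp_config(seed = 1))
  fo <- fit_fp_forest(sel$dataset, sel$patterns,
                      fp_config(ntree = 50, seed = 52))
  union <- selected_features(sel$patterns)
  for (t in fo$trees) {
    vars <- fo$feature_ids[t$var_idx[!is.na(t$var_idx)]]
    expect_true(all(vars %in% union))
  }
})

test_that("variable selection is unbiased w.r.t. value cardinality", {
  # pure noise; one candidate takes 2 distinct values, the other 32;
  # alpha_split = 1 forces a root split so the choice is observable
  set.seed(61)
  picks <- character(500)
  for (r in 1:500) {
    n <- 32
    vals <- rbind(coarse = sample(c(0, 1), n, replace = TRUE),
                  fine = rnorm(n))
    ds <- make_ds(vals, rep(c("A", "B"), each = n / 2))
    tr <- grow_tree(ds, make_patterns(list(A = "coarse", B = "fine")),
                    alpha_split = 1, min_node = n)
    picks[r] <- if (is.na(tr$var_idx[1])) NA_character_ else
      tr$feature_ids[tr$var_idx[1]]
  }
  picks <- picks[!is.na(picks)]
  n_coarse <- sum(picks == "coarse")
  expect_gt(binom.test(n_coarse, length(picks), 0.5)$p.value, 0.001)
})

test_that("ranking sorts by importance with lexicographic tie-break", {
  expect_identical(rank_features(c(a = 0.1, b = 0.3))$feature_id,
                   c("b", "a"))
  tied <- rank_features(c(z = 0.2, a = 0.2, m = 0.2))
  expect_identical(tied$feature_id, c("a", "m", "z"))
  imp <- c(q = 0.5, a = -0.1, z = 0)
  expect_setequal(rank_features(imp)$feature_id, names(imp))
})

test_that("top_n truncates, caps with a warning, and is the identity at len", {
  ranked <- rank_features(c(a = 5, b = 4, c = 3, d = 2, e = 1))
  expect_identical(top_n(ranked, 2), c("a", "b"))
  expect_warning(all5 <- top_n(ranked, 10), "exceeds")
  expect_identical(all5, ranked$feature_id)
  expect_identical(top_n(ranked, 5), ranked$feature_id)
})

test_that("forest JSON serialization round trips predictions exactly", {
  ds <- separable_ds(8, noise = 4)
  pats <- make_patterns(list(A = c("f_sig", "n01"), B = c("n02", "n03")))
  fo <- fit_fp_forest(ds, pats, fp_config(ntree = 15, seed = 71))
  path <- withr::local_tempfile(fileext = ".json")
  write_fp_forest(fo, path)
  back <- read_fp_forest(path)
  expect_identical(predict(back, ds), predict(fo, ds))
  expect_identical(back$feature_ids, fo$feature_ids)
  expect_equal(back$trees, fo$trees)
})
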