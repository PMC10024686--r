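# Label schemes, repeated-holdout CV, RFE, importances, kappa and
# precision/recall.

make_separable_table <- function(n = 40, k = 2, seed = 1) {
  set.seed(seed)
  score <- rep_len(seq_len(k) - 1L, n)
  tab <- data.frame(cow_id = sprintf("c%02d", 1:n))
  tab$back_rmse_median <- score + rnorm(n, 0, 0.01)
  tab$area_total_mean <- 2 * score + rnorm(n, 0, 0.01)
  tab$consolidated <- score
  tab
}

test_that("label schemes map the mobility scale exactly", {
  s <- 0:3
  expect_equal(make_labels(s, "all_classes"), 0:3)
  expect_equal(make_labels(s, "sound_vs_lame"), c(0L, 1L, 1L, 1L))
  expect_equal(make_labels(s, "clear_lame"), c(0L, 0L, 1L, 1L))
  expect_equal(make_labels(s, "severe_lame"), c(0L, 0L, 0L, 1L))
  expect_equal(make_labels(2L, "clear_lame"), 1L)   # impaired = clearly lame
  for (sch in label_schemes()) expect_equal(make_labels(0L, sch), 0L)
  expect_error(make_labels(4L, "all_classes"), "0..3")
})

test_that("each fold holds out the configured fraction", {
  tab <- make_separable_table(n = 10)
  rep_ <- threefold_cv(tab, tab$consolidated, cv_config(seed = 1))
  expect_equal(rep_$folds$n_test, rep(2L, 3))
  expect_length(rep_$splits, 3)
})

test_that("a separable problem is classified perfectly", {
  tab <- make_separable_table(n = 40)
  rep_ <- threefold_cv(tab, tab$consolidated, cv_config(seed = 2))
  expect_equal(rep_$accuracy_mean, 1)
  expect_equal(rep_$accuracy_sd, 0)
  expect_true(all(diag(rep_$confusion) == rowSums(rep_$confusion)))
})

test_that("cross-validation is reproducible and truly re-shuffled", {
  tab <- make_separable_table(n = 60, k = 4)
  a <- threefold_cv(tab, tab$consolidated, cv_config(seed = 7))
  b <- threefold_cv(tab, tab$consolidated, cv_config(seed = 7))
  expect_identical(a, b)
  # independent re-draws: the three holdout sets differ
  expect_false(identical(a$splits[[1]], a$splits[[2]]))
  expect_false(identical(a$splits[[2]], a$splits[[3]]))
  # stratified: every holdout has all 4 classes at 20%
  for (s in a$splits) {
    expect_equal(length(s), 12L)
    expect_setequal(unique(tab$consolidated[s]), 0:3)
  }
  c_ <- threefold_cv(tab, tab$consolidated, cv_config(seed = 8))
  expect_false(identical(a$splits, c_$splits))
})

test_that("strict k-fold partitions are disjoint and exhaustive", {
  tab <- make_separable_table(n = 30)
  rep_ <- threefold_cv(tab, tab$consolidated,
                       cv_config(seed = 3, strict_kfold = TRUE))
  all_idx <- sort(unlist(rep_$splits))
  expect_equal(all_idx, 1:30)
})

test_that("degenerate label inputs are contract errors", {
  tab <- make_separable_table(n = 20)
  expect_error(threefold_cv(tab, rep(1L, 20), cv_config()), "single class")
  expect_error(threefold_cv(tab[1:5, ], tab$consolidated[1:5], cv_config()),
               "10 rows")
})

test_that("importances normalize, sort and accumulate to 1", {
  imp <- feature_importances(c(a = 3, b = 1, c = 0))
  expect_equal(imp$feature, c("a", "b", "c"))
  expect_equal(imp$normalized, c(0.75, 0.25, 0))
  expect_equal(imp$cumulative, c(0.75, 1, 1))
  expect_false(attr(imp, "degenerate"))

  one <- feature_importances(c(only = 5))
  expect_equal(one$normalized, 1)

  degen <- feature_importances(c(a = 0, b = 0))
  expect_true(attr(degen, "degenerate"))
  expect_equal(degen$normalized, c(0.5, 0.5))
})

test_that("Cohen's kappa matches hand and reference computations", {
  expect_equal(cohens_kappa(diag(5, 2))$kappa, 1)
  k <- cohens_kappa(matrix(c(45, 5, 5, 45), 2, 2))
  expect_equal(k$kappa, 0.8, tolerance = 1e-12)
  expect_equal(k$ase, 0.06, tolerance = 1e-9)
  expect_equal(k$ci_low, 0.8 - 1.96 * 0.06, tolerance = 1e-9)
  expect_equal(k$ci_high, 0.8 + 1.96 * 0.06, tolerance = 1e-9)
  expect_equal(cohens_kappa(matrix(25, 2, 2))$kappa, 0)

  # cross-implementation check against e1071 on random matrices
  set.seed(14)
  for (i in 1:100) {
    d <- sample(2:4, 1)
    cm <- matrix(rpois(d * d, 8) + 1, d, d)
    expect_equal(cohens_kappa(cm)$kappa,
                 e1071::classAgreement(cm)$kappa, tolerance = 1e-10)
  }

  expect_warning(k1 <- cohens_kappa(matrix(c(10, 0, 0, 0), 2, 2)), "p_e")
  expect_true(is.na(k1$kappa))
  expect_error(cohens_kappa(matrix(1, 2, 3)), "square")
})

test_that("precision and recall follow the confusion-matrix definitions", {
  pr <- precision_recall(diag(4, 3))
  expect_equal(pr$precision, 1)
  expect_equal(pr$recall, 1)

  cm <- matrix(c(8, 2, 1, 9), 2, 2, byrow = TRUE,
               dimnames = list(0:1, 0:1))
  pos <- precision_recall(cm, positive = "1")
  expect_equal(pos$precision, 9 / 11, tolerance = 1e-12)
  expect_equal(pos$recall, 0.9, tolerance = 1e-12)

  # macro average equals the mean of per-class brute-force values
  set.seed(6)
  for (i in 1:20) {
    d <- sample(2:4, 1)
    cm <- matrix(rpois(d * d, 5) + 1, d, d)
    pr <- precision_recall(cm)
    expect_equal(pr$precision, mean(diag(cm) / colSums(cm)),
                 tolerance = 1e-12)
    expect_equal(pr$recall, mean(diag(cm) / rowSums(cm)), tolerance = 1e-12)
  }

  cm0 <- matrix(c(5, 3, 0, 0), 2, 2, byrow = TRUE)
  expect_warning(pr0 <- precision_recall(cm0), "empty class")
  expect_equal(pr0$recall, 5 / 8)
})

test_that("RFE terminates with the documented curve length", {
  tab <- make_separable_table(n = 40)
  rfe <- recursive_feature_elimination(
    tab, tab$consolidated, cv_config(seed = 4), stop_at = 1L,
    features = c("back_rmse_median", "area_total_mean"))
  expect_equal(nrow(rfe$curve), 2)       # n_features - stop_at + 1
  expect_length(rfe$removal_order, 1)
  expect_equal(rfe$curve$n_features, c(2L, 1L))
})

test_that("RFE discards pure-noise features before informative ones", {
  wins <- 0L
  for (seed in 1:5) {
    set.seed(seed + 100)
    n <- 200
    lab <- rbinom(n, 1, 0.5)
    tab <- data.frame(inf1 = lab + rnorm(n, 0, 0.3),
                      inf2 = lab + rnorm(n, 0, 0.3),
                      noise1 = rnorm(n), noise2 = rnorm(n),
                      noise3 = rnorm(n))
    rfe <- recursive_feature_elimination(
      tab, lab, cv_config(seed = seed), stop_at = 2L,
      features = names(tab))
    if (setequal(rfe$removal_order, c("noise1", "noise2", "noise3")))
      wins <- wins + 1L
  }
  expect_gte(wins, 4L)
})

test_that("per-scorer validation mirrors the consolidated run layout", {
  co <- simulate_cohort(gait_params(rater_error_prob = 0), 40, seed = 15,
                        n_frames = 20)
  tab <- cohort_feature_table(co, min_frames = 10L)
  res <- per_scorer_validation(tab, cv_config(seed = 5),
                               schemes = c("sound_vs_lame", "clear_lame"))
  expect_equal(nrow(res$summary), 6)   # 3 scorers x 2 schemes
  expect_setequal(unique(res$summary$scorer),
                  c("scorer_1", "scorer_2", "scorer_3"))
  # error-free raters all equal the consolidated score: identical reports
  cons <- threefold_cv(tab, make_labels(tab$consolidated, "clear_lame"),
                       cv_config(seed = 5))
  expect_equal(res$reports$scorer_1$clear_lame$accuracy_mean,
               cons$accuracy_mean)
})
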