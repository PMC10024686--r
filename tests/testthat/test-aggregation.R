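# Per-cow aggregation and statistical screening.

test_that("summary statistics match hand-computed moments", {
  s <- summarize_series(c(0, 1, 2, 3, 4))
  expect_equal(s[["min"]], 0)
  expect_equal(s[["max"]], 4)
  expect_equal(s[["mean"]], 2)
  expect_equal(s[["median"]], 2)
  expect_equal(s[["std"]], sqrt(2.5), tolerance = 1e-12)   # 1.5811
  expect_equal(s[["skew"]], 0)
  expect_equal(s[["kurtosis"]], 6.8 / 4 - 3)               # -1.3

  cst <- summarize_series(rep(3.5, 8))
  expect_equal(cst[["std"]], 0)
  expect_equal(cst[["skew"]], 0)
  expect_equal(cst[["kurtosis"]], 0)

  expect_error(summarize_series(numeric(0)), "empty")
})

test_that("summary statistics agree with an independent moment oracle", {
  set.seed(12)
  for (i in 1:50) {
    x <- rnorm(sample(5:60, 1), sd = runif(1, 0.1, 10))
    s <- summarize_series(x)
    m <- mean(x)
    m2 <- mean((x - m)^2); m3 <- mean((x - m)^3); m4 <- mean((x - m)^4)
    expect_equal(s[["std"]], sqrt(sum((x - m)^2) / (length(x) - 1)),
                 tolerance = 1e-12)
    expect_equal(s[["skew"]], m3 / m2^1.5, tolerance = 1e-12)
    expect_equal(s[["kurtosis"]], m4 / m2^2 - 3, tolerance = 1e-12)
  }
})

test_that("the feature table has the documented 48-column schema", {
  cols <- feature_table_columns()
  expect_length(cols, 48)
  expect_false("head_nose_pos_median" %in% cols)
  expect_true("back_rmse_median" %in% cols)
  expect_true(all(c("area_total_kurtosis", "neck_angle_skew") %in% cols))
  expect_length(feature_table_columns(full_stats = TRUE), 49)
})

test_that("build_feature_table aggregates one row per qualifying cow", {
  co <- simulate_cohort(gait_params(), 61, seed = 20, n_frames = 20)
  ff <- collect_frame_features(co$tracks)
  tab <- build_feature_table(ff, co$scores, min_frames = 10L)
  expect_equal(nrow(tab), 61)
  expect_true(all(feature_table_columns() %in% names(tab)))
  expect_length(intersect(names(tab), feature_table_columns(TRUE)), 48)

  # permutation invariance of cow order
  ff2 <- ff[rev(seq_len(nrow(ff))), ]
  tab2 <- build_feature_table(ff2, co$scores, min_frames = 10L)
  tab2 <- tab2[match(tab$cow_id, tab2$cow_id), ]
  expect_equal(tab2$back_rmse_median, tab$back_rmse_median)

  # a cow with too few frames is excluded with a warning
  short <- ff[!(ff$cow_id == "cow001" &
                  ff$frame_index >= 3), ]
  expect_warning(tab3 <- build_feature_table(short, co$scores,
                                             min_frames = 10L),
                 "cow001")
  expect_equal(nrow(tab3), 60)

  # a cow with no score record is an error listing the id
  expect_error(build_feature_table(ff, co$scores[-1, ], min_frames = 10L),
               "cow001")
})

test_that("Pearson screening reproduces the textbook formula and bands", {
  score <- rep(0:3, each = 10)
  tab <- data.frame(back_rmse_median = 2 * score,
                    area_total_mean = -as.numeric(score),
                    neck_angle_std = rnorm(40),
                    area_total_std = rep(1, 40),
                    consolidated = score)
  rep_ <- pearson_screen(tab)
  get <- function(f, col) rep_[rep_$feature == f, col]
  expect_equal(get("back_rmse_median", "rho"), 1)
  expect_equal(get("area_total_mean", "rho"), -1)
  expect_equal(get("area_total_std", "band"), "undefined")
  expect_equal(get("back_rmse_median", "band"), "****")

  # textbook covariance / (sd sd) oracle
  set.seed(8)
  x <- rnorm(40)
  tab$back_rmse_median <- x
  rep2 <- pearson_screen(tab)
  rho_hand <- sum((x - mean(x)) * (score - mean(score))) /
    sqrt(sum((x - mean(x))^2) * sum((score - mean(score))^2))
  expect_equal(rep2[rep2$feature == "back_rmse_median", "rho"], rho_hand,
               tolerance = 1e-12)

  expect_error(pearson_screen(tab[1:2, ]), "3 rows")
  tab0 <- tab; tab0$consolidated <- 1L
  expect_error(pearson_screen(tab0), "variance")
})

test_that("Kendall's W handles perfect agreement, reversal, and ties", {
  # identical untied rankings
  r <- rbind(1:5, 1:5, 1:5)
  expect_equal(kendalls_w(r)$W, 1)

  # two exactly reversed rankings: oracle by definition
  rev2 <- rbind(c(1, 2, 3), c(3, 2, 1))
  expect_equal(kendalls_w(rev2)$W, kendalls_w_definition(rev2))
  expect_equal(kendalls_w(rev2)$W, 0)

  # tied integer scores vs the brute-force definition
  set.seed(3)
  for (i in 1:20) {
    m <- sample(2:4, 1); n <- sample(4:12, 1)
    r <- matrix(sample(0:3, m * n, replace = TRUE), m, n)
    got <- kendalls_w(r)$W
    want <- kendalls_w_definition(r)
    if (is.na(got)) next  # all raters constant: undefined
    expect_equal(got, want, tolerance = 1e-12)
    # invariance to rater relabeling
    expect_equal(kendalls_w(r[sample(m), ])$W, got, tolerance = 1e-12)
  }

  # every rater scoring every item the same: undefined, reported as NA
  expect_true(is.na(kendalls_w(matrix(2, 3, 5))$W))
  expect_error(kendalls_w(matrix(1, 1, 5)), "2 raters")
  expect_error(kendalls_w(matrix(1, 2, 2)), "3 items")
})

test_that("score consolidation averages and rounds half away from zero", {
  expect_equal(consolidate_scores(c(0, 1, 1)), 1L)   # mean 0.667
  expect_equal(consolidate_scores(c(1, 2, 2)), 2L)   # mean 1.667
  expect_equal(consolidate_scores(c(1, 2, 0)), 1L)   # mean 1.0
  expect_equal(consolidate_scores(c(0, 1)), 1L)      # half rounds up
  expect_equal(consolidate_scores(c(2, 3)), 3L)
  expect_equal(consolidate_scores(3L), 3L)
  expect_error(consolidate_scores(c(1, 4)), "0..3")
  expect_error(consolidate_scores(integer(0)), "0..3")
})

test_that("simulated cohorts recover the injected correlation signs", {
  co <- simulate_cohort(gait_params(), 200, seed = 11, n_frames = 30)
  tab <- cohort_feature_table(co, min_frames = 10L)
  rep_ <- pearson_screen(tab, target = tab$truth_score)
  rmse_med <- rep_[rep_$feature == "back_rmse_median", ]
  expect_gt(rmse_med$rho, 0)
  expect_lt(rmse_med$p_value, 0.001)
})
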