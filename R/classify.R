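# Lameness classification and evaluation: label schemes, repeated-holdout
# "threefold" cross-validation of a gradient-boosted tree classifier,
# recursive feature elimination, feature importances, Cohen's kappa with its
# asymptotic standard error, and precision/recall.

#' Available label schemes
#'
#' The four groupings of the 4-point mobility score used for
#' classification:
#' * `all_classes`: scores 0/1/2/3 kept separate;
#' * `sound_vs_lame`: 0 = sound vs 1-3 = lame;
#' * `clear_lame`: 0-1 = little or no lameness vs 2-3 = clearly lame;
#' * `severe_lame`: 0-2 = not obviously lame vs 3 = severely lame.
#'
#' @return Character vector of scheme names.
#' @export
label_schemes <- function() {
  c("all_classes", "sound_vs_lame", "clear_lame", "severe_lame")
}

#' Map mobility scores to classification labels
#'
#' @param scores Integer vector of mobility scores 0..3.
#' @param scheme One of [label_schemes()].
#' @return Integer label vector (0..3 for `all_classes`, 0/1 otherwise).
#' @export
make_labels <- function(scores, scheme = "all_classes") {
  scheme <- match.arg(scheme, label_schemes())
  s <- as.integer(scores)
  if (anyNA(s) || any(s < 0L | s > 3L))
    stop("scores must be integers in 0..3")
  switch(scheme,
         all_classes = s,
         sound_vs_lame = as.integer(s >= 1L),
         clear_lame = as.integer(s >= 2L),
         severe_lame = as.integer(s >= 3L))
}

#' Cross-validation configuration
#'
#' @param n_folds Number of repeated holdout folds.
#' @param holdout_fraction Fraction held out for testing in each fold.
#' @param seed RNG seed controlling every shuffle and the learner.
#' @param early_stopping_patience Boosting rounds without validation
#'   improvement before training stops.
#' @param nrounds Maximum boosting rounds.
#' @param max_depth,eta Tree depth and learning rate passed to the booster.
#' @param stratify Stratify splits by class (keeps the rare severe-lame
#'   class represented in every fold).
#' @param strict_kfold Use disjoint k-fold partitions instead of the
#'   default independent re-shuffled holdouts.
#' @return List of class `cv_config`.
#' @export
cv_config <- function(n_folds = 3L, holdout_fraction = 0.20, seed = 1L,
                      early_stopping_patience = 20L, nrounds = 300L,
                      max_depth = 4L, eta = 0.1,
                      stratify = TRUE, strict_kfold = FALSE) {
  if (holdout_fraction <= 0 || holdout_fraction >= 1)
    stop("`holdout_fraction` must be in (0, 1)")
  structure(list(n_folds = as.integer(n_folds),
                 holdout_fraction = holdout_fraction,
                 seed = as.integer(seed),
                 early_stopping_patience = as.integer(early_stopping_patience),
                 nrounds = as.integer(nrounds),
                 max_depth = as.integer(max_depth), eta = eta,
                 stratify = isTRUE(stratify),
                 strict_kfold = isTRUE(strict_kfold)),
            class = "cv_config")
}

# Stratified test-index draw; every class keeps at least one member in the
# training portion, and classes too small to split stay in training.
.stratified_holdout <- function(y, fraction, stratify = TRUE) {
  n <- length(y)
  if (!stratify) {
    k <- max(1L, round(fraction * n))
    return(sort(sample.int(n, k)))
  }
  test <- integer(0)
  for (cl in unique(y)) {
    idx <- which(y == cl)
    k <- round(fraction * length(idx))
    k <- min(k, length(idx) - 1L)
    if (k > 0L) test <- c(test, sample(idx, k))
  }
  if (length(test) == 0L) test <- sample.int(n, 1L)
  sort(test)
}

# Feature matrix from a feature table (numeric feature columns only).
.feature_matrix <- function(table, features = NULL) {
  if (is.null(features))
    features <- intersect(feature_table_columns(full_stats = TRUE),
                          names(table))
  if (length(features) == 0L) stop("no feature columns found")
  as.matrix(table[, features, drop = FALSE])
}

# Train a gradient-boosted tree classifier with early stopping monitored on
# a stratified 20% carve-out of the training rows. Labels must be 0-based
# contiguous integers. Returns list(model, classes, best_iteration).
.fit_gbm <- function(X, y, config) {
  classes <- sort(unique(y))
  y0 <- match(y, classes) - 1L
  k <- length(classes)
  val <- .stratified_holdout(y0, 0.20, stratify = TRUE)
  if (length(val) >= length(y0)) val <- val[1]
  dtrain <- xgboost::xgb.DMatrix(X[-val, , drop = FALSE],
                                 label = y0[-val], nthread = 1)
  dval <- xgboost::xgb.DMatrix(X[val, , drop = FALSE],
                               label = y0[val], nthread = 1)
  params <- list(max_depth = config$max_depth, eta = config$eta,
                 tree_method = "exact", nthread = 1, verbosity = 0)
  if (k > 2L) {
    params$objective <- "multi:softmax"
    params$num_class <- k
    params$eval_metric <- "mlogloss"
  } else {
    params$objective <- "binary:logistic"
    params$eval_metric <- "logloss"
  }
  model <- xgboost::xgb.train(
    params = params, data = dtrain, nrounds = config$nrounds,
    evals = list(validation = dval),
    early_stopping_rounds = config$early_stopping_patience,
    verbose = 0)
  best <- suppressWarnings(
    as.integer(xgboost::xgb.attr(model, "best_iteration")))
  list(model = model, classes = classes,
       best_iteration = if (length(best) && !is.na(best)) best
                        else xgboost::xgb.get.num.boosted.rounds(model))
}

.predict_gbm <- function(fit, X) {
  pred <- stats::predict(fit$model, xgboost::xgb.DMatrix(X, nthread = 1))
  if (length(fit$classes) > 2L) fit$classes[pred + 1L]
  else fit$classes[as.integer(pred > 0.5) + 1L]
}

# Raw gain importances as a full named vector over all feature names
# (features the booster never used get 0).
.raw_importance <- function(fit, feature_names) {
  imp <- stats::setNames(rep(0, length(feature_names)), feature_names)
  tab <- tryCatch(xgboost::xgb.importance(model = fit$model),
                  error = function(e) NULL)
  if (!is.null(tab) && nrow(tab) > 0L)
    imp[tab$Feature] <- tab$Gain
  imp
}

#' Repeated-holdout ("threefold") cross-validation
#'
#' Runs `n_folds` independent evaluations: each fold freshly shuffles the
#' data into a stratified 80/20 train/holdout split, trains a
#' gradient-boosted tree classifier with early stopping (monitored on a
#' 20% carve-out of the training portion), and scores the holdout. Note
#' these are re-drawn holdouts, not disjoint partitions; set
#' `strict_kfold = TRUE` in the config for conventional disjoint folds.
#' Fully deterministic given `config$seed`.
#'
#' @param table Feature table from [build_feature_table()].
#' @param labels Integer class labels, one per row of `table`.
#' @param config A [cv_config].
#' @param features Optional character vector restricting the feature
#'   columns used.
#' @return An `eval_report`: `splits` (the holdout row indices of each
#'   fold), `folds` (per-fold accuracy and best
#'   iteration), `accuracy_mean`, `accuracy_sd`, `confusion` (pooled,
#'   truth in rows, predicted in columns), `kappa` (list from
#'   [cohens_kappa()]), `precision`, `recall` (macro-averaged),
#'   `importances` (from a final model on all rows, see
#'   [feature_importances()]), `n`, `scheme_classes`.
#' @export
threefold_cv <- function(table, labels, config = cv_config(),
                         features = NULL) {
  stopifnot(inherits(config, "cv_config"))
  y <- as.integer(labels)
  if (length(unique(y)) < 2L) stop("labels contain a single class")
  if (nrow(table) < 10L) stop("need at least 10 rows")
  X <- .feature_matrix(table, features)
  stopifnot(nrow(X) == length(y))
  classes <- sort(unique(y))
  withr::with_seed(config$seed, {
    if (config$strict_kfold) {
      fold_id <- sample(rep_len(seq_len(config$n_folds), length(y)))
      splits <- lapply(seq_len(config$n_folds),
                       function(f) which(fold_id == f))
    } else {
      splits <- lapply(seq_len(config$n_folds), function(f) {
        for (try in 1:10) {
          test <- .stratified_holdout(y, config$holdout_fraction,
                                      config$stratify)
          if (length(unique(y[-test])) == length(classes)) return(test)
          warning("class missing from training split; re-drawing")
        }
        test
      })
    }
    cm <- matrix(0L, length(classes), length(classes),
                 dimnames = list(truth = classes, predicted = classes))
    folds <- data.frame(fold = seq_len(config$n_folds), accuracy = NA_real_,
                        n_test = NA_integer_, best_iteration = NA_integer_)
    for (f in seq_len(config$n_folds)) {
      test <- splits[[f]]
      fit <- .fit_gbm(X[-test, , drop = FALSE], y[-test], config)
      pred <- .predict_gbm(fit, X[test, , drop = FALSE])
      folds$accuracy[f] <- mean(pred == y[test])
      folds$n_test[f] <- length(test)
      folds$best_iteration[f] <- fit$best_iteration
      for (i in seq_along(test)) {
        r <- match(y[test[i]], classes)
        c_ <- match(pred[i], classes)
        cm[r, c_] <- cm[r, c_] + 1L
      }
    }
    final_fit <- .fit_gbm(X, y, config)
    imp <- feature_importances(.raw_importance(final_fit, colnames(X)))
    pr <- precision_recall(cm)
    structure(list(splits = splits, folds = folds,
                   accuracy_mean = mean(folds$accuracy),
                   accuracy_sd = stats::sd(folds$accuracy),
                   confusion = cm,
                   kappa = cohens_kappa(cm),
                   precision = pr$precision, recall = pr$recall,
                   importances = imp,
                   n = nrow(X), scheme_classes = classes),
              class = "eval_report")
  })
}

#' @export
print.eval_report <- function(x, ...) {
  cat(sprintf("<eval_report> n = %d, %d classes\n", x$n,
              length(x$scheme_classes)))
  cat(sprintf("  accuracy: %.3f +/- %.3f over %d folds\n",
              x$accuracy_mean, x$accuracy_sd, nrow(x$folds)))
  cat(sprintf("  kappa: %.4f (ASE %.4f, 95%% CI %.4f..%.4f)\n",
              x$kappa$kappa, x$kappa$ase, x$kappa$ci_low, x$kappa$ci_high))
  cat(sprintf("  precision: %.4f  recall: %.4f\n", x$precision, x$recall))
  invisible(x)
}

#' Normalized and cumulative feature importances
#'
#' Importances are scaled to sum to 1 and sorted in decreasing order, with
#' a running cumulative sum. Features the model never used appear with
#' importance 0. If every importance is 0 the normalization is undefined
#' and a uniform distribution is returned with `degenerate = TRUE`.
#'
#' @param raw Named numeric vector of raw importances (e.g. booster gains).
#' @return Data.frame `feature`, `normalized`, `cumulative`, sorted
#'   decreasing, with attribute `degenerate`.
#' @export
feature_importances <- function(raw) {
  stopifnot(is.numeric(raw), !is.null(names(raw)))
  degenerate <- sum(raw) <= 0
  norm <- if (degenerate) rep(1 / length(raw), length(raw)) else raw / sum(raw)
  ord <- order(norm, decreasing = TRUE)
  out <- data.frame(feature = names(raw)[ord], normalized = unname(norm[ord]),
                    cumulative = cumsum(unname(norm[ord])),
                    stringsAsFactors = FALSE)
  attr(out, "degenerate") <- degenerate
  out
}

#' Recursive feature elimination
#'
#' Iteratively trains the classifier on a fresh stratified 80/20 split,
#' records the holdout error, and removes the lowest-importance feature,
#' until `stop_at` features remain. Deterministic given `config$seed`.
#'
#' @param table Feature table.
#' @param labels Integer class labels.
#' @param config A [cv_config].
#' @param stop_at Stop when this many features remain.
#' @param features Optional starting feature set.
#' @return List: `curve` (data.frame `n_features`, `error`, one row per
#'   evaluated feature-set size from all features down to `stop_at`),
#'   `removal_order` (features in the order removed), `best_n_features`
#'   (argmin of the error curve).
#' @export
recursive_feature_elimination <- function(table, labels,
                                          config = cv_config(),
                                          stop_at = 1L, features = NULL) {
  y <- as.integer(labels)
  X_all <- .feature_matrix(table, features)
  current <- colnames(X_all)
  if (length(current) < 2L) stop("need at least 2 features")
  stopifnot(stop_at >= 1L, stop_at <= length(current))
  withr::with_seed(config$seed, {
    curve <- data.frame(n_features = integer(0), error = numeric(0))
    removed <- character(0)
    while (TRUE) {
      X <- X_all[, current, drop = FALSE]
      test <- .stratified_holdout(y, config$holdout_fraction,
                                  config$stratify)
      fit <- .fit_gbm(X[-test, , drop = FALSE], y[-test], config)
      pred <- .predict_gbm(fit, X[test, , drop = FALSE])
      curve <- rbind(curve,
                     data.frame(n_features = length(current),
                                error = mean(pred != y[test])))
      if (length(current) <= stop_at) break
      imp <- .raw_importance(fit, current)
      weakest <- names(imp)[which.min(imp)]
      removed <- c(removed, weakest)
      current <- setdiff(current, weakest)
    }
    list(curve = curve, removal_order = removed,
         best_n_features = curve$n_features[which.min(curve$error)])
  })
}

#' Cohen's kappa with asymptotic standard error
#'
#' Chance-corrected agreement between the row (truth) and column
#' (predicted) classifications of a confusion matrix:
#' `kappa = (p_o - p_e) / (1 - p_e)`. The standard error is the
#' large-sample form under the alternative (Fleiss-Cohen-Everitt), giving a
#' 95% CI `kappa +/- 1.96 * ASE`; `z` and `p_value` report the
#' variance-under-H0 test of kappa = 0.
#'
#' @param cm Square numeric confusion matrix with a positive total.
#' @return List: `kappa`, `ase`, `ci_low`, `ci_high`, `z`, `p_value`,
#'   `p_o`, `p_e`. All `NA` (with a warning) when `p_e = 1`.
#' @export
cohens_kappa <- function(cm) {
  cm <- as.matrix(cm)
  if (nrow(cm) != ncol(cm)) stop("confusion matrix must be square")
  n <- sum(cm)
  if (n <= 0) stop("confusion matrix must have a positive total")
  p <- cm / n
  pr <- rowSums(p); pc <- colSums(p)
  po <- sum(diag(p))
  pe <- sum(pr * pc)
  if (abs(1 - pe) < 1e-12) {
    warning("p_e = 1: kappa undefined")
    return(list(kappa = NA_real_, ase = NA_real_, ci_low = NA_real_,
                ci_high = NA_real_, z = NA_real_, p_value = NA_real_,
                p_o = po, p_e = pe))
  }
  kappa <- (po - pe) / (1 - pe)
  # large-sample variance under the alternative
  A <- sum(diag(p) * (1 - (pr + pc) * (1 - kappa))^2)
  off <- p * outer(pc, pr, "+")^2
  diag(off) <- 0
  B <- (1 - kappa)^2 * sum(off)
  C <- (kappa - pe * (1 - kappa))^2
  var_k <- (A + B - C) / (n * (1 - pe)^2)
  ase <- sqrt(max(var_k, 0))
  # variance under H0: kappa = 0 (the "variance equal-zero" z-test)
  var0 <- (pe + pe^2 - sum(pr * pc * (pr + pc))) / (n * (1 - pe)^2)
  z <- if (var0 > 0) kappa / sqrt(var0) else NA_real_
  list(kappa = kappa, ase = ase,
       ci_low = kappa - 1.96 * ase, ci_high = kappa + 1.96 * ase,
       z = z,
       p_value = if (is.na(z)) NA_real_ else
         2 * stats::pnorm(-abs(z)),
       p_o = po, p_e = pe)
}

#' Precision and recall from a confusion matrix
#'
#' Truth in rows, predictions in columns. Per-class precision is
#' `diag / colSums`, recall `diag / rowSums`; the returned values are
#' macro-averages over classes. Classes with no true members (recall) or no
#' predictions (precision) are excluded from the average with a warning.
#' For a binary matrix, `positive` restricts both metrics to that class.
#'
#' @param cm Square confusion matrix.
#' @param positive Optional class label (row/col name or index) to report
#'   instead of the macro average.
#' @return List: `precision`, `recall`, `per_class` (data.frame).
#' @export
precision_recall <- function(cm, positive = NULL) {
  cm <- as.matrix(cm)
  if (nrow(cm) != ncol(cm)) stop("confusion matrix must be square")
  d <- diag(cm)
  prec <- ifelse(colSums(cm) > 0, d / colSums(cm), NA_real_)
  rec <- ifelse(rowSums(cm) > 0, d / rowSums(cm), NA_real_)
  labels <- rownames(cm) %||% as.character(seq_len(nrow(cm)))
  per_class <- data.frame(class = labels, precision = unname(prec),
                          recall = unname(rec), stringsAsFactors = FALSE)
  if (!is.null(positive)) {
    i <- if (is.numeric(positive)) as.integer(positive)
         else match(as.character(positive), labels)
    if (is.na(i) || i < 1L || i > nrow(cm)) stop("unknown positive class")
    return(list(precision = unname(prec[i]), recall = unname(rec[i]),
                per_class = per_class))
  }
  if (anyNA(prec) || anyNA(rec))
    warning("empty class excluded from the macro average")
  list(precision = mean(prec, na.rm = TRUE),
       recall = mean(rec, na.rm = TRUE),
       per_class = per_class)
}

#' Per-scorer classification validation
#'
#' Repeats the full cross-validated classification against each individual
#' rater's scores (instead of the consolidated score), for each label
#' scheme. Used to check that consolidating raters by averaging does not
#' hide rater-specific structure.
#'
#' @param table Feature table containing `scorer_*` columns.
#' @param config A [cv_config].
#' @param schemes Label schemes to evaluate (default all four).
#' @return List: `reports` (nested `[[scorer]][[scheme]]` eval_reports) and
#'   `summary` (data.frame `scorer`, `scheme`, `accuracy_mean`,
#'   `accuracy_sd`).
#' @export
per_scorer_validation <- function(table, config = cv_config(),
                                  schemes = label_schemes()) {
  scorer_cols <- grep("^scorer_", names(table), value = TRUE)
  if (length(scorer_cols) < 2L) stop("need at least 2 scorer columns")
  reports <- list()
  rows <- list()
  for (sc in scorer_cols) {
    reports[[sc]] <- list()
    for (scheme in schemes) {
      labs <- make_labels(table[[sc]], scheme)
      rep_ <- threefold_cv(table, labs, config)
      reports[[sc]][[scheme]] <- rep_
      rows[[length(rows) + 1L]] <- data.frame(
        scorer = sc, scheme = scheme,
        accuracy_mean = rep_$accuracy_mean,
        accuracy_sd = rep_$accuracy_sd, stringsAsFactors = FALSE)
    }
  }
  list(reports = reports, summary = do.call(rbind, rows))
}
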