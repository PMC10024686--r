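# Per-cow aggregation of frame features, the feature table, and statistical
# screening: Pearson correlation against mobility scores, Kendall's
# coefficient of concordance between raters, and score consolidation.

.STAT_NAMES <- c("min", "max", "mean", "median", "std", "skew", "kurtosis")
.FEATURE_NAMES <- c("back_rmse", "area_hip_centre", "area_shoulder_centre",
                    "area_neck_shoulder", "area_total", "head_nose_pos",
                    "neck_angle")

#' Seven summary statistics of a per-frame feature series
#'
#' Standard deviation uses one delta degree of freedom (the n-1
#' denominator); skewness and kurtosis are the biased (population) moment
#' estimators, with kurtosis reported as excess (Fisher) kurtosis. For a
#' constant series the skew and kurtosis are defined as 0 rather than NaN so
#' that downstream feature tables stay numeric.
#'
#' @param series Numeric vector (NAs dropped), at least one value.
#' @return Named numeric vector: `min`, `max`, `mean`, `median`, `std`,
#'   `skew`, `kurtosis`.
#' @export
summarize_series <- function(series) {
  x <- series[!is.na(series)]
  if (length(x) == 0L) stop("empty series")
  s <- stats::sd(x)
  if (length(x) == 1L) s <- 0
  if (s == 0 || isTRUE(all(x == x[1]))) {
    sk <- 0; ku <- 0
  } else {
    m <- mean(x)
    m2 <- mean((x - m)^2)
    sk <- mean((x - m)^3) / m2^1.5
    ku <- mean((x - m)^4) / m2^2 - 3
  }
  c(min = min(x), max = max(x), mean = mean(x),
    median = stats::median(x), std = s, skew = sk, kurtosis = ku)
}

#' Column names of the per-cow feature table
#'
#' The default table has 48 feature columns: the 7 per-frame kinematic
#' features crossed with the 7 summary statistics, minus the median of the
#' head/nose elevation series (whose information is already carried by its
#' mean and extrema). `full_stats = TRUE` restores it, giving 49 columns.
#'
#' @param full_stats Include `head_nose_pos_median`?
#' @return Character vector of column names.
#' @export
feature_table_columns <- function(full_stats = FALSE) {
  cols <- as.vector(t(outer(.FEATURE_NAMES, .STAT_NAMES, paste, sep = "_")))
  if (!full_stats) cols <- setdiff(cols, "head_nose_pos_median")
  cols
}

#' Build the per-cow feature table
#'
#' Collapses per-frame kinematic features into one row per cow (the 48
#' aggregate columns of [feature_table_columns()]) and attaches the rater
#' and consolidated mobility scores. A feature's statistics use only the
#' frames where that feature was valid; cows with fewer than `min_frames`
#' valid back-feature frames are excluded with a warning.
#'
#' @param frame_feats Data.frame of per-frame features with a `cow_id`
#'   column (rows from [track_features()]).
#' @param scores Data.frame with `cow_id`, `scorer_*` columns and optional
#'   `consolidated` (as from [read_scores()]); a missing `consolidated` is
#'   filled with [consolidate_scores()].
#' @param min_frames Minimum number of valid frames per cow.
#' @param full_stats Include `head_nose_pos_median` (see
#'   [feature_table_columns()]).
#' @return Data.frame, one row per cow: `cow_id`, the feature columns, the
#'   `scorer_*` columns and `consolidated`.
#' @export
build_feature_table <- function(frame_feats, scores, min_frames = 10L,
                                full_stats = FALSE) {
  stopifnot(is.data.frame(frame_feats), "cow_id" %in% names(frame_feats))
  cow_ids <- unique(frame_feats$cow_id)
  missing <- setdiff(cow_ids, scores$cow_id)
  if (length(missing))
    stop("no score record for cow(s): ", paste(missing, collapse = ", "))
  scorer_cols <- grep("^scorer_", names(scores), value = TRUE)
  if (!"consolidated" %in% names(scores) || anyNA(scores$consolidated)) {
    scores$consolidated <- vapply(seq_len(nrow(scores)), function(i)
      consolidate_scores(stats::na.omit(
        as.integer(unlist(scores[i, scorer_cols])))), integer(1))
  }
  cols <- feature_table_columns(full_stats)
  rows <- list()
  dropped <- character(0)
  for (cid in cow_ids) {
    ff <- frame_feats[frame_feats$cow_id == cid, ]
    if (sum(ff$valid_back) < min_frames) {
      dropped <- c(dropped, cid)
      next
    }
    row <- list(cow_id = cid)
    for (feat in .FEATURE_NAMES) {
      ok <- switch(feat,
                   head_nose_pos = ff$valid_head,
                   neck_angle = ff$valid_neck,
                   ff$valid_back)
      vals <- ff[[feat]][ok]
      st <- if (length(vals)) summarize_series(vals)
            else stats::setNames(rep(NA_real_, 7L), .STAT_NAMES)
      for (sn in .STAT_NAMES) {
        cn <- paste(feat, sn, sep = "_")
        if (cn %in% cols) row[[cn]] <- unname(st[sn])
      }
    }
    rows[[length(rows) + 1L]] <- as.data.frame(row, stringsAsFactors = FALSE)
  }
  if (length(dropped))
    warning("excluded ", length(dropped), " cow(s) below min_frames = ",
            min_frames, ": ", paste(dropped, collapse = ", "))
  if (!length(rows)) stop("no cow met min_frames = ", min_frames)
  tab <- do.call(rbind, rows)
  idx <- match(tab$cow_id, scores$cow_id)
  for (sc in scorer_cols) tab[[sc]] <- scores[[sc]][idx]
  tab$consolidated <- scores$consolidated[idx]
  tab
}

#' Pearson screening of features against the mobility score
#'
#' Computes the Pearson correlation and two-sided p-value of every feature
#' column against the target score, with a significance band per the
#' thresholds: dagger p < 0.10, `*` p < 0.05, `**` p < 0.01,
#' `****` p < 0.001.
#'
#' @param table Feature table from [build_feature_table()] (or any
#'   data.frame of numeric feature columns).
#' @param target Numeric vector of scores, or the name of a column of
#'   `table` (default `"consolidated"`).
#' @param features Character vector of feature columns to screen; defaults
#'   to every [feature_table_columns()] name present in `table`.
#' @return Data.frame: `feature`, `rho`, `p_value`, `band`. Zero-variance
#'   features get `NA` rho with band `"undefined"`.
#' @export
pearson_screen <- function(table, target = "consolidated",
                           features = NULL) {
  if (is.character(target) && length(target) == 1L) {
    stopifnot(target %in% names(table))
    target <- table[[target]]
  }
  if (nrow(table) < 3L) stop("need at least 3 rows")
  if (stats::var(target) == 0) stop("target has zero variance")
  if (is.null(features))
    features <- intersect(feature_table_columns(full_stats = TRUE),
                          names(table))
  band_of <- function(p) {
    if (is.na(p)) "undefined"
    else if (p < 0.001) "****"
    else if (p < 0.01) "**"
    else if (p < 0.05) "*"
    else if (p < 0.10) "†"
    else ""
  }
  rows <- lapply(features, function(f) {
    x <- table[[f]]
    ok <- !is.na(x)
    if (sum(ok) < 3L || stats::var(x[ok]) == 0)
      return(data.frame(feature = f, rho = NA_real_, p_value = NA_real_,
                        band = "undefined", stringsAsFactors = FALSE))
    ct <- stats::cor.test(x[ok], target[ok], method = "pearson")
    data.frame(feature = f, rho = unname(ct$estimate),
               p_value = ct$p.value, band = band_of(ct$p.value),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Kendall's coefficient of concordance (W) with tie correction
#'
#' Agreement of m raters ranking n items, tie-corrected (integer mobility
#' scores are heavily tied). The p-value uses the chi-square approximation
#' `chi2 = m * (n - 1) * W` on `n - 1` degrees of freedom.
#'
#' @param ratings Numeric matrix, raters in rows, items in columns.
#' @return List: `W` (in `[0, 1]`, `NA` if every rater ranks all items
#'   identically so the denominator vanishes), `chisq`, `df`, `p_value`,
#'   `n_raters`, `n_items`.
#' @export
kendalls_w <- function(ratings) {
  ratings <- as.matrix(ratings)
  m <- nrow(ratings); n <- ncol(ratings)
  if (m < 2L) stop("need at least 2 raters")
  if (n < 3L) stop("need at least 3 items")
  ranks <- t(apply(ratings, 1, rank))          # average ranks within rater
  R <- colSums(ranks)
  S <- sum((R - mean(R))^2)
  Tj <- apply(ranks, 1, function(r) {
    t <- table(r)
    sum(t^3 - t)
  })
  denom <- m^2 * (n^3 - n) - m * sum(Tj)
  if (denom <= 0)
    return(list(W = NA_real_, chisq = NA_real_, df = n - 1L,
                p_value = NA_real_, n_raters = m, n_items = n))
  W <- 12 * S / denom
  chisq <- m * (n - 1) * W
  list(W = W, chisq = chisq, df = n - 1L,
       p_value = stats::pchisq(chisq, n - 1L, lower.tail = FALSE),
       n_raters = m, n_items = n)
}

#' Consolidate several raters' mobility scores into one
#'
#' Arithmetic mean of the rater scores, rounded to the nearest whole score
#' with halves rounded away from zero.
#'
#' @param rater_scores Integer vector of scores in 0..3.
#' @return Integer consolidated score in 0..3.
#' @export
consolidate_scores <- function(rater_scores) {
  s <- as.numeric(rater_scores)
  if (length(s) == 0L || anyNA(s) || any(s < 0 | s > 3 | s != round(s)))
    stop("rater scores must be integers in 0..3")
  as.integer(floor(mean(s) + 0.5))
}
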