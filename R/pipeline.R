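# End-to-end orchestration: simulate -> track -> features -> aggregate ->
# screen -> classify, writing every intermediate artifact to disk so each
# stage can be re-run independently.

#' Run configuration for the end-to-end demo
#'
#' @param out_dir Output directory for artifacts.
#' @param seed Master seed for the whole run.
#' @param n_cows Cohort size.
#' @param n_frames Frames per simulated sequence.
#' @param params A [gait_params].
#' @param tracker A [tracker_config].
#' @param cv A [cv_config] (its seed is overridden by `seed`).
#' @param schemes Label schemes to classify.
#' @param min_frames Minimum valid frames per cow for aggregation.
#' @return List of class `run_config`.
#' @export
run_config <- function(out_dir = tempfile("gaitkit_demo_"), seed = 1L,
                       n_cows = 50L, n_frames = 60L,
                       params = gait_params(),
                       tracker = tracker_config(),
                       cv = cv_config(),
                       schemes = label_schemes(),
                       min_frames = 10L) {
  cv$seed <- as.integer(seed)
  structure(list(out_dir = out_dir, seed = as.integer(seed),
                 n_cows = as.integer(n_cows), n_frames = as.integer(n_frames),
                 params = params, tracker = tracker, cv = cv,
                 schemes = schemes, min_frames = as.integer(min_frames)),
            class = "run_config")
}

#' Collect per-frame features for a list of tracks
#'
#' @param tracks List of `tracked_cow` objects.
#' @return Data.frame of per-frame features (see [track_features()]).
#' @export
collect_frame_features <- function(tracks) {
  do.call(rbind, lapply(tracks, track_features))
}

#' Attach ground-truth cow identities to tracker output
#'
#' Labels each confirmed track with its majority ground-truth cow (via the
#' simulator's per-frame truth assignment) so scores can be joined.
#'
#' @param tracks Output of [run_tracker()].
#' @param fs The simulated [frame_set] (carrying the `truth` attribute).
#' @return The tracks with `cow_id` filled in.
#' @export
label_tracks <- function(tracks, fs) {
  truth <- attr(fs, "truth")
  if (is.null(truth)) stop("frame set carries no truth assignment")
  m <- match_tracks_to_truth(tracks, truth)
  for (i in seq_along(tracks))
    tracks[[i]]$cow_id <- m$cow_id[match(tracks[[i]]$track_id, m$track_id)]
  tracks
}

#' Run the full demo pipeline
#'
#' Simulates a scored cohort, re-tracks every sequence from the anonymous
#' per-frame detections, extracts per-frame kinematics, aggregates to the
#' per-cow feature table, screens features with Pearson correlation,
#' computes Kendall's W across the simulated raters, and cross-validates a
#' classifier under each requested label scheme. Artifacts written to
#' `config$out_dir`: `keypoints.json`, `keypoints_tracked.json`,
#' `frame_features.csv`, `features.csv`, `correlations.csv`, `scores.csv`,
#' `report.json`, `run_log.txt`.
#'
#' @param config A [run_config].
#' @return Invisibly, a list with the in-memory results: `cohort`,
#'   `tracks`, `feature_table`, `correlations`, `kendall`, `reports`
#'   (per-scheme `eval_report`), `artifact_dir`.
#' @export
run_demo <- function(config = run_config()) {
  stopifnot(inherits(config, "run_config"))
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  art <- function(f) file.path(config$out_dir, f)
  log_lines <- c(sprintf("gaitkit=%s", as.character(utils::packageVersion("gaitkit"))),
                 sprintf("seed=%d", config$seed),
                 sprintf("n_cows=%d", config$n_cows))

  cohort <- simulate_cohort(config$params, config$n_cows, seed = config$seed,
                            n_frames = config$n_frames)
  write_keypoint_sequences(cohort$frame_sets, art("keypoints.json"))
  write_scores(cohort$scores, art("scores.csv"))

  tracks <- list()
  tracked_sets <- list()
  for (fs in cohort$frame_sets) {
    tr <- run_tracker(fs, config$tracker)
    tr <- label_tracks(tr, fs)
    tracks <- c(tracks, tr)
    tracked_sets[[length(tracked_sets) + 1L]] <- .apply_track_ids(fs, tr)
  }
  write_keypoint_sequences(tracked_sets, art("keypoints_tracked.json"))
  log_lines <- c(log_lines, sprintf("stage=track n_tracks=%d", length(tracks)))

  frame_feats <- collect_frame_features(tracks)
  utils::write.csv(frame_feats, art("frame_features.csv"), row.names = FALSE)

  tab <- build_feature_table(frame_feats, cohort$scores,
                             min_frames = config$min_frames)
  utils::write.csv(tab, art("features.csv"), row.names = FALSE)
  log_lines <- c(log_lines, sprintf("stage=aggregate n_rows=%d", nrow(tab)))

  corr <- pearson_screen(tab)
  utils::write.csv(corr, art("correlations.csv"), row.names = FALSE)

  kend <- kendalls_w(t(as.matrix(
    tab[, grep("^scorer_", names(tab)), drop = FALSE])))

  reports <- list()
  for (scheme in config$schemes) {
    labs <- make_labels(tab$consolidated, scheme)
    if (length(unique(labs)) < 2L) {
      log_lines <- c(log_lines,
                     sprintf("stage=classify scheme=%s skipped=single_class",
                             scheme))
      next
    }
    reports[[scheme]] <- threefold_cv(tab, labs, config$cv)
    log_lines <- c(log_lines,
                   sprintf("stage=classify scheme=%s accuracy=%.4f", scheme,
                           reports[[scheme]]$accuracy_mean))
  }

  report_json <- list(
    seed = config$seed, n_cows = config$n_cows,
    kendalls_w = kend[c("W", "chisq", "df", "p_value")],
    correlations = corr,
    schemes = lapply(reports, function(r) list(
      accuracy_mean = r$accuracy_mean, accuracy_sd = r$accuracy_sd,
      per_fold = r$folds$accuracy,
      confusion = unclass(r$confusion),
      kappa = r$kappa, precision = r$precision, recall = r$recall,
      importances = r$importances)))
  jsonlite::write_json(report_json, art("report.json"), auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  writeLines(log_lines, art("run_log.txt"))

  invisible(list(cohort = cohort, tracks = tracks, feature_table = tab,
                 correlations = corr, kendall = kend, reports = reports,
                 artifact_dir = config$out_dir))
}

# Re-emit a frame set with the tracker's ids written into each pose.
.apply_track_ids <- function(fs, tracks) {
  id_of <- list()
  for (tc in tracks)
    for (k in seq_len(nrow(tc$assignments)))
      id_of[[paste(tc$assignments$frame_index[k],
                   tc$assignments$animal[k])]] <- tc$track_id
  fs$frames <- lapply(fs$frames, function(fr) {
    fr$animals <- lapply(seq_along(fr$animals), function(j) {
      p <- fr$animals[[j]]
      tid <- id_of[[paste(fr$frame_index, j)]]
      p$track_id <- if (is.null(tid)) NA_integer_ else tid
      p
    })
    fr
  })
  attr(fs, "truth") <- NULL
  attr(fs, "tracks") <- NULL
  fs
}

#' Build a per-cow feature table straight from a simulated cohort
#'
#' Convenience for studies that do not need the tracker in the loop: uses
#' the simulator's ground-truth tracks directly.
#'
#' @param cohort A `simulated_cohort`.
#' @param min_frames Minimum valid frames per cow.
#' @return Feature table as from [build_feature_table()], with the true
#'   score joined as column `truth_score`.
#' @export
cohort_feature_table <- function(cohort, min_frames = 10L) {
  stopifnot(inherits(cohort, "simulated_cohort"))
  ff <- collect_frame_features(cohort$tracks)
  tab <- build_feature_table(ff, cohort$scores, min_frames = min_frames)
  tab$truth_score <- cohort$truth$score[match(tab$cow_id,
                                              cohort$truth$cow_id)]
  tab
}
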