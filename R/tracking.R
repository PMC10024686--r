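# SORT-style tracking-by-detection: constant-velocity Kalman prediction of
# each track's bounding box, IoU-cost one-to-one assignment (Hungarian), and
# track lifecycle management (tentative / confirmed / retired).

#' Intersection over union of two bounding boxes
#'
#' @param a,b `bbox` vectors (`x_min`, `y_min`, `x_max`, `y_max`).
#' @return IoU in `[0, 1]`; 0 for disjoint boxes.
#' @export
iou <- function(a, b) {
  ix <- max(0, min(a[["x_max"]], b[["x_max"]]) - max(a[["x_min"]], b[["x_min"]]))
  iy <- max(0, min(a[["y_max"]], b[["y_max"]]) - max(a[["y_min"]], b[["y_min"]]))
  inter <- ix * iy
  if (inter <= 0) return(0)
  area_a <- (a[["x_max"]] - a[["x_min"]]) * (a[["y_max"]] - a[["y_min"]])
  area_b <- (b[["x_max"]] - b[["x_min"]]) * (b[["y_max"]] - b[["y_min"]])
  inter / (area_a + area_b - inter)
}

#' Tracker configuration
#'
#' @param iou_threshold Minimum IoU for a detection/track match (0..1).
#' @param max_misses Consecutive missed frames before a track is retired.
#' @param min_hits_to_confirm Hits required before a track is confirmed;
#'   unconfirmed (tentative) tracks are dropped from the output.
#' @param q_scale,r_scale Multipliers on the process and measurement noise
#'   covariances of the constant-velocity Kalman model.
#' @param trust_input_ids If `TRUE`, [run_tracker()] bypasses tracking and
#'   groups poses by the `track_id` already present in the input.
#' @return List of class `tracker_config`.
#' @export
tracker_config <- function(iou_threshold = 0.3, max_misses = 5L,
                           min_hits_to_confirm = 3L,
                           q_scale = 1, r_scale = 1,
                           trust_input_ids = FALSE) {
  if (iou_threshold <= 0 || iou_threshold >= 1)
    stop("`iou_threshold` must be in (0, 1)")
  structure(list(iou_threshold = iou_threshold,
                 max_misses = as.integer(max_misses),
                 min_hits_to_confirm = as.integer(min_hits_to_confirm),
                 q_scale = q_scale, r_scale = r_scale,
                 trust_input_ids = isTRUE(trust_input_ids)),
            class = "tracker_config")
}

# --- Kalman filter (constant velocity in centre and area, fixed aspect) ----
# State: (cx, cy, s, r, vcx, vcy, vs); measurement: (cx, cy, s, r).

.kf_F <- local({
  F <- diag(7)
  F[1, 5] <- F[2, 6] <- F[3, 7] <- 1
  F
})
.kf_H <- cbind(diag(4), matrix(0, 4, 3))

.bbox_to_z <- function(b) {
  w <- b[["x_max"]] - b[["x_min"]]
  h <- b[["y_max"]] - b[["y_min"]]
  c(b[["x_min"]] + w / 2, b[["y_min"]] + h / 2, w * h, w / h)
}

.z_to_bbox <- function(z) {
  w <- sqrt(max(z[3], 1e-12) * max(z[4], 1e-12))
  h <- max(z[3], 1e-12) / w
  structure(c(x_min = z[1] - w / 2, y_min = z[2] - h / 2,
              x_max = z[1] + w / 2, y_max = z[2] + h / 2),
            class = "bbox")
}

.kf_new <- function(z, config) {
  list(x = c(z, 0, 0, 0),
       P = diag(c(10, 10, 10, 10, 1e4, 1e4, 1e4)),
       Q = config$q_scale * diag(c(1, 1, 1, 1, 0.01, 0.01, 1e-4)),
       R = config$r_scale * diag(c(1, 1, 10, 10)))
}

.kf_predict <- function(kf) {
  if (kf$x[3] + kf$x[7] <= 0) kf$x[7] <- 0   # do not predict negative area
  kf$x <- drop(.kf_F %*% kf$x)
  kf$P <- .kf_F %*% kf$P %*% t(.kf_F) + kf$Q
  kf
}

.kf_update <- function(kf, z) {
  y <- z - drop(.kf_H %*% kf$x)
  S <- .kf_H %*% kf$P %*% t(.kf_H) + kf$R
  K <- kf$P %*% t(.kf_H) %*% solve(S)
  kf$x <- kf$x + drop(K %*% y)
  kf$P <- (diag(7) - K %*% .kf_H) %*% kf$P
  kf
}

.new_track <- function(id, z, config) {
  list(track_id = id, kf = .kf_new(z, config),
       hits = 1L, misses = 0L, age = 1L,
       max_hits = 1L, records = list())
}

#' Advance the tracker by one frame
#'
#' Kalman-predicts every active track, solves the optimal one-to-one
#' IoU-cost assignment between predicted boxes and detections (matches with
#' IoU below `config$iou_threshold` are rejected), updates matched tracks,
#' spawns tentative tracks for unmatched detections and retires tracks that
#' exceed `max_misses`.
#'
#' @param states List of active track states (from a previous call, or
#'   `list()` for the first frame).
#' @param detections List of [cow_pose] objects for one frame.
#' @param config A [tracker_config].
#' @param next_id First id to use for newly spawned tracks.
#' @return List with `states` (updated active tracks), `assignment`
#'   (integer vector, detection index -> track id) and `next_id`.
#' @export
step_tracker <- function(states, detections, config = tracker_config(),
                         next_id = 1L) {
  n_det <- length(detections)
  states <- lapply(states, function(tr) { tr$kf <- .kf_predict(tr$kf); tr })
  assignment <- rep(NA_integer_, n_det)
  matched_tr <- integer(0)
  if (length(states) > 0L && n_det > 0L) {
    det_boxes <- lapply(detections, bbox_from_pose)
    pred_boxes <- lapply(states, function(tr) .z_to_bbox(tr$kf$x))
    iou_mat <- matrix(0, length(states), n_det)
    for (i in seq_along(states))
      for (j in seq_len(n_det))
        iou_mat[i, j] <- iou(pred_boxes[[i]], det_boxes[[j]])
    pairs <- solve_assignment(1 - iou_mat)
    for (k in seq_len(nrow(pairs))) {
      i <- pairs[k, 1]; j <- pairs[k, 2]
      if (iou_mat[i, j] >= config$iou_threshold) {
        assignment[j] <- states[[i]]$track_id
        matched_tr <- c(matched_tr, i)
        z <- .bbox_to_z(det_boxes[[j]])
        states[[i]]$kf <- .kf_update(states[[i]]$kf, z)
        states[[i]]$hits <- states[[i]]$hits + 1L
        states[[i]]$max_hits <- max(states[[i]]$max_hits, states[[i]]$hits)
        states[[i]]$misses <- 0L
      }
    }
  }
  for (i in seq_along(states)) {
    states[[i]]$age <- states[[i]]$age + 1L
    if (!i %in% matched_tr)
      states[[i]]$misses <- states[[i]]$misses + 1L
  }
  for (j in which(is.na(assignment))) {
    z <- .bbox_to_z(bbox_from_pose(detections[[j]]))
    states[[length(states) + 1L]] <- .new_track(next_id, z, config)
    assignment[j] <- next_id
    next_id <- next_id + 1L
  }
  keep <- vapply(states, function(tr) tr$misses <= config$max_misses,
                 logical(1))
  list(states = states[keep], assignment = assignment, next_id = next_id)
}

#' Minimum-cost one-to-one assignment
#'
#' Solves the rectangular linear sum assignment problem (Hungarian
#' algorithm) for a cost matrix; every row (track) is matched to at most one
#' column (detection) and vice versa.
#'
#' @param cost Numeric cost matrix (rows x columns).
#' @return Two-column integer matrix of matched `(row, col)` pairs, one per
#'   matched pair, `min(nrow, ncol)` rows.
#' @export
solve_assignment <- function(cost) {
  cost <- as.matrix(cost)
  nr <- nrow(cost); nc <- ncol(cost)
  if (nr == 0L || nc == 0L)
    return(matrix(integer(0), 0, 2, dimnames = list(NULL, c("row", "col"))))
  if (nr <= nc) {
    sol <- clue::solve_LSAP(cost)
    pairs <- cbind(row = seq_len(nr), col = as.integer(sol))
  } else {
    sol <- clue::solve_LSAP(t(cost))
    pairs <- cbind(row = as.integer(sol), col = seq_len(nc))
  }
  pairs
}

#' Run the tracker over a whole sequence
#'
#' @param fs A [frame_set] (frames time-ordered).
#' @param config A [tracker_config]. With `trust_input_ids = TRUE`, poses
#'   are grouped by their existing `track_id` instead of being tracked.
#' @return List of `tracked_cow` objects, one per confirmed track (tracks
#'   that never reached `min_hits_to_confirm` hits are dropped). Each
#'   carries an `assignments` data.frame (`frame_index`, `animal`) recording
#'   which detection fed the track in each frame.
#' @export
run_tracker <- function(fs, config = tracker_config()) {
  stopifnot(inherits(fs, "frame_set"), inherits(config, "tracker_config"))
  if (config$trust_input_ids) return(.group_by_input_ids(fs))
  states <- list()
  next_id <- 1L
  records <- list()   # per track id: list(poses, frames, animals)
  for (fr in fs$frames) {
    st <- step_tracker(states, fr$animals, config, next_id)
    states <- st$states; next_id <- st$next_id
    for (j in seq_along(fr$animals)) {
      id <- as.character(st$assignment[j])
      rec <- records[[id]] %||% list(poses = list(), frames = integer(0),
                                     animals = integer(0))
      p <- fr$animals[[j]]
      p$track_id <- st$assignment[j]
      rec$poses[[length(rec$poses) + 1L]] <- p
      rec$frames <- c(rec$frames, fr$frame_index)
      rec$animals <- c(rec$animals, j)
      records[[id]] <- rec
    }
  }
  # tracks retired mid-sequence can still be confirmed: judge by record length
  ids <- names(records)
  out <- list()
  for (id in ids) {
    rec <- records[[id]]
    if (length(rec$poses) < config$min_hits_to_confirm) next
    out[[length(out) + 1L]] <- structure(
      list(track_id = as.integer(id), cow_id = NULL, fps = fs$fps,
           frame_indices = rec$frames, poses = rec$poses,
           assignments = data.frame(frame_index = rec$frames,
                                    animal = rec$animals)),
      class = "tracked_cow")
  }
  out[order(vapply(out, function(tc) tc$track_id, integer(1)))]
}

.group_by_input_ids <- function(fs) {
  records <- list()
  for (fr in fs$frames) {
    for (j in seq_along(fr$animals)) {
      p <- fr$animals[[j]]
      if (is.na(p$track_id)) next
      id <- as.character(p$track_id)
      rec <- records[[id]] %||% list(poses = list(), frames = integer(0),
                                     animals = integer(0))
      rec$poses[[length(rec$poses) + 1L]] <- p
      rec$frames <- c(rec$frames, fr$frame_index)
      rec$animals <- c(rec$animals, j)
      records[[id]] <- rec
    }
  }
  out <- lapply(names(records), function(id) {
    rec <- records[[id]]
    structure(list(track_id = as.integer(id), cow_id = NULL, fps = fs$fps,
                   frame_indices = rec$frames, poses = rec$poses,
                   assignments = data.frame(frame_index = rec$frames,
                                            animal = rec$animals)),
              class = "tracked_cow")
  })
  out[order(vapply(out, function(tc) tc$track_id, integer(1)))]
}

#' Match tracker output to simulator ground truth
#'
#' Joins each track's per-frame detection indices against the simulator's
#' `truth` attribute and labels the track with its majority ground-truth
#' cow. Purity is the fraction of the track's frames that belong to that
#' cow.
#'
#' @param tracks Output of [run_tracker()].
#' @param truth Data.frame `frame_index`, `animal`, `cow_id` (the `truth`
#'   attribute of [simulate_sequence()] output).
#' @return Data.frame: `track_id`, `cow_id` (majority truth), `n_frames`,
#'   `purity`.
#' @export
match_tracks_to_truth <- function(tracks, truth) {
  rows <- lapply(tracks, function(tc) {
    key <- paste(tc$assignments$frame_index, tc$assignments$animal)
    tkey <- paste(truth$frame_index, truth$animal)
    ids <- truth$cow_id[match(key, tkey)]
    tab <- sort(table(ids), decreasing = TRUE)
    data.frame(track_id = tc$track_id, cow_id = names(tab)[1],
               n_frames = length(ids),
               purity = as.integer(tab[1]) / length(ids),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Count identity switches against ground truth
#'
#' For each ground-truth cow, follows the sequence of track ids assigned to
#' its detections over frames and counts how many times that id changes.
#'
#' @param tracks Output of [run_tracker()].
#' @param truth Truth assignment data.frame (see [match_tracks_to_truth()]).
#' @return Total number of identity switches (integer).
#' @export
count_identity_switches <- function(tracks, truth) {
  # invert: (frame, animal) -> track id
  key <- unlist(lapply(tracks, function(tc)
    paste(tc$assignments$frame_index, tc$assignments$animal)))
  tid <- unlist(lapply(tracks, function(tc)
    rep(tc$track_id, nrow(tc$assignments))))
  truth$track <- tid[match(paste(truth$frame_index, truth$animal), key)]
  switches <- 0L
  for (cid in unique(truth$cow_id)) {
    tr <- truth[truth$cow_id == cid, ]
    tr <- tr[order(tr$frame_index), ]
    ids <- tr$track[!is.na(tr$track)]
    if (length(ids) > 1L) switches <- switches + sum(diff(ids) != 0L)
  }
  switches
}
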