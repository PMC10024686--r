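# Domain types and I/O for per-frame cattle pose keypoints and mobility scores.

#' Canonical keypoint names
#'
#' The 15 anatomical landmarks annotated on each cow, in canonical order.
#' The order is stable across all readers and writers; every pose object
#' stores its coordinates in this order.
#'
#' @return Character vector of length 15.
#' @export
#' @examples
#' keypoint_names()
keypoint_names <- function() {
  c("nose", "head", "scapula", "withers", "back_centre",
    "hook_bone", "tail_setting",
    "knee_front_left", "knee_front_right", "knee_hind_left", "knee_hind_right",
    "hoof_front_left", "hoof_front_right", "hoof_hind_left", "hoof_hind_right")
}

#' Names of the five back (topline) keypoints
#'
#' Ordered rear-to-front along the dorsal line: tail setting, hook bone,
#' centre of the back, withers, scapula (lower neck). The chord joining the
#' first and last of these is the baseline used for area features.
#'
#' @return Character vector of length 5.
#' @export
back_point_names <- function() {
  c("tail_setting", "hook_bone", "back_centre", "withers", "scapula")
}

# Visibility codes follow the COCO keypoint convention.
VIS_ABSENT <- 0L
VIS_OCCLUDED <- 1L
VIS_VISIBLE <- 2L

#' Construct a single-animal pose for one frame
#'
#' Coordinates use image conventions: origin top-left, y increases downward.
#'
#' @param points Numeric 15 x 2 matrix of (x, y) pixel coordinates, rows in
#'   canonical [keypoint_names()] order. Rows for absent points may be `NA`.
#' @param visibility Integer vector of length 15: 0 absent, 1 occluded,
#'   2 visible. Defaults to all visible.
#' @param frame_index Non-negative integer frame number.
#' @param track_id Optional integer identity, `NA` when not yet tracked.
#' @return An object of class `cow_pose`.
#' @export
cow_pose <- function(points, visibility = rep(VIS_VISIBLE, 15L),
                     frame_index = 0L, track_id = NA_integer_) {
  points <- as.matrix(points)
  if (!is.numeric(points) || nrow(points) != 15L || ncol(points) != 2L)
    stop("`points` must be a numeric 15 x 2 matrix (x, y)")
  visibility <- as.integer(visibility)
  if (length(visibility) != 15L || anyNA(visibility) ||
      any(!visibility %in% c(VIS_ABSENT, VIS_OCCLUDED, VIS_VISIBLE)))
    stop("`visibility` must be 15 integers in {0, 1, 2}")
  has_coord <- visibility != VIS_ABSENT
  if (any(!is.finite(points[has_coord, , drop = FALSE])))
    stop("non-finite coordinates for a point not marked absent")
  points[!has_coord, ] <- NA_real_
  dimnames(points) <- list(keypoint_names(), c("x", "y"))
  frame_index <- as.integer(frame_index)
  if (is.na(frame_index) || frame_index < 0L)
    stop("`frame_index` must be a non-negative integer")
  structure(list(points = points, visibility = visibility,
                 frame_index = frame_index,
                 track_id = as.integer(track_id)),
            class = "cow_pose")
}

#' @export
print.cow_pose <- function(x, ...) {
  nv <- sum(x$visibility == VIS_VISIBLE)
  cat(sprintf("<cow_pose> frame %d, track %s, %d/15 visible\n",
              x$frame_index,
              if (is.na(x$track_id)) "?" else x$track_id, nv))
  invisible(x)
}

#' Construct a frame set (one video sequence of per-frame poses)
#'
#' @param sequence_id Character identifier.
#' @param fps Frames per second, > 0.
#' @param frames List of frames; each frame is a list with `frame_index`
#'   (integer) and `animals` (list of [cow_pose] objects). Frame indices must
#'   be strictly increasing.
#' @param max_cows Maximum animals allowed in one frame (camera field of
#'   view constraint; default 3 matches a narrow race view, raise it for
#'   simulated wide views).
#' @return An object of class `frame_set`.
#' @export
frame_set <- function(sequence_id, fps, frames, max_cows = 10L) {
  stopifnot(is.character(sequence_id), length(sequence_id) == 1L)
  fps <- as.numeric(fps)
  if (!is.finite(fps) || fps <= 0) stop("`fps` must be > 0")
  idx <- vapply(frames, function(f) as.integer(f$frame_index), integer(1))
  if (length(idx) > 1L && any(diff(idx) <= 0L))
    stop("frame_index must be strictly increasing")
  for (f in frames) {
    if (length(f$animals) > max_cows)
      stop(sprintf("frame %d has %d animals, more than max_cows = %d",
                   f$frame_index, length(f$animals), max_cows))
    ok <- vapply(f$animals, inherits, logical(1), what = "cow_pose")
    if (!all(ok)) stop("all animals must be cow_pose objects")
  }
  structure(list(sequence_id = sequence_id, fps = fps, frames = frames),
            class = "frame_set")
}

#' @export
print.frame_set <- function(x, ...) {
  cat(sprintf("<frame_set> '%s': %d frames @ %g fps\n",
              x$sequence_id, length(x$frames), x$fps))
  invisible(x)
}

#' Tight bounding box over the visible points of a pose
#'
#' @param pose A [cow_pose].
#' @return Named numeric vector `c(x_min, y_min, x_max, y_max)` of class
#'   `bbox`.
#' @export
bbox_from_pose <- function(pose) {
  stopifnot(inherits(pose, "cow_pose"))
  vis <- pose$visibility == VIS_VISIBLE
  if (sum(vis) < 2L)
    stop("degenerate pose: fewer than 2 visible points")
  p <- pose$points[vis, , drop = FALSE]
  structure(c(x_min = min(p[, "x"]), y_min = min(p[, "y"]),
              x_max = max(p[, "x"]), y_max = max(p[, "y"])),
            class = "bbox")
}

#' Read keypoint sequences from the package's JSON dialect
#'
#' The file layout is
#' `{"sequences": [{"sequence_id", "fps", "keypoint_names", "frames":
#' [{"frame_index", "animals": [{"track_id", "keypoints": [[x, y, v] x 15]}]}]}]}`
#' with visibility `v`: 0 absent, 1 occluded, 2 visible.
#'
#' @param path Path to a JSON file.
#' @return List of [frame_set] objects.
#' @seealso [write_keypoint_sequences()]
#' @export
read_keypoint_sequences <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  doc <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  if (is.null(doc$sequences)) stop("malformed keypoint file: no 'sequences'")
  lapply(doc$sequences, function(sq) {
    kn <- unlist(sq$keypoint_names)
    if (!identical(kn, keypoint_names()))
      stop(sprintf("sequence '%s': keypoint_names differ from canonical order",
                   sq$sequence_id))
    frames <- lapply(sq$frames, function(fr) {
      animals <- lapply(seq_along(fr$animals), function(ai) {
        an <- fr$animals[[ai]]
        kp <- an$keypoints
        if (length(kp) != 15L)
          stop(sprintf(
            "sequence '%s' frame %d animal %d: expected 15 keypoints, got %d",
            sq$sequence_id, fr$frame_index, ai, length(kp)))
        m <- do.call(rbind, lapply(kp, function(t) as.numeric(unlist(t))))
        if (ncol(m) != 3L)
          stop(sprintf(
            "sequence '%s' frame %d animal %d: keypoints must be [x, y, v]",
            sq$sequence_id, fr$frame_index, ai))
        tid <- if (is.null(an$track_id)) NA_integer_ else as.integer(an$track_id)
        cow_pose(m[, 1:2, drop = FALSE], visibility = as.integer(m[, 3]),
                 frame_index = fr$frame_index, track_id = tid)
      })
      list(frame_index = as.integer(fr$frame_index), animals = animals)
    })
    frame_set(sq$sequence_id, sq$fps, frames)
  })
}

#' Write keypoint sequences to the package's JSON dialect
#'
#' Coordinates are written at full double precision so that
#' `read_keypoint_sequences(write_keypoint_sequences(x))` reproduces them
#' bit-for-bit. Absent points are written as `[0, 0, 0]`.
#'
#' @param data List of [frame_set] objects.
#' @param path Output file path.
#' @return Invisibly, `path`.
#' @export
write_keypoint_sequences <- function(data, path) {
  stopifnot(is.list(data))
  seqs <- lapply(data, function(fs) {
    stopifnot(inherits(fs, "frame_set"))
    frames <- lapply(fs$frames, function(fr) {
      animals <- lapply(fr$animals, function(p) {
        pts <- p$points
        pts[p$visibility == VIS_ABSENT, ] <- 0
        kp <- lapply(seq_len(15L), function(i)
          c(pts[i, 1], pts[i, 2], p$visibility[i]))
        list(track_id = if (is.na(p$track_id)) NULL else p$track_id,
             keypoints = kp)
      })
      list(frame_index = fr$frame_index, animals = animals)
    })
    list(sequence_id = fs$sequence_id, fps = fs$fps,
         keypoint_names = keypoint_names(), frames = frames)
  })
  json <- jsonlite::toJSON(list(sequences = seqs), auto_unbox = TRUE,
                           digits = I(17), null = "null")
  writeLines(json, path, useBytes = TRUE)
  invisible(path)
}

#' Read a mobility score table
#'
#' Expects a CSV with header `cow_id,scorer_1,scorer_2,scorer_3,consolidated`;
#' trailing scorer columns and the consolidated column may be empty. Scores
#' are integers on the 4-point AHDB mobility scale (0 good mobility .. 3
#' severely impaired).
#'
#' @param path Path to the CSV file.
#' @return A data.frame with columns `cow_id`, one `scorer_<i>` column per
#'   rater, and `consolidated` (`NA` where unset).
#' @export
read_scores <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        colClasses = "character")
  if (!"cow_id" %in% names(df)) stop("scores CSV must have a cow_id column")
  scorer_cols <- grep("^scorer_", names(df), value = TRUE)
  if (length(scorer_cols) == 0L) stop("scores CSV must have scorer_* columns")
  out <- data.frame(cow_id = df$cow_id, stringsAsFactors = FALSE)
  parse_col <- function(v, what) {
    v[!nzchar(trimws(v))] <- NA
    x <- suppressWarnings(as.integer(v))
    bad <- which((!is.na(v) & is.na(x)) | (!is.na(x) & (x < 0L | x > 3L)))
    if (length(bad))
      stop(sprintf("invalid %s score '%s' at row %d (must be 0-3)",
                   what, v[bad[1]], bad[1]))
    x
  }
  for (sc in scorer_cols) out[[sc]] <- parse_col(df[[sc]], sc)
  n_scores <- rowSums(!is.na(out[scorer_cols]))
  if (any(n_scores == 0L))
    stop(sprintf("row %d has no rater scores", which(n_scores == 0L)[1]))
  out$consolidated <- if ("consolidated" %in% names(df))
    parse_col(df$consolidated, "consolidated") else NA_integer_
  out
}

#' Write a mobility score table
#'
#' Inverse of [read_scores()].
#'
#' @param scores Data.frame as returned by [read_scores()].
#' @param path Output CSV path.
#' @return Invisibly, `path`.
#' @export
write_scores <- function(scores, path) {
  utils::write.csv(scores, path, row.names = FALSE, na = "")
  invisible(path)
}
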