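# Per-frame kinematic features from a single pose: back-line regression and
# RMSE, topline area sections, signed head/nose elevation, neck angle.
# All geometry is computed in image coordinates (origin top-left, y down).

#' Least-squares line through the five back points
#'
#' Ordinary least squares of y on x through the topline keypoints (tail
#' setting, hook bone, back centre, withers, scapula). The root mean squared
#' error of the vertical residuals quantifies back arching: a flat, well
#' postured back gives RMSE near 0, an arched back a large RMSE.
#'
#' @param back_points Numeric 5 x 2 matrix of (x, y), rows ordered tail
#'   setting to scapula.
#' @return List of class `back_fit`: `slope`, `intercept`, `residuals`
#'   (y_keypoint - y_line, length 5), `rmse`, `n`.
#' @export
fit_back_line <- function(back_points) {
  p <- as.matrix(back_points)
  if (nrow(p) != 5L || ncol(p) != 2L || !is.numeric(p))
    stop("`back_points` must be a numeric 5 x 2 matrix")
  x <- p[, 1]; y <- p[, 2]
  if (max(x) - min(x) <= 0)
    stop("degenerate back configuration: no x spread (vertical topline)")
  xc <- x - mean(x)
  slope <- sum(xc * y) / sum(xc^2)
  intercept <- mean(y) - slope * mean(x)
  res <- y - (intercept + slope * x)
  structure(list(slope = slope, intercept = intercept, residuals = res,
                 rmse = sqrt(mean(res^2)), n = 5L),
            class = "back_fit")
}

#' Area sections under the back topline
#'
#' The baseline is the chord from the tail setting to the scapula. The three
#' intermediate keypoints are projected onto the baseline axis and their
#' perpendicular heights above it taken (signed: a sway-backed segment below
#' the baseline contributes negative area). The enclosed area is accumulated
#' as trapezoids between consecutive projections, split into three named
#' sections: rear (tail setting -> hook bone -> back centre), front (back
#' centre -> withers) and neck (withers -> scapula). "Above" means the side
#' of the baseline away from increasing y, i.e. physically upward in image
#' coordinates.
#'
#' @param back_points Numeric 5 x 2 matrix (x, y), tail setting to scapula.
#' @return List of class `area_sections`: `back_hip_to_centre`,
#'   `front_shoulder_to_centre`, `neck_to_shoulder`, `total` (pixels^2).
#' @export
back_areas <- function(back_points) {
  p <- as.matrix(back_points)
  if (nrow(p) != 5L || ncol(p) != 2L || !is.numeric(p))
    stop("`back_points` must be a numeric 5 x 2 matrix")
  d <- p[5, ] - p[1, ]
  len <- sqrt(sum(d^2))
  if (len <= 0) stop("degenerate baseline: tail setting equals scapula")
  u <- d / len                    # along baseline
  up <- c(u[2], -u[1])            # perpendicular, pointing upward (y down)
  rel <- sweep(p, 2, p[1, ])
  tcoord <- rel %*% u             # position along baseline
  h <- rel %*% up                 # signed height above baseline
  trap <- unname(diff(tcoord[, 1]) * (h[-5, 1] + h[-1, 1]) / 2)
  structure(list(back_hip_to_centre = trap[1] + trap[2],
                 front_shoulder_to_centre = trap[3],
                 neck_to_shoulder = trap[4],
                 total = sum(trap)),
            class = "area_sections")
}

#' Signed squared elevation of head and nose above the back line
#'
#' The back regression line is extended forward past the scapula and
#' evaluated at the head and nose x positions. Each elevation is the squared
#' vertical distance to the line, negated when the point lies below it
#' (y_line < y_keypoint in image coordinates means the keypoint is
#' physically lower than the line). A lame cow carrying its head low thus
#' yields negative values; `combined` is the mean of the head and nose
#' values.
#'
#' @param fit A `back_fit` from [fit_back_line()].
#' @param head,nose Numeric length-2 (x, y) coordinates.
#' @return List of class `head_elevation`: `head_pos`, `nose_pos`,
#'   `combined` (signed pixels^2).
#' @export
head_nose_pos <- function(fit, head, nose) {
  stopifnot(inherits(fit, "back_fit"))
  pos1 <- function(pt) {
    y_line <- fit$intercept + fit$slope * unname(pt[1])
    d <- y_line - unname(pt[2])
    if (d < 0) -(d^2) else d^2
  }
  hp <- pos1(head); np <- pos1(nose)
  structure(list(head_pos = hp, nose_pos = np, combined = (hp + np) / 2),
            class = "head_elevation")
}

#' Angle of the neck relative to the back
#'
#' Computes the gradient `m1` of the withers -> scapula segment (the front
#' of the back) and `m2` of the scapula -> head segment (the neck), then the
#' angle between the two lines, `atan((m1 - m2) / (1 + m1 * m2))`. When the
#' lines are perpendicular (`1 + m1 * m2 = 0`) the angle is +/- pi/2 by the
#' sign of `m1 - m2`.
#'
#' @param withers,scapula,head Numeric length-2 (x, y) coordinates.
#' @return List of class `neck_geometry`: `m1`, `m2`, `angle` (radians).
#' @export
neck_angle <- function(withers, scapula, head) {
  grad <- function(a, b, what) {
    dx <- b[1] - a[1]
    if (dx == 0) stop("vertical segment: ", what)
    (b[2] - a[2]) / dx
  }
  m1 <- grad(withers, scapula, "withers -> scapula (back)")
  m2 <- grad(scapula, head, "scapula -> head (neck)")
  denom <- 1 + m1 * m2
  ang <- if (abs(denom) < 1e-12) sign(m1 - m2) * pi / 2
         else atan((m1 - m2) / denom)
  structure(list(m1 = m1, m2 = m2, angle = ang), class = "neck_geometry")
}

#' All per-frame kinematic features for one pose
#'
#' Each feature is computed only when all of its required keypoints are
#' visible; otherwise it is `NA` and its validity flag `FALSE`. Missing
#' points never raise an error here.
#'
#' @param pose A [cow_pose].
#' @return One-row data.frame: `frame_index`, `back_rmse`,
#'   `area_hip_centre`, `area_shoulder_centre`, `area_neck_shoulder`,
#'   `area_total`, `head_nose_pos`, `neck_angle`, and logical
#'   `valid_back`, `valid_head`, `valid_neck`.
#' @export
frame_features <- function(pose) {
  stopifnot(inherits(pose, "cow_pose"))
  vis <- pose$visibility == VIS_VISIBLE
  names(vis) <- keypoint_names()
  out <- data.frame(frame_index = pose$frame_index,
                    back_rmse = NA_real_, area_hip_centre = NA_real_,
                    area_shoulder_centre = NA_real_,
                    area_neck_shoulder = NA_real_, area_total = NA_real_,
                    head_nose_pos = NA_real_, neck_angle = NA_real_,
                    valid_back = FALSE, valid_head = FALSE,
                    valid_neck = FALSE)
  back_ok <- all(vis[back_point_names()])
  fit <- NULL
  if (back_ok) {
    bp <- pose$points[back_point_names(), , drop = FALSE]
    fit <- try(fit_back_line(bp), silent = TRUE)
    ar <- try(back_areas(bp), silent = TRUE)
    if (!inherits(fit, "try-error") && !inherits(ar, "try-error")) {
      out$back_rmse <- fit$rmse
      out$area_hip_centre <- ar$back_hip_to_centre
      out$area_shoulder_centre <- ar$front_shoulder_to_centre
      out$area_neck_shoulder <- ar$neck_to_shoulder
      out$area_total <- ar$total
      out$valid_back <- TRUE
    } else fit <- NULL
  }
  if (!is.null(fit) && vis["head"] && vis["nose"]) {
    he <- head_nose_pos(fit, pose$points["head", ], pose$points["nose", ])
    out$head_nose_pos <- he$combined
    out$valid_head <- TRUE
  }
  if (vis["withers"] && vis["scapula"] && vis["head"]) {
    ng <- try(neck_angle(pose$points["withers", ], pose$points["scapula", ],
                         pose$points["head", ]), silent = TRUE)
    if (!inherits(ng, "try-error")) {
      out$neck_angle <- ng$angle
      out$valid_neck <- TRUE
    }
  }
  out
}

#' Normalize a track's travel direction to +x
#'
#' If the net horizontal displacement of a track is negative, every x
#' coordinate is mirrored (negated) so that all cows travel toward +x. This
#' makes the sign of the neck gradients comparable across camera
#' orientations; RMSE and areas are unaffected by the mirroring.
#'
#' @param tc A `tracked_cow`.
#' @return The track, possibly mirrored.
#' @export
normalize_travel_direction <- function(tc) {
  stopifnot(inherits(tc, "tracked_cow"))
  n <- length(tc$poses)
  if (n < 2L) return(tc)
  centre_x <- function(p) mean(p$points[p$visibility != VIS_ABSENT, "x"],
                               na.rm = TRUE)
  if (centre_x(tc$poses[[n]]) >= centre_x(tc$poses[[1]])) return(tc)
  tc$poses <- lapply(tc$poses, function(p) {
    p$points[, "x"] <- -p$points[, "x"]
    p
  })
  tc
}

#' Per-frame feature table for a whole track
#'
#' Computes [frame_features()] for every pose of a track (after
#' [normalize_travel_direction()]), assembling the result in one pass.
#'
#' @param tc A `tracked_cow`.
#' @return Data.frame with one row per frame plus `track_id` and `cow_id`
#'   columns.
#' @export
track_features <- function(tc) {
  stopifnot(inherits(tc, "tracked_cow"))
  tc <- normalize_travel_direction(tc)
  n <- length(tc$poses)
  num <- matrix(NA_real_, n, 7L)
  flags <- matrix(FALSE, n, 3L)
  fidx <- integer(n)
  bidx <- match(back_point_names(), keypoint_names())
  widx <- match(c("withers", "scapula", "head", "nose"), keypoint_names())
  for (k in seq_len(n)) {
    p <- tc$poses[[k]]
    fidx[k] <- p$frame_index
    vis <- p$visibility == VIS_VISIBLE
    fit <- NULL
    if (all(vis[bidx])) {
      bp <- p$points[bidx, , drop = FALSE]
      fit <- try(fit_back_line(bp), silent = TRUE)
      ar <- try(back_areas(bp), silent = TRUE)
      if (!inherits(fit, "try-error") && !inherits(ar, "try-error")) {
        num[k, 1] <- fit$rmse
        num[k, 2] <- ar$back_hip_to_centre
        num[k, 3] <- ar$front_shoulder_to_centre
        num[k, 4] <- ar$neck_to_shoulder
        num[k, 5] <- ar$total
        flags[k, 1] <- TRUE
      } else fit <- NULL
    }
    if (!is.null(fit) && vis[widx[3]] && vis[widx[4]]) {
      he <- head_nose_pos(fit, p$points[widx[3], ], p$points[widx[4], ])
      num[k, 6] <- he$combined
      flags[k, 2] <- TRUE
    }
    if (vis[widx[1]] && vis[widx[2]] && vis[widx[3]]) {
      ng <- try(neck_angle(p$points[widx[1], ], p$points[widx[2], ],
                           p$points[widx[3], ]), silent = TRUE)
      if (!inherits(ng, "try-error")) {
        num[k, 7] <- ng$angle
        flags[k, 3] <- TRUE
      }
    }
  }
  data.frame(frame_index = fidx,
             back_rmse = num[, 1], area_hip_centre = num[, 2],
             area_shoulder_centre = num[, 3], area_neck_shoulder = num[, 4],
             area_total = num[, 5], head_nose_pos = num[, 6],
             neck_angle = num[, 7],
             valid_back = flags[, 1], valid_head = flags[, 2],
             valid_neck = flags[, 3],
             track_id = tc$track_id,
             cow_id = if (is.null(tc$cow_id)) NA_character_ else tc$cow_id)
}
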