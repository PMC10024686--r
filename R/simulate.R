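# Synthetic gait simulator: keypoint trajectories for cows crossing a fixed
# camera view, with mobility-score-dependent back arch, spine flexing, head
# drop/bob and walking speed, plus simulated mobility raters.

#' Gait simulation parameters
#'
#' All `*_by_score` vectors hold one value per mobility score 0..3.
#' Amplitudes are in pixels in the image frame (y increases downward), speeds
#' in pixels/frame. Defaults encode the qualitative structure the analysis
#' relies on: arch height, spine flexing and head bobbing increase with the
#' mobility score, head carriage drops, and walking speed decreases.
#'
#' @param body_length Back chord length (tail setting to scapula), pixels.
#' @param baseline_height Vertical image position of the resting topline.
#' @param arch_amplitude_by_score Static peak back-arch height per score.
#' @param flex_amplitude_by_score Amplitude of the sinusoidal arch
#'   modulation (spine flexing over the stride cycle) per score.
#' @param head_drop_by_score Mean head elevation above the topline, pixels;
#'   negative means the head is carried below the back line.
#' @param head_bob_amplitude_by_score Head bob amplitude per score.
#' @param speed_by_score Walking speed per score, pixels/frame.
#' @param stride_frequency Stride cycles per second.
#' @param keypoint_noise_sd SD of i.i.d. Gaussian jitter added to every
#'   coordinate (detection noise).
#' @param fps Frames per second.
#' @param rater_error_prob Probability that a simulated rater deviates from
#'   the true score by one point (result clamped to 0..3).
#' @return A list of class `gait_params`.
#' @export
gait_params <- function(body_length = 400,
                        baseline_height = 300,
                        arch_amplitude_by_score = c(0, 3, 7, 12),
                        flex_amplitude_by_score = c(0.5, 1.5, 3, 6),
                        head_drop_by_score = c(25, 10, -5, -25),
                        head_bob_amplitude_by_score = c(1, 3, 7, 14),
                        speed_by_score = c(6, 5, 4, 2.5),
                        stride_frequency = 1.2,
                        keypoint_noise_sd = 1.0,
                        fps = 30,
                        rater_error_prob = 0.15) {
  p <- list(body_length = body_length, baseline_height = baseline_height,
            arch_amplitude_by_score = arch_amplitude_by_score,
            flex_amplitude_by_score = flex_amplitude_by_score,
            head_drop_by_score = head_drop_by_score,
            head_bob_amplitude_by_score = head_bob_amplitude_by_score,
            speed_by_score = speed_by_score,
            stride_frequency = stride_frequency,
            keypoint_noise_sd = keypoint_noise_sd,
            fps = fps, rater_error_prob = rater_error_prob)
  for (f in c("arch_amplitude_by_score", "flex_amplitude_by_score",
              "head_bob_amplitude_by_score", "speed_by_score",
              "head_drop_by_score"))
    if (length(p[[f]]) != 4L || !is.numeric(p[[f]]))
      stop(f, " must be 4 numbers (one per score 0-3)")
  if (any(p$arch_amplitude_by_score < 0) || any(p$flex_amplitude_by_score < 0) ||
      any(p$head_bob_amplitude_by_score < 0))
    stop("amplitudes must be >= 0")
  if (any(p$speed_by_score <= 0)) stop("speeds must be > 0")
  if (p$keypoint_noise_sd < 0) stop("keypoint_noise_sd must be >= 0")
  if (p$rater_error_prob < 0 || p$rater_error_prob > 1)
    stop("rater_error_prob must be in [0, 1]")
  class(p) <- "gait_params"
  p
}

#' Scale the score-dependent gait effects
#'
#' Shrinks or stretches every `*_by_score` vector about its mean by `scale`.
#' At `scale = 0` all four scores produce statistically identical gaits (a
#' null cohort); `scale = 1` returns the parameters unchanged. Amplitudes
#' are floored at 0 and speeds at 0.5 px/frame.
#'
#' @param params A [gait_params] object.
#' @param scale Non-negative multiplier of the between-score effect size.
#' @return A modified `gait_params` object.
#' @export
scale_gait_effects <- function(params, scale) {
  stopifnot(inherits(params, "gait_params"), scale >= 0)
  sc <- function(v) mean(v) + scale * (v - mean(v))
  params$arch_amplitude_by_score <- pmax(0, sc(params$arch_amplitude_by_score))
  params$flex_amplitude_by_score <- pmax(0, sc(params$flex_amplitude_by_score))
  params$head_bob_amplitude_by_score <-
    pmax(0, sc(params$head_bob_amplitude_by_score))
  params$head_drop_by_score <- sc(params$head_drop_by_score)
  params$speed_by_score <- pmax(0.5, sc(params$speed_by_score))
  params
}

# Build the 15 x 2 coordinate matrix for one cow at one time point.
# tail_x: x of the tail setting; t: time in seconds.
.pose_coords <- function(params, score, tail_x, t, phase) {
  L <- params$body_length
  base <- params$baseline_height
  s <- score + 1L
  peak <- params$arch_amplitude_by_score[s] +
    params$flex_amplitude_by_score[s] *
      sin(2 * pi * params$stride_frequency * t + phase)
  u <- c(0, 0.25, 0.5, 0.75, 1)          # chord fractions tail -> scapula
  h <- peak * 4 * u * (1 - u)            # parabolic topline height
  back_x <- tail_x + u * L
  back_y <- base - h                     # above baseline = smaller y
  head_elev <- params$head_drop_by_score[s] +
    params$head_bob_amplitude_by_score[s] *
      sin(2 * pi * params$stride_frequency * t + phase + pi / 3)
  head_x <- tail_x + 1.12 * L
  head_y <- base - head_elev
  nose_x <- tail_x + 1.22 * L
  nose_y <- head_y + 0.06 * L            # nose slightly below the head
  knee_y <- base + 0.35 * L
  hoof_y <- base + 0.50 * L
  fx <- tail_x + 0.90 * L                # front legs under the shoulder
  hx <- tail_x + 0.08 * L                # hind legs under the pelvis
  off <- 0.03 * L                        # left/right stagger
  m <- matrix(NA_real_, 15L, 2L, dimnames = list(keypoint_names(), c("x", "y")))
  m["nose", ] <- c(nose_x, nose_y)
  m["head", ] <- c(head_x, head_y)
  m["scapula", ] <- c(back_x[5], back_y[5])
  m["withers", ] <- c(back_x[4], back_y[4])
  m["back_centre", ] <- c(back_x[3], back_y[3])
  m["hook_bone", ] <- c(back_x[2], back_y[2])
  m["tail_setting", ] <- c(back_x[1], back_y[1])
  m["knee_front_left", ] <- c(fx - off, knee_y)
  m["knee_front_right", ] <- c(fx + off, knee_y)
  m["knee_hind_left", ] <- c(hx - off, knee_y)
  m["knee_hind_right", ] <- c(hx + off, knee_y)
  m["hoof_front_left", ] <- c(fx - off, hoof_y)
  m["hoof_front_right", ] <- c(fx + off, hoof_y)
  m["hoof_hind_left", ] <- c(hx - off, hoof_y)
  m["hoof_hind_right", ] <- c(hx + off, hoof_y)
  m
}

#' Simulate one cow's tracked pose sequence
#'
#' Deterministic given `seed`. The five back points lie on a parabolic
#' topline whose chord endpoints (tail setting, scapula) sit on the
#' baseline; the arch peak is the static score-dependent amplitude plus a
#' sinusoidal flexing term over the stride cycle. The head and nose ride
#' ahead of the scapula at a score-dependent elevation with sinusoidal
#' bobbing. The whole animal advances by the score-dependent speed each
#' frame, and i.i.d. Gaussian jitter is added to every coordinate.
#'
#' @param params A [gait_params] object.
#' @param score True mobility score, 0..3.
#' @param seed Integer RNG seed.
#' @param start_x Initial x of the tail setting, pixels.
#' @param n_frames Number of frames to simulate.
#' @param cow_id Identifier attached to the track.
#' @param first_frame Frame index of the first simulated frame.
#' @return An object of class `tracked_cow`: fields `track_id`, `cow_id`,
#'   `fps`, `frame_indices`, `poses` (list of [cow_pose]).
#' @export
simulate_cow_track <- function(params, score, seed, start_x = 0,
                               n_frames = 60L, cow_id = "cow1",
                               first_frame = 0L) {
  stopifnot(inherits(params, "gait_params"))
  if (!score %in% 0:3) stop("`score` must be in {0, 1, 2, 3}")
  withr::with_seed(seed, {
    phase <- stats::runif(1, 0, 2 * pi)
    v <- params$speed_by_score[score + 1L]
    poses <- vector("list", n_frames)
    for (k in seq_len(n_frames)) {
      t <- (k - 1L) / params$fps
      m <- .pose_coords(params, score, start_x + v * (k - 1L), t, phase)
      if (params$keypoint_noise_sd > 0)
        m <- m + matrix(stats::rnorm(30L, sd = params$keypoint_noise_sd),
                        15L, 2L)
      poses[[k]] <- cow_pose(m, frame_index = first_frame + k - 1L)
    }
    structure(list(track_id = NA_integer_, cow_id = cow_id, fps = params$fps,
                   frame_indices = first_frame + seq_len(n_frames) - 1L,
                   poses = poses),
              class = "tracked_cow")
  })
}

#' @export
print.tracked_cow <- function(x, ...) {
  cat(sprintf("<tracked_cow> %s (track %s): %d frames @ %g fps\n",
              x$cow_id %||% "?",
              if (is.na(x$track_id)) "?" else x$track_id,
              length(x$poses), x$fps))
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Simulate a single-file multi-cow sequence
#'
#' Cows walk in single file toward +x and cannot pass each other: initial
#' tail-to-tail gaps are sized so the x-extents of consecutive animals stay
#' disjoint over the whole clip even when a faster cow follows a slower one.
#' The per-frame poses carry no track id (the tracker must recover
#' identities); the ground-truth frame-by-frame assignment is attached as
#' attribute `"truth"` (data.frame `frame_index`, `animal`, `cow_id`), and
#' the underlying per-cow tracks as attribute `"tracks"`.
#'
#' @param params A [gait_params] object.
#' @param scores Integer vector (1 to 10 cows) of true mobility scores.
#' @param seed Integer RNG seed.
#' @param n_frames Frames to simulate.
#' @param sequence_id Identifier for the sequence.
#' @param cow_ids Optional character ids, default `cow1..cowN`.
#' @return A [frame_set] with attributes `truth` and `tracks`.
#' @export
simulate_sequence <- function(params, scores, seed, n_frames = 60L,
                              sequence_id = "seq1", cow_ids = NULL) {
  stopifnot(inherits(params, "gait_params"))
  n <- length(scores)
  if (n > 10L) stop("at most 10 cows per sequence")
  if (n == 0L)
    return(frame_set(sequence_id, params$fps, list()))
  if (is.null(cow_ids)) cow_ids <- paste0("cow", seq_len(n))
  stopifnot(length(cow_ids) == n)
  withr::with_seed(seed, {
    cow_seeds <- sample.int(.Machine$integer.max - 1L, n)
    speeds <- params$speed_by_score[scores + 1L]
    # front cow first; gaps absorb any closing speed over the clip
    start_x <- numeric(n)
    start_x[1] <- 0
    if (n > 1L) for (i in 2:n) {
      closing <- max(0, speeds[i] - speeds[i - 1L]) * n_frames
      start_x[i] <- start_x[i - 1L] - (1.4 * params$body_length + closing)
    }
    tracks <- lapply(seq_len(n), function(i)
      simulate_cow_track(params, scores[i], cow_seeds[i], start_x[i],
                         n_frames = n_frames, cow_id = cow_ids[i]))
    truth <- vector("list", n_frames)
    frames <- vector("list", n_frames)
    for (k in seq_len(n_frames)) {
      ord <- sample.int(n)                # detection order is arbitrary
      animals <- lapply(ord, function(i) {
        p <- tracks[[i]]$poses[[k]]
        p$track_id <- NA_integer_
        p
      })
      frames[[k]] <- list(frame_index = k - 1L, animals = animals)
      truth[[k]] <- data.frame(frame_index = k - 1L,
                               animal = seq_len(n),
                               cow_id = cow_ids[ord],
                               stringsAsFactors = FALSE)
    }
    fs <- frame_set(sequence_id, params$fps, frames)
    attr(fs, "truth") <- do.call(rbind, truth)
    attr(fs, "tracks") <- tracks
    fs
  })
}

#' Simulate a scored cohort of cows
#'
#' Draws true mobility scores from `class_probs`, simulates each cow's
#' trajectory (grouped into single-file sequences of up to
#' `cows_per_sequence` animals), and has three simulated raters score each
#' cow: a rater reports the truth, deviating by one point (up or down with
#' equal probability) with probability `rater_error_prob`, clamped to 0..3.
#'
#' The default class probabilities (25.2% / 43.2% / 25.6% / 6.0%) reflect
#' the mobility-score mix of a typical commercial herd where most animals
#' show at most imperfect mobility and severe lameness is rare.
#'
#' @param params A [gait_params] object.
#' @param n_cows Number of cows.
#' @param class_probs Probabilities of true scores 0..3, summing to 1.
#' @param seed Integer RNG seed.
#' @param n_frames Frames per sequence.
#' @param cows_per_sequence Maximum cows per simulated sequence (<= 10).
#' @return An object of class `simulated_cohort`: `frame_sets` (list of
#'   [frame_set]), `tracks` (per-cow [simulate_cow_track] output, ground
#'   truth identities), `truth` (data.frame `cow_id`, `score`), `scores`
#'   (data.frame `cow_id`, `scorer_1..3`, `consolidated`), `params`, `seed`.
#' @export
simulate_cohort <- function(params, n_cows,
                            class_probs = c(0.252, 0.432, 0.256, 0.060),
                            seed = 1L, n_frames = 60L,
                            cows_per_sequence = 10L) {
  stopifnot(inherits(params, "gait_params"), n_cows >= 1L)
  if (length(class_probs) != 4L || any(class_probs < 0) ||
      abs(sum(class_probs) - 1) > 1e-9)
    stop("`class_probs` must be 4 non-negative numbers summing to 1")
  stopifnot(cows_per_sequence >= 1L, cows_per_sequence <= 10L)
  withr::with_seed(seed, {
    truth_scores <- sample(0:3, n_cows, replace = TRUE, prob = class_probs)
    cow_ids <- sprintf("cow%03d", seq_len(n_cows))
    groups <- split(seq_len(n_cows),
                    ceiling(seq_len(n_cows) / cows_per_sequence))
    seq_seeds <- sample.int(.Machine$integer.max - 1L, length(groups))
    frame_sets <- vector("list", length(groups))
    for (g in seq_along(groups)) {
      idx <- groups[[g]]
      frame_sets[[g]] <- simulate_sequence(
        params, truth_scores[idx], seq_seeds[g], n_frames = n_frames,
        sequence_id = sprintf("seq%03d", g), cow_ids = cow_ids[idx])
    }
    tracks <- unlist(lapply(frame_sets, attr, which = "tracks"),
                     recursive = FALSE)
    rate <- function() {
      dev <- stats::rbinom(n_cows, 1L, params$rater_error_prob) *
        sample(c(-1L, 1L), n_cows, replace = TRUE)
      pmin(3L, pmax(0L, truth_scores + dev))
    }
    scores <- data.frame(cow_id = cow_ids,
                         scorer_1 = rate(), scorer_2 = rate(),
                         scorer_3 = rate(), stringsAsFactors = FALSE)
    scores$consolidated <- vapply(seq_len(n_cows), function(i)
      consolidate_scores(c(scores$scorer_1[i], scores$scorer_2[i],
                           scores$scorer_3[i])), integer(1))
    structure(list(frame_sets = frame_sets, tracks = tracks,
                   truth = data.frame(cow_id = cow_ids, score = truth_scores,
                                      stringsAsFactors = FALSE),
                   scores = scores, params = params, seed = seed),
              class = "simulated_cohort")
  })
}

#' @export
print.simulated_cohort <- function(x, ...) {
  cat(sprintf("<simulated_cohort> %d cows in %d sequences (seed %d)\n",
              nrow(x$truth), length(x$frame_sets), x$seed))
  print(table(score = x$truth$score))
  invisible(x)
}
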