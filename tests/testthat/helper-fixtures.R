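# Shared fixtures built in code.

# A pose with every keypoint at a distinct position; back points on an
# arched topline (image coords, baseline y = 100), head/nose ahead of the
# scapula.
make_test_pose <- function(arch = 10, baseline = 100, frame_index = 0L,
                           visibility = rep(2L, 15L)) {
  m <- matrix(NA_real_, 15L, 2L,
              dimnames = list(keypoint_names(), c("x", "y")))
  u <- c(0, 0.25, 0.5, 0.75, 1)
  bx <- u * 200
  by <- baseline - arch * 4 * u * (1 - u)
  m["tail_setting", ] <- c(bx[1], by[1])
  m["hook_bone", ] <- c(bx[2], by[2])
  m["back_centre", ] <- c(bx[3], by[3])
  m["withers", ] <- c(bx[4], by[4])
  m["scapula", ] <- c(bx[5], by[5])
  m["head", ] <- c(230, baseline - 20)
  m["nose", ] <- c(250, baseline - 5)
  m["knee_front_left", ] <- c(170, baseline + 60)
  m["knee_front_right", ] <- c(175, baseline + 60)
  m["knee_hind_left", ] <- c(20, baseline + 60)
  m["knee_hind_right", ] <- c(25, baseline + 60)
  m["hoof_front_left", ] <- c(170, baseline + 90)
  m["hoof_front_right", ] <- c(175, baseline + 90)
  m["hoof_hind_left", ] <- c(20, baseline + 90)
  m["hoof_hind_right", ] <- c(25, baseline + 90)
  cow_pose(m, visibility = visibility, frame_index = frame_index)
}

# Random topline with positive arch heights over a horizontal baseline,
# in image coordinates (above the baseline = smaller y).
random_arched_topline <- function() {
  x <- sort(stats::runif(5, 0, 100))
  while (max(x) - min(x) < 1) x <- sort(stats::runif(5, 0, 100))
  h <- c(0, stats::runif(3, 0, 30), 0)
  cbind(x, 50 - h)
}

# Brute-force minimal assignment cost by permutation enumeration.
brute_force_assignment <- function(cost) {
  nr <- nrow(cost); nc <- ncol(cost)
  stopifnot(nr <= nc)
  perms <- function(v) {
    if (length(v) <= 1L) return(list(v))
    out <- list()
    for (i in seq_along(v))
      for (p in perms(v[-i])) out[[length(out) + 1L]] <- c(v[i], p)
    out
  }
  best <- Inf
  for (p in perms(seq_len(nc))) {
    cols <- p[seq_len(nr)]
    s <- sum(cost[cbind(seq_len(nr), cols)])
    if (s < best) best <- s
  }
  best
}

# Kendall's W straight from its definition (tie-corrected), independent of
# the package implementation.
kendalls_w_definition <- function(ratings) {
  m <- nrow(ratings); n <- ncol(ratings)
  ranks <- t(apply(ratings, 1, rank))
  R <- colSums(ranks)
  S <- sum((R - m * (n + 1) / 2)^2)
  Tj <- sum(apply(ranks, 1, function(r) {
    tt <- table(r); sum(tt^3 - tt)
  }))
  12 * S / (m^2 * (n^3 - n) - m * Tj)
}
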