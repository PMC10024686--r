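# Per-frame kinematics: back-line fit and RMSE, area sections, signed head
# elevation, neck angle, and their invariances.

test_that("back-line fit recovers collinear points exactly", {
  x <- 0:4
  f <- fit_back_line(cbind(x, 2 * x + 1))
  expect_equal(f$slope, 2)
  expect_equal(f$intercept, 1)
  expect_equal(f$rmse, 0)
  expect_equal(f$residuals, rep(0, 5))
})

test_that("back-line fit matches hand-computed least squares", {
  f <- fit_back_line(cbind(0:4, c(0, 1, 0, 1, 0)))
  expect_equal(f$slope, 0)
  expect_equal(f$intercept, 0.4)
  expect_equal(f$residuals, c(-0.4, 0.6, -0.4, 0.6, -0.4))
  expect_equal(f$rmse, sqrt(0.24), tolerance = 1e-12)

  f2 <- fit_back_line(cbind(0:4, c(0, 1.5, 2, 1.5, 0)))
  expect_equal(f2$rmse, 0.8366600265340755, tolerance = 1e-12)
  expect_gt(f2$rmse, f$rmse)  # taller arch, larger RMSE
})

test_that("degenerate x configurations are rejected", {
  expect_error(fit_back_line(cbind(rep(1, 5), 1:5)), "degenerate")
  expect_error(back_areas(matrix(1, 5, 2)), "baseline")
})

test_that("area sections match the hand-worked trapezoid example", {
  # arch of heights (0,1,2,1,0) above a horizontal baseline (image coords)
  a <- back_areas(cbind(0:4, c(0, -1, -2, -1, 0)))
  expect_equal(a$back_hip_to_centre, 2.0)
  expect_equal(a$front_shoulder_to_centre, 1.5)
  expect_equal(a$neck_to_shoulder, 0.5)
  expect_equal(a$total, 4.0)
  # the three sections exhaust the total
  expect_equal(a$back_hip_to_centre + a$front_shoulder_to_centre +
                 a$neck_to_shoulder, a$total, tolerance = 1e-12)

  flat <- back_areas(cbind(0:4, rep(7, 5)))
  expect_equal(flat$total, 0)
})

test_that("areas are invariant to rigid rotation and translation", {
  pts <- cbind(0:4, c(0, -1, -2, -1, 0))
  ref <- back_areas(pts)
  set.seed(5)
  for (i in 1:10) {
    th <- runif(1, -pi, pi)
    R <- matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2, 2)
    moved <- pts %*% t(R) + matrix(runif(2, -50, 50), 5, 2, byrow = TRUE)
    got <- back_areas(moved)
    expect_equal(got$total, ref$total, tolerance = 1e-9)
    expect_equal(got$back_hip_to_centre, ref$back_hip_to_centre,
                 tolerance = 1e-9)
  }
})

test_that("total area equals the shoelace polygon area for arched toplines", {
  set.seed(31)
  for (i in 1:200) {
    pts <- random_arched_topline()
    got <- back_areas(pts)$total
    # shoelace of the closed polygon (orientation-independent magnitude)
    x <- pts[, 1]; y <- pts[, 2]
    shoelace <- abs(sum(x * c(y[-1], y[1]) - c(x[-1], x[1]) * y)) / 2
    expect_equal(got, shoelace, tolerance = 1e-9)
  }
})

test_that("RMSE equals a brute-force residual computation", {
  set.seed(77)
  for (i in 1:200) {
    pts <- cbind(sort(runif(5, 0, 50)) + c(0, 1, 2, 3, 4), rnorm(5, 0, 10))
    f <- fit_back_line(pts)
    co <- stats::lm.fit(cbind(1, pts[, 1]), pts[, 2])$coefficients
    res <- pts[, 2] - (co[1] + co[2] * pts[, 1])
    expect_equal(f$rmse, sqrt(mean(res^2)), tolerance = 1e-12)
  }
})

test_that("head/nose elevation carries the stated sign convention", {
  fit <- fit_back_line(cbind(0:4, rep(10, 5)))  # horizontal line y = 10
  expect_equal(head_nose_pos(fit, head = c(6, 7), nose = c(7, 7))$head_pos, 9)
  expect_equal(head_nose_pos(fit, head = c(6, 13), nose = c(7, 7))$head_pos, -9)
  expect_equal(head_nose_pos(fit, head = c(6, 10), nose = c(7, 10))$combined, 0)
  # antisymmetry under reflection about the line
  set.seed(2)
  for (i in 1:20) {
    dy <- runif(1, 0, 8)
    up <- head_nose_pos(fit, c(6, 10 - dy), c(7, 10 - dy))
    dn <- head_nose_pos(fit, c(6, 10 + dy), c(7, 10 + dy))
    expect_equal(up$combined, -dn$combined, tolerance = 1e-12)
  }
  # combined is the mean of the two signed values
  he <- head_nose_pos(fit, c(6, 7), c(7, 13))
  expect_equal(he$combined, (9 - 9) / 2)
})

test_that("neck angle follows the angle-between-lines identity", {
  # m1 = 1, m2 = 0
  ng <- neck_angle(withers = c(0, 0), scapula = c(1, 1), head = c(2, 1))
  expect_equal(ng$m1, 1); expect_equal(ng$m2, 0)
  expect_equal(ng$angle, pi / 4, tolerance = 1e-12)
  # m1 = m2 -> 0
  ng0 <- neck_angle(c(0, 0), c(1, 1), c(2, 2))
  expect_equal(ng0$angle, 0)
  # antisymmetric counterpart: m1 = 0, m2 = 1
  ngm <- neck_angle(c(0, 1), c(1, 1), c(2, 2))
  expect_equal(ngm$angle, -pi / 4, tolerance = 1e-12)
  # perpendicular: m1 = 2, m2 = -1/2 -> +pi/2 by sign of m1 - m2
  ngp <- neck_angle(c(0, 0), c(1, 2), c(3, 1))
  expect_equal(ngp$angle, pi / 2)
  expect_error(neck_angle(c(0, 0), c(0, 1), c(1, 2)), "vertical")
})

test_that("frame_features respects visibility and composes the parts", {
  # head absent: back features set, head/neck unset
  vis <- rep(2L, 15L)
  vis[match(c("head", "nose"), keypoint_names())] <- 0L
  ff <- frame_features(make_test_pose(visibility = vis))
  expect_true(ff$valid_back)
  expect_false(ff$valid_head)
  expect_false(ff$valid_neck)
  expect_true(is.na(ff$head_nose_pos))

  # fully visible: equals the component operations
  p <- make_test_pose(arch = 10)
  ff2 <- frame_features(p)
  bp <- p$points[back_point_names(), ]
  expect_equal(ff2$back_rmse, fit_back_line(bp)$rmse)
  ar <- back_areas(bp)
  expect_equal(ff2$area_total, ar$total)
  expect_equal(ff2$area_hip_centre, ar$back_hip_to_centre)
  he <- head_nose_pos(fit_back_line(bp), p$points["head", ],
                      p$points["nose", ])
  expect_equal(ff2$head_nose_pos, he$combined)

  # flat topline: zero rmse and area
  ff3 <- frame_features(make_test_pose(arch = 0))
  expect_equal(ff3$back_rmse, 0)
  expect_equal(ff3$area_total, 0)
})

test_that("features are invariant to translation; arch scaling is monotone", {
  p <- make_test_pose(arch = 8)
  shift <- p
  shift$points <- p$points + matrix(c(37, -12), 15, 2, byrow = TRUE)
  a <- frame_features(p); b <- frame_features(shift)
  for (col in c("back_rmse", "area_total", "head_nose_pos", "neck_angle"))
    expect_equal(b[[col]], a[[col]], tolerance = 1e-9)

  # scaling arch height by k scales total area by k and increases rmse
  for (k in c(1.5, 2, 3)) {
    f1 <- frame_features(make_test_pose(arch = 8))
    fk <- frame_features(make_test_pose(arch = 8 * k))
    expect_equal(fk$area_total, k * f1$area_total, tolerance = 1e-9)
    expect_gt(fk$back_rmse, f1$back_rmse)
  }
})

test_that("travel direction is normalized to +x", {
  tc <- simulate_cow_track(gait_params(), 1, seed = 44, n_frames = 10)
  mirrored <- tc
  mirrored$poses <- lapply(tc$poses, function(p) {
    p$points[, "x"] <- -p$points[, "x"]
    p
  })
  # mirrored cow travels toward -x; normalization must undo it
  expect_equal(track_features(mirrored)$neck_angle,
               track_features(tc)$neck_angle, tolerance = 1e-12)
  expect_equal(track_features(mirrored)$back_rmse,
               track_features(tc)$back_rmse, tolerance = 1e-12)
})
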