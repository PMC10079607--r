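test_that("low-pass filter passes the band and is zero-phase", {
  fs <- 80
  t <- seq(0, 3, by = 1 / fs)
  # DC passes untouched
  expect_equal(lowpass_filter(rep(5, length(t)), fs), rep(5, length(t)),
               tolerance = 1e-9)
  # a 2 Hz sinusoid is attenuated by < 1% with zero phase lag
  x2 <- sin(2 * pi * 2 * t)
  y2 <- lowpass_filter(x2, fs)
  expect_lt(max(abs(y2 - x2)), 0.01)
  # 30 Hz rides far beyond the digital filter's cutoff; the residual is
  # bounded by the squared (forward-backward) single-pass magnitude of the
  # bilinear-transform design
  H30 <- 1 / sqrt(1 + (tan(pi * 30 / fs) / tan(pi * 12 / fs))^16)
  mix <- x2 + 0.3 * sin(2 * pi * 30 * t)
  ym <- lowpass_filter(mix, fs)
  interior <- 40:(length(t) - 40)
  expect_lt(max(abs((ym - y2)[interior])), 0.3 * H30^2 + 1e-6)
  expect_error(lowpass_filter(rnorm(10), fs), "too short")
})

test_that("axis projection maps the layout landmarks correctly", {
  lay <- board_layout()
  u <- (lay$target - lay$start) / sqrt(sum((lay$target - lay$start)^2))
  n <- 81
  tt <- seq(0, 1, length.out = n)
  # cup parked at the start, then at the target
  for (pos in list(c(0, 0), c(0.52, 0.52))) {
    cup <- matrix(rep(lay$start + pos[1] * u, n), ncol = 2, byrow = TRUE)
    rec <- trial_recording(t = tt, cup = cup, start = lay$start,
                           target = lay$target)
    kin <- project_to_axis(rec)
    expect_equal(kin$x, rep(pos[1], n), tolerance = 1e-12)
  }
  # ball displaced by l/2 along the axis: theta = arcsin(1/2) = pi/6
  sys <- cup_ball_system()
  cup <- matrix(rep(lay$start, n), ncol = 2, byrow = TRUE)
  ball <- cup + matrix(rep(sys$pendulum_length / 2 * u, n), ncol = 2,
                       byrow = TRUE)
  rec <- trial_recording(t = tt, cup = cup, ball = ball, start = lay$start,
                         target = lay$target, system = sys)
  expect_equal(project_to_axis(rec)$theta, rep(pi / 6, n), tolerance = 1e-12)
})

test_that("ball displacement beyond the pendulum length warns and clamps", {
  lay <- board_layout()
  u <- (lay$target - lay$start) / sqrt(sum((lay$target - lay$start)^2))
  sys <- cup_ball_system()
  n <- 81
  cup <- matrix(rep(lay$start, n), ncol = 2, byrow = TRUE)
  ball <- cup + matrix(rep(1.2 * sys$pendulum_length * u, n), ncol = 2,
                       byrow = TRUE)
  rec <- trial_recording(t = seq(0, 1, length.out = n), cup = cup,
                         ball = ball, start = lay$start,
                         target = lay$target, system = sys)
  expect_warning(kin <- project_to_axis(rec), "tracking glitch")
  expect_equal(kin$theta, rep(pi / 2, n))
})

test_that("projection distances are invariant under board-frame rotation", {
  lay <- board_layout()
  n <- 161
  tt <- seq(0, 2, length.out = n)
  u <- (lay$target - lay$start) / sqrt(sum((lay$target - lay$start)^2))
  s <- 0.26 * (1 - cos(2 * pi * tt / 2))
  cup <- cbind(lay$start[1] + s * u[1], lay$start[2] + s * u[2])
  ang <- 0.7
  R <- matrix(c(cos(ang), sin(ang), -sin(ang), cos(ang)), 2, 2)
  rot <- function(m) t(R %*% t(m))
  rec1 <- trial_recording(t = tt, cup = cup, start = lay$start,
                          target = lay$target)
  rec2 <- trial_recording(t = tt, cup = rot(cup),
                          start = as.numeric(R %*% lay$start),
                          target = as.numeric(R %*% lay$target))
  expect_equal(project_to_axis(rec1)$x, project_to_axis(rec2)$x,
               tolerance = 1e-12)
})

test_that("finite-difference derivatives converge on analytic cases", {
  fs <- 80
  tt <- seq(0, 2, by = 1 / fs)
  # linear ramp: exact everywhere, zero interior acceleration
  kin <- kin_from_velocity(rep(0.3, length(tt)), fs)
  kin$x <- 0.3 * tt
  kin <- derivatives(kin)
  expect_equal(kin$v, rep(0.3, length(tt)), tolerance = 1e-12)
  expect_equal(kin$a[2:(length(tt) - 1)], rep(0, length(tt) - 2),
               tolerance = 1e-9)
  # constant position
  kin$x <- rep(1, length(tt))
  expect_equal(derivatives(kin)$v, rep(0, length(tt)))
  # sampled sinusoid: central differences are O(dt^2)
  err_for <- function(fs) {
    tt <- seq(0, 2, by = 1 / fs)
    kin <- kin_from_velocity(numeric(length(tt)), fs)
    kin$x <- sin(2 * pi * tt)
    kin <- derivatives(kin)
    interior <- 2:(length(tt) - 1)
    max(abs(kin$v[interior] - 2 * pi * cos(2 * pi * tt[interior])))
  }
  e1 <- err_for(80); e2 <- err_for(160)
  expect_gt(e1 / e2, 3.5) # halving dt cuts the error ~4x
})

test_that("segmentation matches the analytic trapezoid crossings", {
  fs <- 80
  tz <- trapezoid_speed(fs = fs, ramp = 0.2, plateau = 1.0, peak = 1.0)
  kin <- kin_from_velocity(tz$v, fs)
  kin <- find_active_segment(kin)
  # analytic 5% crossings: 0.05 * 0.2 s = 0.01 s after ramp onset, mirrored
  t_on <- tz$t1 + 0.01
  t_off <- tz$t4 - 0.01
  expect_lte(abs(kin$t[kin$segment[1]] - t_on), 1 / fs)
  expect_lte(abs(kin$t[kin$segment[2]] - t_off), 1 / fs)
})

test_that("segmentation edge cases behave as specified", {
  fs <- 80
  # no movement at all
  expect_error(find_active_segment(kin_from_velocity(rep(0, 100), fs)),
               "no movement")
  # a single suprathreshold spike yields a one-frame segment plus warning
  v <- rep(0.001, 100); v[50] <- 1
  expect_warning(kin <- find_active_segment(kin_from_velocity(v, fs)),
                 "short-segment")
  expect_equal(kin$segment, c(50, 50))
  # idempotence: re-segmenting the active window returns the same window
  tz <- trapezoid_speed(fs = fs)
  kin <- find_active_segment(kin_from_velocity(tz$v, fs))
  seg <- kin$segment
  sub <- kin_from_velocity(tz$v[seg[1]:seg[2]], fs)
  sub <- find_active_segment(sub)
  expect_equal(sub$segment, c(1, seg[2] - seg[1] + 1))
})

test_that("non-uniform timestamps are resampled with a warning", {
  rec <- generate_synthetic_trial(seed = 5)
  drop <- seq_along(rec$t)[-c(40, 41, 90)] # three dropped frames
  rec2 <- trial_recording(t = rec$t[drop], cup = rec$cup[drop, ],
                          ball = rec$ball[drop, ], start = rec$start,
                          target = rec$target, system = rec$system)
  expect_warning(kin <- preprocess_trial(rec2), "non-uniform")
  expect_equal(median(diff(kin$t)), 1 / 80, tolerance = 1e-9)
})
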