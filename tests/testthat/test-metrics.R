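test_that("movement time is the active-segment span and scales with time", {
  fs <- 80
  tz <- trapezoid_speed(fs = fs, ramp = 0.2, plateau = 1.0, peak = 1.0)
  kin <- find_active_segment(kin_from_velocity(tz$v, fs))
  mt <- movement_time(kin)
  # analytic: between the mirrored 5% crossings, within one frame each side
  expect_lt(abs(mt - ((tz$t4 - 0.01) - (tz$t1 + 0.01))), 2 / fs)
  # halving the sample rate (doubling the time axis) doubles movement time
  kin2 <- find_active_segment(kin_from_velocity(tz$v, fs / 2))
  expect_equal(movement_time(kin2), 2 * mt, tolerance = 1e-9)
  # a one-frame segment has zero movement time
  v <- rep(0.001, 100); v[50] <- 1
  suppressWarnings(kin3 <- find_active_segment(kin_from_velocity(v, fs)))
  expect_equal(movement_time(kin3), 0)
})

test_that("SPARC is amplitude-invariant and penalizes submovements", {
  fs <- 200
  v1 <- mj_speed(fs = fs)
  # scaling the speed profile leaves SPARC unchanged (DC normalization)
  expect_equal(sparc(v1, fs), sparc(2 * v1, fs), tolerance = 1e-12)
  expect_equal(sparc(v1, fs), sparc(0.1 * v1, fs), tolerance = 1e-12)
  # an added delayed half-amplitude submovement lengthens the spectral arc
  v2 <- mj_speed(fs = fs, submovement = TRUE)
  expect_lt(sparc(v2, fs), sparc(v1, fs))
  expect_lte(sparc(v1, fs), 0)
})

test_that("SPARC equals the dense trapezoid arc-length oracle on random profiles", {
  set.seed(101)
  fs <- 80
  for (rep in 1:20) {
    n <- sample(60:240, 1)
    tt <- (0:(n - 1)) / fs
    # random mixture of smooth humps: a plausible family of speed profiles
    k <- sample(1:4, 1)
    v <- rep(0, n)
    for (j in 1:k) {
      c0 <- runif(1, 0.2, 0.8) * max(tt)
      w <- runif(1, 0.08, 0.3)
      v <- v + runif(1, 0.2, 1) * exp(-((tt - c0) / w)^2)
    }
    expect_equal(sparc(v, fs), oracle_sparc(v, fs), tolerance = 1e-6)
  }
})

test_that("SPARC is duration-invariant on sinusoidal profiles in-band", {
  fs <- 200
  make <- function(scale) {
    tt <- seq(0, 2 * scale, by = 1 / fs)
    1 + 0.5 * sin(2 * pi * 2 * tt / scale) # 2/scale Hz, well below the cap
  }
  s1 <- sparc(make(1), fs)
  s2 <- sparc(make(2), fs)
  expect_equal(s1, s2, tolerance = 0.02)
})

test_that("SPARC rejects degenerate input", {
  expect_error(sparc(rep(0, 100), 80), "all-zero")
  expect_error(sparc(c(1, 2, 3), 80), "at least 8")
})

test_that("energy trace reproduces the closed-form energies", {
  sys <- cup_ball_system()
  n <- 101
  tt <- seq(0, 1, length.out = n)
  # rest: zero total energy, margin equals the escape energy throughout
  tr <- energy_trace(rep(0, n), rep(0, n), tt, sys)
  expect_equal(tr$e_total, rep(0, n))
  expect_equal(tr$e_margin, rep(tr$e_esc, n))
  # the escape energy with the printed device parameters
  expect_equal(tr$e_esc, 0.067 * 9.81 * 0.075 * (1 - cos(55 * pi / 180)))
  # a stationary hold at the rim angle has zero margin at its maximum
  th <- sys$escape_angle * sin(pi * tt) # peaks at the rim, thetadot = 0 there
  thd <- sys$escape_angle * pi * cos(pi * tt)
  tr2 <- energy_trace(th, thd, tt, sys)
  peak <- which.max(abs(th))
  expect_equal(tr2$e_margin[peak], 0, tolerance = 1e-6)
})

test_that("local maxima handle plateaus and prominence", {
  # plateau flanked by lower samples: midpoint counted once
  x <- c(0, 1, 2, 2, 2, 1, 0)
  expect_equal(local_maxima(x), 4L)
  # two peaks, the minor one killed by the prominence floor
  y <- c(0, 1, 0.95, 0.97, 0.5, 0)
  expect_equal(local_maxima(y), c(2L, 4L))
  expect_equal(local_maxima(y, min_prominence = 0.1), 2L)
  # endpoints never qualify
  expect_equal(local_maxima(c(3, 1, 2)), integer(0))
})

test_that("risk hits its boundary values exactly", {
  sys <- cup_ball_system()
  n <- 201
  tt <- seq(0, 2, length.out = n)
  # tiny oscillation: energy negligible, every margin ~ E_ESC, risk ~ 0
  eps <- 1e-9
  tr <- energy_trace(eps * sin(2 * pi * 2 * tt),
                     eps * 4 * pi * cos(2 * pi * 2 * tt), tt, sys,
                     min_prominence = 0)
  expect_equal(risk(tr), 0, tolerance = 1e-12)
  # swings exactly to the rim with no speed at the peaks: risk = 1
  th <- sys$escape_angle * sin(2 * pi * tt)
  thd <- sys$escape_angle * 2 * pi * cos(2 * pi * tt)
  tr2 <- energy_trace(th, thd, tt, sys)
  expect_equal(risk(tr2), 1, tolerance = 1e-4)
  # monotone |theta| (no interior maxima) leaves the metric undefined
  tr3 <- energy_trace(tt / 10, rep(0.1, n) / 10, tt, sys)
  expect_error(risk(tr3), "maxima")
})

test_that("risk agrees with the brute-force oracle on simulated trials", {
  sys <- cup_ball_system()
  for (s in 1:20) {
    drv <- impaired_drive(runif(1, 0, 0.7), seed = 7000 + s)
    tr <- simulate_trial(sys, drv, dt = 2e-3)
    th <- tr$theta; thd <- tr$theta_dot
    et <- energy_trace(th, thd, tr$t, sys)
    r_oracle <- oracle_risk(th, thd, sys)
    if (is.na(r_oracle)) next
    expect_equal(risk(et), r_oracle, tolerance = 1e-10)
  }
  # analytic sinusoidal swing checked against the same oracle
  tt <- seq(0, 2, by = 1 / 200)
  th <- 0.3 * sin(2 * pi * 1.5 * tt)
  thd <- 0.3 * 2 * pi * 1.5 * cos(2 * pi * 1.5 * tt)
  expect_equal(risk(energy_trace(th, thd, tt, sys)),
               oracle_risk(th, thd, sys), tolerance = 1e-12)
})

test_that("risk is non-increasing in the rim angle on identical kinematics", {
  deep <- condition_system("deep_ball")
  shallow <- condition_system("shallow_ball")
  tt <- seq(0, 3, by = 1 / 200)
  th <- 0.35 * sin(2 * pi * 1.2 * tt) * exp(-tt / 3)
  thd <- c(diff(th) * 200, 0)
  r_deep <- risk(energy_trace(th, thd, tt, deep))
  r_shallow <- risk(energy_trace(th, thd, tt, shallow))
  expect_gte(r_shallow, r_deep)
})

test_that("phase advances uniformly for sinusoidal state-space motion", {
  fs <- 80
  f <- 1.5
  tt <- seq(0, 4, by = 1 / fs)
  A <- 0.1
  kin <- kin_from_velocity(numeric(length(tt)), fs)
  kin$x <- A * sin(2 * pi * f * tt)
  kin$v <- A * 2 * pi * f * cos(2 * pi * f * tt)
  kin$theta <- 0.5 * kin$x # ball identical up to scale
  kin$theta_dot <- 0.5 * kin$v
  kin$segment <- c(1L, length(tt))
  ph <- phase_series(kin)
  # frequency recovered from the spectrum
  expect_equal(ph$f_x, f, tolerance = 0.05)
  # one wrap per period: unwrapped phase advances 2*pi*f per second
  dphi <- diff(ph$phi_cup)
  dphi <- ifelse(dphi > pi, dphi - 2 * pi, ifelse(dphi < -pi, dphi + 2 * pi,
                                                  dphi))
  expect_equal(abs(mean(dphi)) * fs, 2 * pi * f, tolerance = 0.05)
  # scaled identical signals give identical phases
  expect_equal(ph$phi_ball, ph$phi_cup, tolerance = 1e-9)
})

test_that("phase with estimated frequency matches a known-frequency oracle", {
  sys <- cup_ball_system()
  f_drive <- 1.3
  tt <- seq(0, 6, by = 1 / 200)
  x <- 0.08 * (1 - cos(2 * pi * f_drive * pmin(tt, 5)))
  drv <- sampled_drive(tt, x)
  rec <- generate_synthetic_trial(sys, drv, noise_sd = 0, pixel_pitch = 0)
  kin <- preprocess_trial(rec)
  ph <- phase_series(kin)
  i <- kin$segment[1]:kin$segment[2]
  xs <- kin$x[i] - mean(kin$x[i])
  phi_oracle <- atan2(kin$v[i] / (2 * pi * f_drive), xs)
  d <- ph$phi_cup - phi_oracle
  d <- atan2(sin(d), cos(d)) # wrap differences
  expect_lt(sqrt(mean(d^2)), 0.05)
})

test_that("phase rejects degenerate input", {
  fs <- 80
  kin <- kin_from_velocity(rep(0, 100), fs)
  kin$theta <- rep(0.2, 100)
  kin$theta_dot <- rep(0, 100)
  kin$segment <- c(1L, 100L)
  expect_error(phase_series(kin), "degenerate")
})

test_that("mutual information of identical phases is the marginal entropy", {
  set.seed(3)
  phi <- runif(500, -pi, pi)
  expect_equal(mutual_information(phi, phi, bins = 10),
               oracle_entropy(phi, bins = 10), tolerance = 1e-12)
})

test_that("mutual information is symmetric, non-negative, and matches the cell-sum oracle", {
  set.seed(4)
  for (rep in 1:5) {
    n <- 400
    a <- runif(n, -pi, pi)
    b <- atan2(sin(a + rnorm(n, 0, rep)), cos(a + rnorm(n, 0, rep)))
    expect_equal(mutual_information(a, b), mutual_information(b, a))
    expect_gte(mutual_information(a, b), -1e-12)
    expect_equal(mutual_information(a, b), oracle_mi(a, b),
                 tolerance = 1e-12)
  }
})

test_that("independent phases give MI within the chi-square null bound, decaying in n", {
  bins <- 10
  # 2n*MI for independent inputs is asymptotically chi-square((bins-1)^2)
  bound <- function(n) qchisq(0.999, (bins - 1)^2) / (2 * n)
  mis <- vapply(c(1e3, 1e4, 1e5), function(n) {
    set.seed(as.integer(n))
    mutual_information(runif(n, -pi, pi), runif(n, -pi, pi), bins = bins)
  }, numeric(1))
  expect_true(all(mis < bound(c(1e3, 1e4, 1e5))))
  expect_true(all(diff(mis) < 0)) # estimator bias shrinks as 1/n
  expect_lt(mis[3], 5e-4)
})

test_that("under-sampled MI warns", {
  set.seed(5)
  expect_warning(mutual_information(runif(50, -pi, pi),
                                    runif(50, -pi, pi), bins = 10),
                 "biased")
})

test_that("compute_metrics dispatches and flags correctly", {
  # no-ball trial: movement time and SPARC only, ball-absent flag
  rec <- generate_synthetic_trial(condition = "deep_no_ball", seed = 21)
  m <- compute_metrics(preprocess_trial(rec))
  expect_true("ball_absent" %in% m$flags)
  expect_true(is.finite(m$movement_time) && is.finite(m$sparc))
  expect_true(is.na(m$risk) && is.na(m$mutual_information))

  # smooth able-bodied trial: all four metrics, no flags
  m2 <- compute_metrics(preprocess_trial(generate_synthetic_trial(seed = 22)))
  expect_length(m2$flags, 0)
  expect_true(all(is.finite(c(m2$movement_time, m2$sparc, m2$risk,
                              m2$mutual_information))))
  expect_lte(m2$sparc, 0)
  expect_gte(m2$mutual_information, 0)

  # over-amplitude drive escapes; risk may legitimately exceed 1
  sys <- condition_system("shallow_ball")
  drv <- min_jerk_drive(amplitude = 1.2, out_duration = 0.55, dwell = 0.2,
                        back_duration = 0.55)
  sim <- simulate_trial(sys, drv, truncate_at_escape = FALSE)
  expect_true(sim$escaped)
  rec3 <- generate_synthetic_trial(sys, drv, noise_sd = 0, pixel_pitch = 0,
                                   condition = "shallow_ball", sim = sim)
  # the truncated escape trace is short; the MI under-sampling diagnostic
  # is expected here
  m3 <- suppressWarnings(compute_metrics(preprocess_trial(rec3),
                                         escape_detected = sim$escaped))
  expect_true("escape_detected" %in% m3$flags)
  expect_gt(m3$risk, 1)
})
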