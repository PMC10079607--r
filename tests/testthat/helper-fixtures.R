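# Shared fixture builders for the test suite. Everything is generated in
# code; no data files.

# Build a kinematics1d object directly from a velocity series (positions by
# cumulative integration), bypassing the preprocessing chain, for tests that
# target segmentation and the metrics in isolation.
kin_from_velocity <- function(v, fs = 80, theta = NULL, theta_dot = NULL) {
  t <- (seq_along(v) - 1) / fs
  structure(
    list(
      t = t,
      x = cumsum(v) / fs,
      v = v,
      a = c(diff(v) * fs, 0),
      theta = theta,
      theta_dot = theta_dot,
      segment = NULL,
      sample_rate = fs,
      system = cup_ball_system(),
      condition = "deep_ball", hand = "able", subject = "T1"
    ),
    class = "kinematics1d"
  )
}

# Symmetric trapezoidal speed profile: linear ramps of `ramp` seconds up to
# `peak`, a plateau, mirrored release. Analytic 5%-threshold crossings.
trapezoid_speed <- function(fs = 80, ramp = 0.2, plateau = 1.0, peak = 1.0,
                            lead = 0.5, tail = 0.5) {
  t <- seq(0, lead + ramp + plateau + ramp + tail, by = 1 / fs)
  v <- numeric(length(t))
  t1 <- lead; t2 <- lead + ramp; t3 <- t2 + plateau; t4 <- t3 + ramp
  up <- t >= t1 & t < t2
  v[up] <- peak * (t[up] - t1) / ramp
  v[t >= t2 & t < t3] <- peak
  down <- t >= t3 & t < t4
  v[down] <- peak * (t4 - t[down]) / ramp
  list(t = t, v = v, t1 = t1, t2 = t2, t3 = t3, t4 = t4)
}

# Minimum-jerk speed profile on [0, T] (unit displacement), optionally with
# a delayed half-amplitude copy superimposed, as a canonical smooth /
# less-smooth pair.
mj_speed <- function(fs = 200, T = 1, submovement = FALSE) {
  t <- seq(0, if (submovement) 1.6 * T else T, by = 1 / fs)
  tau <- pmin(t / T, 1)
  v <- (30 * tau^2 - 60 * tau^3 + 30 * tau^4) / T
  if (submovement) {
    tau2 <- pmin(pmax((t - 0.6 * T) / T, 0), 1)
    v <- v + 0.5 * (30 * tau2^2 - 60 * tau2^3 + 30 * tau2^4) / T
  }
  v
}
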