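#' Angular acceleration of the ball pendulum
#'
#' Equation of motion of the kinematically driven pendulum:
#' \deqn{\ddot\theta = -\frac{\ddot X}{l}\cos\theta - \frac{g}{l}\sin\theta}
#' where \eqn{\theta = 0} is the downward vertical and counterclockwise is
#' positive.
#'
#' @param system A [cup_ball_system()].
#' @param theta Ball angle (rad).
#' @param theta_dot Ball angular velocity (rad/s). Not used by the dynamics
#'   (the pendulum is undamped) but accepted for a uniform state signature.
#' @param cup_accel Cup acceleration \eqn{\ddot X} (m/s^2).
#' @return Angular acceleration (rad/s^2). Vectorized over the state inputs.
#' @export
ball_dynamics <- function(system, theta, theta_dot = 0, cup_accel = 0) {
  stopifnot(inherits(system, "cup_ball_system"))
  if (!all(is.finite(theta)) || !all(is.finite(theta_dot)) ||
      !all(is.finite(cup_accel))) {
    stop("ball_dynamics: non-finite input state", call. = FALSE)
  }
  -(cup_accel / system$pendulum_length) * cos(theta) -
    (system$gravity / system$pendulum_length) * sin(theta)
}

#' Simulate one trial of the driven cup-and-ball system
#'
#' Integrates the ball pendulum under the prescribed cup trajectory with a
#' fixed-step classical 4th-order Runge-Kutta scheme, then fills in the force
#' the ball exerts on the cup,
#' \eqn{F_{ball} = m_b l(\dot\theta^2\sin\theta - \ddot\theta\cos\theta)},
#' and the participant's interaction force
#' \eqn{F_{inter} = (m_c+m_b)\ddot X - F_{ball}}.
#'
#' Escape is declared at the first step where the ball's total mechanical
#' energy exceeds the escape energy \eqn{E_{ESC}} (the same energy criterion
#' the risk metric is built on); crossing of the rim angle itself is reported
#' as a secondary flag. By default the trace is truncated at escape.
#'
#' @param system A [cup_ball_system()].
#' @param drive A [drive_profile][min_jerk_drive()] prescribing \eqn{X(t)}.
#' @param dt Integration step (s), default 1e-3. Must be well below the
#'   pendulum period \eqn{2\pi\sqrt{l/g}}.
#' @param theta0,theta_dot0 Initial ball state (rad, rad/s).
#' @param duration Simulation span (s); defaults to [drive_duration()].
#' @param truncate_at_escape If `TRUE` (default) the returned series stop at
#'   the escape step; if `FALSE` integration continues (the pendulum model
#'   formally extends past the rim).
#' @return An object of class `sim_trace`: a list with the time grid `t`,
#'   cup kinematics `x`, `v`, `a`, ball state `theta`, `theta_dot`,
#'   `theta_ddot`, forces `f_ball`, `f_inter`, logicals `escaped` /
#'   `rim_exceeded`, `escape_time` (or `NA`), and the `system` and `dt` used.
#' @examples
#' sys <- cup_ball_system()
#' tr <- simulate_trial(sys, min_jerk_drive(amplitude = 0.3), dt = 1e-3)
#' max(abs(tr$theta)) * 180 / pi # peak ball angle in degrees
#' @export
simulate_trial <- function(system, drive, dt = 1e-3,
                           theta0 = 0, theta_dot0 = 0,
                           duration = NULL,
                           truncate_at_escape = TRUE) {
  stopifnot(inherits(system, "cup_ball_system"),
            inherits(drive, "drive_profile"),
            is.numeric(dt), length(dt) == 1, dt > 0,
            is.finite(theta0), is.finite(theta_dot0))
  period <- natural_period(system)
  if (dt >= period / 2) {
    stop(sprintf(
      "simulate_trial: dt = %g s is too coarse for the pendulum period %.4g s",
      dt, period), call. = FALSE)
  }
  if (is.null(duration)) duration <- drive_duration(drive)
  if (duration <= 0) stop("simulate_trial: drive has non-positive duration",
                          call. = FALSE)
  n <- floor(duration / dt) + 1L
  t <- (seq_len(n) - 1L) * dt

  dr <- eval_drive(drive, t)
  dr_half <- eval_drive(drive, t + dt / 2)
  a_grid <- dr$a
  a_half <- dr_half$a

  l <- system$pendulum_length
  g <- system$gravity
  th <- numeric(n)
  om <- numeric(n)
  th[1] <- theta0
  om[1] <- theta_dot0

  f <- function(theta, omega, a) -(a / l) * cos(theta) - (g / l) * sin(theta)

  for (k in seq_len(n - 1L)) {
    a0 <- a_grid[k]; ah <- a_half[k]; a1 <- a_grid[k + 1L]
    th_k <- th[k]; om_k <- om[k]
    k1_th <- om_k
    k1_om <- f(th_k, om_k, a0)
    k2_th <- om_k + dt / 2 * k1_om
    k2_om <- f(th_k + dt / 2 * k1_th, k2_th, ah)
    k3_th <- om_k + dt / 2 * k2_om
    k3_om <- f(th_k + dt / 2 * k2_th, k3_th, ah)
    k4_th <- om_k + dt * k3_om
    k4_om <- f(th_k + dt * k3_th, k4_th, a1)
    th[k + 1L] <- th_k + dt / 6 * (k1_th + 2 * k2_th + 2 * k3_th + k4_th)
    om[k + 1L] <- om_k + dt / 6 * (k1_om + 2 * k2_om + 2 * k3_om + k4_om)
  }

  alpha <- f(th, om, a_grid)
  e_esc <- escape_energy(system)
  e_tot <- 0.5 * system$ball_mass * l^2 * om^2 +
    system$ball_mass * g * l * (1 - cos(th))
  esc_idx <- which(e_tot > e_esc)
  escaped <- length(esc_idx) > 0
  escape_time <- if (escaped) t[esc_idx[1]] else NA_real_

  keep <- if (escaped && truncate_at_escape) seq_len(esc_idx[1]) else seq_len(n)
  th <- th[keep]; om <- om[keep]; alpha <- alpha[keep]
  t <- t[keep]
  xk <- dr$x[keep]; vk <- dr$v[keep]; ak <- dr$a[keep]

  f_ball <- system$ball_mass * l * (om^2 * sin(th) - alpha * cos(th))
  f_inter <- (system$cup_mass + system$ball_mass) * ak - f_ball

  structure(
    list(
      t = t, x = xk, v = vk, a = ak,
      theta = th, theta_dot = om, theta_ddot = alpha,
      f_ball = f_ball, f_inter = f_inter,
      escaped = escaped, escape_time = escape_time,
      rim_exceeded = any(abs(th) > system$escape_angle),
      system = system, dt = dt
    ),
    class = "sim_trace"
  )
}

#' @export
print.sim_trace <- function(x, ...) {
  cat(sprintf("<sim_trace: %d steps, %.3g s, dt = %g s>\n",
              length(x$t), max(x$t), x$dt))
  cat(sprintf("  peak |theta| %.3g deg; escaped: %s\n",
              max(abs(x$theta)) * 180 / pi, x$escaped))
  invisible(x)
}

#' Default board layout for synthetic recordings
#'
#' Start and target circle centres on the 60.9 x 91.4 cm board, 52 cm apart
#' along a diagonal movement axis, circle diameter 14 cm. Mirrors the layout
#' drawn for a right-handed extension-flexion movement.
#'
#' @return A list with `start`, `target` (m, board frame), `diameter` (m)
#'   and `separation` (m).
#' @export
board_layout <- function() {
  start <- c(0.12, 0.08)
  u <- c(0.76, 0.45)
  u <- u / sqrt(sum(u^2))
  list(start = start, target = start + 0.52 * u,
       diameter = 0.14, separation = 0.52)
}

#' Camera pixel pitch of the overhead view
#'
#' The device records 640 x 480 px frames covering the 91.4 cm board width;
#' one pixel therefore spans about 1.43 mm.
#'
#' @return Metres per pixel.
#' @export
board_pixel_pitch <- function() 0.914 / 640

#' Generate a synthetic trial recording
#'
#' Emulates the output of the overhead camera: simulates the driven
#' cup-and-ball at fine time step, resamples to the camera frame rate, maps
#' the 1-D trajectory onto the board between the start and target circle
#' centres, reconstructs the ball centre as the cup centre displaced by
#' \eqn{l\sin\theta} along the movement axis, then adds i.i.d. Gaussian
#' tracking noise and quantizes positions to the pixel grid.
#'
#' @param system A [cup_ball_system()]; ignored when `ball = FALSE`.
#' @param drive Drive profile for the cup.
#' @param sample_rate Camera frame rate (Hz), default 80.
#' @param noise_sd Tracking noise standard deviation (m), default 0.5 mm;
#'   0 disables noise.
#' @param pixel_pitch Pixel grid spacing (m/px), default
#'   [board_pixel_pitch()]; 0 disables quantization.
#' @param seed Optional integer; when given the recording is a
#'   deterministic function of the arguments.
#' @param condition Condition label stored in the metadata.
#' @param subject,hand Metadata labels.
#' @param ball Include the ball marker? `FALSE` for the no-ball condition
#'   (the ball columns are then absent).
#' @param layout Board layout, default [board_layout()].
#' @param dt Internal simulation step (s).
#' @param sim Optional precomputed [simulate_trial()] trace to reuse (e.g.
#'   when generating many noise realizations of one trajectory).
#' @return A [trial_recording()].
#' @export
generate_synthetic_trial <- function(system = cup_ball_system(),
                                     drive = min_jerk_drive(),
                                     sample_rate = 80,
                                     noise_sd = 5e-4,
                                     pixel_pitch = board_pixel_pitch(),
                                     seed = NULL,
                                     condition = "deep_ball",
                                     subject = "S1",
                                     hand = "able",
                                     ball = condition_has_ball(condition),
                                     layout = board_layout(),
                                     dt = 1e-3,
                                     sim = NULL) {
  stopifnot(sample_rate > 0, noise_sd >= 0, pixel_pitch >= 0)
  if (!is.null(seed)) set.seed(as.integer(seed))

  u <- layout$target - layout$start
  u <- u / sqrt(sum(u^2))

  if (ball) {
    if (is.null(sim)) sim <- simulate_trial(system, drive, dt = dt)
    if (sim$escaped && max(sim$t) < 0.6) {
      # escape within the first frames: keep recording on the formal model so
      # the trace still satisfies the minimum-duration contract
      sim <- simulate_trial(system, drive, dt = dt,
                            truncate_at_escape = FALSE)
    }
    t_end <- max(sim$t)
    tf <- seq(0, t_end, by = 1 / sample_rate)
    x1 <- stats::approx(sim$t, sim$x, xout = tf)$y
    th <- stats::approx(sim$t, sim$theta, xout = tf)$y
  } else {
    t_end <- drive_duration(drive)
    tf <- seq(0, t_end, by = 1 / sample_rate)
    x1 <- eval_drive(drive, tf)$x
    th <- NULL
  }

  cup <- cbind(layout$start[1] + x1 * u[1], layout$start[2] + x1 * u[2])
  ball_xy <- NULL
  if (ball) {
    d <- system$pendulum_length * sin(th)
    ball_xy <- cbind(cup[, 1] + d * u[1], cup[, 2] + d * u[2])
  }

  jitter_quantize <- function(m) {
    if (noise_sd > 0) {
      m <- m + matrix(stats::rnorm(length(m), 0, noise_sd), ncol = 2)
    }
    if (pixel_pitch > 0) m <- round(m / pixel_pitch) * pixel_pitch
    m
  }
  cup <- jitter_quantize(cup)
  if (!is.null(ball_xy)) ball_xy <- jitter_quantize(ball_xy)

  trial_recording(
    t = tf, cup = cup, ball = ball_xy,
    start = layout$start, target = layout$target,
    condition = condition, hand = hand, subject = subject,
    system = if (ball) system else NULL,
    sample_rate = sample_rate, seed = seed,
    diameter = layout$diameter
  )
}
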