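#' Zero-phase Butterworth low-pass filter
#'
#' 8th-order Butterworth at 12 Hz cutoff applied forward and backward
#' (zero phase lag, squared single-pass magnitude). Ends are handled by odd
#' reflection padding so constants and slowly varying signals pass without
#' edge transients; segment boundaries and the times of ball-angle maxima
#' must not be lag-shifted, which is why the zero-phase form is used.
#'
#' @param x Uniformly sampled numeric series.
#' @param sample_rate Sampling rate (Hz).
#' @param cutoff Cutoff frequency (Hz), default 12.
#' @param order Filter order of the single pass, default 8.
#' @return Filtered series, same length as `x`.
#' @export
lowpass_filter <- function(x, sample_rate, cutoff = 12, order = 8) {
  stopifnot(is.numeric(x), sample_rate > 0, cutoff > 0,
            cutoff < sample_rate / 2)
  n <- length(x)
  if (n <= 3 * order) {
    stop("lowpass_filter: series too short to filter (need > 3x order)",
         call. = FALSE)
  }
  bf <- signal::butter(order, cutoff / (sample_rate / 2))
  pad <- min(n - 1L, max(3L * order, 100L))
  pre <- 2 * x[1] - x[(pad + 1L):2]
  post <- 2 * x[n] - x[(n - 1L):(n - pad)]
  y <- signal::filtfilt(bf, c(pre, x, post))
  y[(pad + 1L):(pad + n)]
}

#' 1-D kinematics of a trial
#'
#' Container produced by the preprocessing chain: filtered cup position
#' projected on the movement axis, its derivatives, the recovered ball angle
#' and angular velocity (when ball data exist), and the active movement
#' segment.
#'
#' @name kinematics1d
#' @return A list of class `kinematics1d` with fields `t`, `x`, `v`, `a`,
#'   `theta`, `theta_dot` (the latter two `NULL` without ball data),
#'   `segment` (inclusive 1-based frame indices `c(i_start, i_end)`, or
#'   `NULL` before segmentation), `sample_rate`, `system`, and metadata
#'   copied from the recording.
NULL

#' Project a trial recording onto the movement axis
#'
#' Positions are expressed along the unit vector from the start-circle
#' centre to the target-circle centre, origin at the start centre:
#' \eqn{X = (p_{cup} - p_{start})\cdot\hat u}. The ball angle is recovered
#' from the overhead view as
#' \eqn{\theta = \arcsin((p_{ball}-p_{cup})\cdot\hat u / l)}, clamped to
#' `[-1, 1]` before the arcsine; a projection exceeding the pendulum length
#' by more than 10\% raises a tracking-glitch warning.
#'
#' @param rec A [trial_recording()] (positions should already be filtered
#'   when called from [preprocess_trial()]).
#' @param system Cup-ball system giving the pendulum length; defaults to the
#'   one stored in the recording.
#' @return A [kinematics1d] object with positions (and `theta`) filled,
#'   derivatives `NULL`.
#' @export
project_to_axis <- function(rec, system = rec$system) {
  stopifnot(inherits(rec, "trial_recording"))
  u <- rec$target - rec$start
  u <- u / sqrt(sum(u^2))
  x <- (rec$cup[, 1] - rec$start[1]) * u[1] +
       (rec$cup[, 2] - rec$start[2]) * u[2]
  theta <- NULL
  if (!is.null(rec$ball)) {
    if (is.null(system)) {
      stop("project_to_axis: ball data present but no cup_ball_system given",
           call. = FALSE)
    }
    proj <- ((rec$ball[, 1] - rec$cup[, 1]) * u[1] +
             (rec$ball[, 2] - rec$cup[, 2]) * u[2]) / system$pendulum_length
    if (any(abs(proj) > 1.1)) {
      warning(sprintf(
        "project_to_axis: ball-cup displacement exceeds pendulum length by >10%% at %d frame(s) (tracking glitch?)",
        sum(abs(proj) > 1.1)), call. = FALSE)
    }
    theta <- asin(pmin(1, pmax(-1, proj)))
  }
  structure(
    list(t = rec$t, x = x, v = NULL, a = NULL,
         theta = theta, theta_dot = NULL, segment = NULL,
         sample_rate = rec$sample_rate, system = system,
         condition = rec$condition, hand = rec$hand, subject = rec$subject),
    class = "kinematics1d"
  )
}

#' Numerical derivatives of the projected kinematics
#'
#' Central differences on the interior, one-sided at the endpoints, applied
#' after filtering. Fills cup velocity/acceleration and, when the ball angle
#' is present, its angular velocity.
#'
#' @param kin A [kinematics1d] object with positions present.
#' @param sample_rate Sampling rate (Hz); defaults to the stored one.
#' @return The `kinematics1d` with `v`, `a` (and `theta_dot`) filled.
#' @export
derivatives <- function(kin, sample_rate = kin$sample_rate) {
  stopifnot(inherits(kin, "kinematics1d"))
  kin$v <- diff_series(kin$x, sample_rate)
  kin$a <- diff_series(kin$v, sample_rate)
  if (!is.null(kin$theta)) kin$theta_dot <- diff_series(kin$theta, sample_rate)
  kin
}

diff_series <- function(x, fs) {
  n <- length(x)
  d <- numeric(n)
  if (n < 2) return(d)
  d[2:(n - 1)] <- (x[3:n] - x[1:(n - 2)]) * fs / 2
  d[1] <- (x[2] - x[1]) * fs
  d[n] <- (x[n] - x[n - 1]) * fs
  d
}

#' Find the active movement segment
#'
#' The active segment spans the first to the last frame at which the
#' absolute cup velocity exceeds 5\% of its maximum in the same trial. All
#' metrics that restrict to a window (movement time, SPARC, mutual
#' information) use this segment.
#'
#' @param kin A [kinematics1d] with velocities filled.
#' @param threshold Fraction of the trial's peak absolute velocity,
#'   default 0.05.
#' @return The `kinematics1d` with `segment = c(i_start, i_end)` (1-based,
#'   inclusive). A single-frame segment triggers a short-segment warning.
#' @export
find_active_segment <- function(kin, threshold = 0.05) {
  stopifnot(inherits(kin, "kinematics1d"), !is.null(kin$v),
            threshold > 0, threshold < 1)
  sp <- abs(kin$v)
  vmax <- max(sp)
  if (!is.finite(vmax) || vmax <= 0) {
    stop("find_active_segment: no movement (max |velocity| is zero)",
         call. = FALSE)
  }
  above <- which(sp > threshold * vmax)
  seg <- c(above[1], above[length(above)])
  if (seg[2] - seg[1] < 2) {
    warning("find_active_segment: segment spans <3 frames (short-segment)",
            call. = FALSE)
  }
  kin$segment <- seg
  kin
}

#' Full preprocessing chain for one trial
#'
#' Resamples to the nominal rate if timestamps are non-uniform (dropped
#' frames; linear interpolation, with a warning), low-pass filters the 2-D
#' cup and ball traces (12 Hz, 8th-order Butterworth, zero-phase), projects
#' onto the movement axis, differentiates, and marks the active segment.
#' The ball angular velocity is obtained by differentiating the recovered
#' angle, not by differencing raw ball positions.
#'
#' @param rec A [trial_recording()].
#' @param cutoff,order Filter parameters (Hz, -), defaults 12 and 8.
#' @param threshold Velocity threshold fraction for segmentation.
#' @param system Cup-ball system; defaults to the recording's.
#' @return A [kinematics1d] ready for [compute_metrics()].
#' @examples
#' rec <- generate_synthetic_trial(seed = 1)
#' kin <- preprocess_trial(rec)
#' kin$segment
#' @export
preprocess_trial <- function(rec, cutoff = 12, order = 8, threshold = 0.05,
                             system = rec$system) {
  stopifnot(inherits(rec, "trial_recording"))
  fs <- rec$sample_rate
  dtv <- diff(rec$t)
  if (max(dtv) > 1.5 * median(dtv) || abs(median(dtv) - 1 / fs) > 0.1 / fs) {
    warning("preprocess_trial: non-uniform timestamps; resampling to nominal rate",
            call. = FALSE)
    tg <- seq(min(rec$t), max(rec$t), by = 1 / fs)
    resample <- function(m) {
      cbind(stats::approx(rec$t, m[, 1], xout = tg)$y,
            stats::approx(rec$t, m[, 2], xout = tg)$y)
    }
    rec$cup <- resample(rec$cup)
    if (!is.null(rec$ball)) rec$ball <- resample(rec$ball)
    rec$t <- tg
  }
  rec$cup[, 1] <- lowpass_filter(rec$cup[, 1], fs, cutoff, order)
  rec$cup[, 2] <- lowpass_filter(rec$cup[, 2], fs, cutoff, order)
  if (!is.null(rec$ball)) {
    rec$ball[, 1] <- lowpass_filter(rec$ball[, 1], fs, cutoff, order)
    rec$ball[, 2] <- lowpass_filter(rec$ball[, 2], fs, cutoff, order)
  }
  kin <- project_to_axis(rec, system = system)
  kin <- derivatives(kin)
  find_active_segment(kin, threshold = threshold)
}

#' @export
print.kinematics1d <- function(x, ...) {
  cat(sprintf("<kinematics1d: %d frames @ %g Hz, %s ball angle%s>\n",
              length(x$t), x$sample_rate,
              if (is.null(x$theta)) "no" else "with",
              if (is.null(x$segment)) "" else
                sprintf(", segment [%d, %d]", x$segment[1], x$segment[2])))
  invisible(x)
}
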