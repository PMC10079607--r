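#' Prescribed cup trajectories (drive profiles)
#'
#' The simulator is kinematically driven: the cup position along the movement
#' axis is prescribed and the ball responds. The canonical profile is a
#' minimum-jerk reach from the start circle to the target, a dwell, and a
#' minimum-jerk return, optionally corrupted by corrective submovements
#' (themselves small minimum-jerk displacement increments) that emulate the
#' intermittent trajectories of impaired movement.
#'
#' @param amplitude Reach amplitude in m; default 0.52, the start-to-target
#'   centre distance of the board layout.
#' @param out_duration,back_duration Durations of the outward and return
#'   strokes in s.
#' @param dwell Pause at the target in s.
#' @param lead_in Stationary time before movement onset in s.
#' @param tail Stationary time after the return in s (lets the ball ring
#'   down, as the device keeps recording until the cup has rested in the
#'   start circle).
#' @param submovements `NULL`, or a data.frame with columns `onset` (s),
#'   `amplitude` (m, signed) and `duration` (s): each row adds a minimum-jerk
#'   displacement increment on top of the base profile.
#' @return An object of class `drive_profile`.
#' @seealso [eval_drive()], [impaired_drive()], [sampled_drive()]
#' @examples
#' d <- min_jerk_drive()
#' drive_duration(d)
#' eval_drive(d, c(0, 0.5, 1.0))
#' @export
min_jerk_drive <- function(amplitude = 0.52,
                           out_duration = 1.1,
                           dwell = 0.25,
                           back_duration = 1.1,
                           lead_in = 0.25,
                           tail = 1.0,
                           submovements = NULL) {
  stopifnot(
    amplitude > 0, out_duration > 0, back_duration > 0,
    dwell >= 0, lead_in >= 0, tail >= 0
  )
  if (!is.null(submovements)) {
    stopifnot(
      is.data.frame(submovements),
      all(c("onset", "amplitude", "duration") %in% names(submovements)),
      all(is.finite(as.matrix(submovements[c("onset", "amplitude",
                                             "duration")]))),
      all(submovements$duration > 0), all(submovements$onset >= 0)
    )
  }
  structure(
    list(
      kind = "min_jerk",
      amplitude = amplitude,
      out_duration = out_duration,
      dwell = dwell,
      back_duration = back_duration,
      lead_in = lead_in,
      tail = tail,
      submovements = submovements
    ),
    class = "drive_profile"
  )
}

#' Drive profile built purely from a list of submovements
#'
#' @param submovements data.frame with `onset`, `amplitude`, `duration`.
#' @param tail Stationary time after the last submovement ends (s).
#' @return A `drive_profile` of kind `"submovements"`.
#' @export
submovement_drive <- function(submovements, tail = 1.0) {
  stopifnot(
    is.data.frame(submovements), nrow(submovements) >= 1,
    all(c("onset", "amplitude", "duration") %in% names(submovements)),
    all(submovements$duration > 0), all(submovements$onset >= 0), tail >= 0
  )
  structure(
    list(kind = "submovements", submovements = submovements, tail = tail),
    class = "drive_profile"
  )
}

#' Drive profile from a sampled position trace
#'
#' Interpolates the supplied samples with a natural cubic spline; velocity
#' and acceleration come from the spline's derivatives.
#'
#' @param time Strictly increasing sample times (s).
#' @param position Cup positions along the movement axis (m).
#' @return A `drive_profile` of kind `"sampled"`.
#' @export
sampled_drive <- function(time, position) {
  stopifnot(length(time) == length(position), length(time) >= 4,
            all(diff(time) > 0), all(is.finite(time)), all(is.finite(position)))
  structure(
    list(kind = "sampled", time = time, position = position,
         spline = stats::splinefun(time, position, method = "natural")),
    class = "drive_profile"
  )
}

#' Impairment-graded drive profile
#'
#' A surrogate for impaired reach-and-return movement built on the
#' submovement-decomposition picture of post-stroke reaching: with growing
#' severity each stroke fragments into sequential minimum-jerk subreaches
#' separated by brief pauses (the multi-peaked velocity profiles typical of
#' impaired movement), stroke and dwell times lengthen, and small randomized
#' corrective submovements are superimposed. Fragment durations scale with
#' the square root of their amplitude share, keeping peak acceleration close
#' to that of the unfragmented stroke (slower, not more violent, movement).
#' `severity = 0` reduces to the smooth single-stroke reach-and-return.
#'
#' @param severity Impairment severity in `[0, 1]`.
#' @param amplitude Reach amplitude (m).
#' @param base_out,base_back Unimpaired stroke durations (s).
#' @param dwell,lead_in,tail As in [min_jerk_drive()].
#' @param seed Optional integer seed for the randomized fragmentation.
#' @return A `drive_profile` (submovement kind).
#' @export
impaired_drive <- function(severity,
                           amplitude = 0.52,
                           base_out = 1.1,
                           base_back = 1.1,
                           dwell = 0.25,
                           lead_in = 0.25,
                           tail = 1.0,
                           seed = NULL) {
  stopifnot(is.numeric(severity), length(severity) == 1,
            severity >= 0, severity <= 1)
  if (!is.null(seed)) set.seed(as.integer(seed))
  slow <- 1 + 0.6 * severity

  fragment_stroke <- function(total_amp, base_T, t0) {
    k <- 1L + stats::rpois(1, 3 * severity)
    w <- stats::runif(k, 0.5, 1.5)
    w <- w / sum(w)
    durs <- base_T * slow * sqrt(w) * exp(stats::rnorm(k, 0, 0.05))
    onsets <- numeric(k)
    t <- t0
    for (i in seq_len(k)) {
      onsets[i] <- t
      t <- t + durs[i]
      if (i < k) t <- t + stats::runif(1, 0.05, 0.15 + 0.45 * severity)
    }
    list(df = data.frame(onset = onsets, amplitude = total_amp * w,
                         duration = durs),
         t_end = t)
  }

  out <- fragment_stroke(amplitude, base_out, lead_in)
  t_dwell_end <- out$t_end + dwell * slow
  back <- fragment_stroke(-amplitude, base_back, t_dwell_end)
  subs <- rbind(out$df, back$df)

  n_jit <- stats::rpois(1, 6 * severity)
  if (n_jit > 0) {
    subs <- rbind(subs, data.frame(
      onset = stats::runif(n_jit, lead_in, max(lead_in + 0.4,
                                               back$t_end - 0.3)),
      amplitude = stats::rnorm(n_jit, 0, 0.006 + 0.018 * severity),
      duration = stats::runif(n_jit, 0.3, 0.6)
    ))
  }
  submovement_drive(subs, tail = tail)
}

#' Total duration of a drive profile
#' @param drive A `drive_profile`.
#' @return Duration in seconds.
#' @export
drive_duration <- function(drive) {
  stopifnot(inherits(drive, "drive_profile"))
  switch(drive$kind,
    min_jerk = {
      base <- drive$lead_in + drive$out_duration + drive$dwell +
        drive$back_duration + drive$tail
      if (!is.null(drive$submovements)) {
        base <- max(base, max(drive$submovements$onset +
                                drive$submovements$duration) + drive$tail)
      }
      base
    },
    submovements = max(drive$submovements$onset +
                         drive$submovements$duration) + drive$tail,
    sampled = max(drive$time)
  )
}

# Minimum-jerk unit sigmoid and derivatives on tau in [0,1]; clamped outside.
mj_s <- function(tau) {
  tau <- pmin(pmax(tau, 0), 1)
  tau^3 * (10 - 15 * tau + 6 * tau^2)
}
mj_ds <- function(tau) {
  inside <- tau > 0 & tau < 1
  tau <- pmin(pmax(tau, 0), 1)
  ifelse(inside, 30 * tau^2 - 60 * tau^3 + 30 * tau^4, 0)
}
mj_dds <- function(tau) {
  inside <- tau > 0 & tau < 1
  tau <- pmin(pmax(tau, 0), 1)
  ifelse(inside, 60 * tau - 180 * tau^2 + 120 * tau^3, 0)
}

# Evaluate one minimum-jerk displacement increment (amplitude A over
# [t0, t0+T]) at times t; returns x, v, a contributions.
mj_pulse <- function(t, t0, A, T) {
  tau <- (t - t0) / T
  list(x = A * mj_s(tau), v = A * mj_ds(tau) / T, a = A * mj_dds(tau) / T^2)
}

#' Evaluate a drive profile
#'
#' @param drive A `drive_profile`.
#' @param t Numeric vector of times (s); values outside the profile's span
#'   evaluate to the held endpoint positions with zero velocity.
#' @return A data.frame with columns `t`, `x` (m), `v` (m/s), `a` (m/s^2).
#'   For the minimum-jerk kinds the profile is C1-continuous (C2 except at
#'   submovement boundaries where acceleration is still continuous and zero).
#' @export
eval_drive <- function(drive, t) {
  stopifnot(inherits(drive, "drive_profile"), is.numeric(t),
            all(is.finite(t)))
  out <- switch(drive$kind,
    min_jerk = {
      x <- numeric(length(t)); v <- numeric(length(t)); a <- numeric(length(t))
      # outward stroke
      p <- mj_pulse(t, drive$lead_in, drive$amplitude, drive$out_duration)
      x <- x + p$x; v <- v + p$v; a <- a + p$a
      # return stroke (negative increment)
      t_back <- drive$lead_in + drive$out_duration + drive$dwell
      p <- mj_pulse(t, t_back, -drive$amplitude, drive$back_duration)
      x <- x + p$x; v <- v + p$v; a <- a + p$a
      if (!is.null(drive$submovements)) {
        for (i in seq_len(nrow(drive$submovements))) {
          s <- drive$submovements[i, ]
          p <- mj_pulse(t, s$onset, s$amplitude, s$duration)
          x <- x + p$x; v <- v + p$v; a <- a + p$a
        }
      }
      list(x = x, v = v, a = a)
    },
    submovements = {
      x <- numeric(length(t)); v <- numeric(length(t)); a <- numeric(length(t))
      for (i in seq_len(nrow(drive$submovements))) {
        s <- drive$submovements[i, ]
        p <- mj_pulse(t, s$onset, s$amplitude, s$duration)
        x <- x + p$x; v <- v + p$v; a <- a + p$a
      }
      list(x = x, v = v, a = a)
    },
    sampled = {
      tc <- pmin(pmax(t, min(drive$time)), max(drive$time))
      list(
        x = drive$spline(tc),
        v = drive$spline(tc, deriv = 1),
        a = drive$spline(tc, deriv = 2)
      )
    }
  )
  data.frame(t = t, x = out$x, v = out$v, a = out$a)
}

#' @export
print.drive_profile <- function(x, ...) {
  cat(sprintf("<drive_profile: %s, duration %.3g s", x$kind,
              drive_duration(x)))
  if (x$kind == "min_jerk") {
    cat(sprintf(", amplitude %.3g m, %d submovement(s)", x$amplitude,
                if (is.null(x$submovements)) 0L else nrow(x$submovements)))
  }
  cat(">\n")
  invisible(x)
}
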