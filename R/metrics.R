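#' Movement time
#'
#' Time to complete extension and flexion: the span of the active segment,
#' whose endpoints are the first and last frames with absolute cup velocity
#' above 5\% of the trial's peak.
#'
#' @param kin A [kinematics1d] with the active segment marked.
#' @return Movement time in seconds.
#' @export
movement_time <- function(kin) {
  stopifnot(inherits(kin, "kinematics1d"))
  if (is.null(kin$segment)) {
    stop("movement_time: no active segment; run find_active_segment()",
         call. = FALSE)
  }
  kin$t[kin$segment[2]] - kin$t[kin$segment[1]]
}

#' SPARC smoothness of a speed profile
#'
#' Spectral arc length: the negated arc length of the normalized magnitude
#' spectrum \eqn{\hat V(\omega) = V(\omega)/V(0)} of the speed profile over
#' \eqn{[0, \omega_c]}, with the frequency axis scaled by \eqn{\omega_c},
#' \deqn{SPARC = -\int_0^{\omega_c}\sqrt{\left(\frac{1}{\omega_c}\right)^2 +
#'   \left(\frac{d\hat V}{d\omega}\right)^2}\, d\omega .}
#' The cutoff \eqn{\omega_c} adapts to the signal: it is the largest
#' frequency not exceeding \eqn{\omega_{cmax}} beyond which the normalized
#' spectrum stays below the threshold \eqn{\bar V}; the cap removes
#' high-frequency noise. Less smooth profiles have more frequency content,
#' a longer spectral arc, and hence a more negative SPARC. The DC
#' normalization makes the metric amplitude-invariant and the
#' frequency-axis scaling makes it duration-invariant.
#'
#' @param speed Speed samples \eqn{|\dot X|} over the active segment
#'   (at least 8 samples, not all zero).
#' @param sample_rate Sampling rate (Hz).
#' @param vbar Spectral amplitude threshold \eqn{\bar V}, default 0.05.
#' @param omega_cmax Cutoff cap in rad/s, default \eqn{20\pi} (10 Hz).
#' @param pad_min Minimum FFT length after zero-padding, default 65536
#'   (a 0.0012 Hz grid at 80 Hz sampling: fine enough that the discrete arc
#'   length is grid-converged and the cutoff search granularity is far below
#'   any spectral feature of interest; the zero-padded spectrum is the
#'   band-limited interpolation of the segment's spectrum, so refining the
#'   grid converges rather than adding wiggle).
#' @return SPARC in arbitrary units (always \eqn{\le 0}).
#' @examples
#' fs <- 80; t <- seq(0, 1, by = 1 / fs)
#' v <- sin(pi * t)^2                   # single-peaked speed profile
#' sparc(v, fs)
#' sparc(2 * v, fs)                     # amplitude-invariant
#' @export
sparc <- function(speed, sample_rate, vbar = 0.05, omega_cmax = 20 * pi,
                  pad_min = 65536) {
  stopifnot(is.numeric(speed), sample_rate > 0, vbar > 0, omega_cmax > 0)
  if (length(speed) < 8) {
    stop("sparc: need at least 8 speed samples", call. = FALSE)
  }
  if (all(speed == 0)) stop("sparc: all-zero speed profile", call. = FALSE)
  n <- length(speed)
  nfft <- max(pad_min, 2^ceiling(log2(4 * n)))
  V <- Mod(stats::fft(c(speed, rep(0, nfft - n))))
  half <- seq_len(nfft %/% 2 + 1L)
  V <- V[half]
  f <- (half - 1L) * sample_rate / nfft
  if (V[1] == 0) stop("sparc: zero DC component", call. = FALSE)
  Vh <- V / V[1]
  f_max <- omega_cmax / (2 * pi)
  sel <- which(f <= f_max)
  above <- which(Vh[sel] >= vbar)
  # omega_c: last frequency below the cap after which Vhat stays under vbar
  keep <- above[1]:above[length(above)]
  fS <- f[sel][keep]
  VS <- Vh[sel][keep]
  f_range <- fS[length(fS)] - fS[1]
  -sum(sqrt((diff(fS) / f_range)^2 + diff(VS)^2))
}

#' Energy trace of the ball
#'
#' Mechanical energy bookkeeping behind the risk metric:
#' \eqn{E_{Kin} = \tfrac12 m_b l^2 \dot\theta^2},
#' \eqn{E_{Pot} = m_b g l(1-\cos\theta)},
#' \eqn{E_{Total} = E_{Kin}+E_{Pot}},
#' \eqn{E_{ESC} = m_b g l(1-\cos\theta_{ESC})}, and the margin
#' \eqn{E_{MARGIN}(t) = E_{ESC} - E_{Total}(t)}. The evaluation times
#' \eqn{t_i} are the interior local maxima of the ball-angle magnitude
#' \eqn{|\theta|} (strict neighbour comparison; plateaus contribute their
#' midpoint; maxima with prominence under 0.5 deg are discarded as sensor
#' noise).
#'
#' @param theta Ball angle series (rad).
#' @param theta_dot Ball angular velocity series (rad/s).
#' @param time Sample times (s).
#' @param system A [cup_ball_system()].
#' @param min_prominence Minimum peak prominence (rad), default 0.5 deg.
#' @return An object of class `energy_trace`: `e_kinetic`, `e_potential`,
#'   `e_total`, `e_margin` (J, pointwise), scalar `e_esc`, maxima indices
#'   `maxima_idx`, times `maxima_t`, and count `n_maxima`.
#' @export
energy_trace <- function(theta, theta_dot, time, system,
                         min_prominence = 0.5 * pi / 180) {
  stopifnot(inherits(system, "cup_ball_system"),
            length(theta) == length(theta_dot),
            length(theta) == length(time))
  if (is.null(theta)) stop("energy_trace: ball data absent", call. = FALSE)
  m <- system$ball_mass; l <- system$pendulum_length; g <- system$gravity
  ek <- 0.5 * m * l^2 * theta_dot^2
  ep <- m * g * l * (1 - cos(theta))
  et <- ek + ep
  eesc <- escape_energy(system)
  idx <- local_maxima(abs(theta), min_prominence = min_prominence)
  structure(
    list(e_kinetic = ek, e_potential = ep, e_total = et,
         e_margin = eesc - et, e_esc = eesc,
         maxima_idx = idx, maxima_t = time[idx], n_maxima = length(idx),
         time = time),
    class = "energy_trace"
  )
}

#' Interior local maxima with a prominence floor
#'
#' Strict neighbour comparison (`x[i]` greater than both neighbours);
#' plateaus of equal values flanked by lower samples count once, at the
#' plateau midpoint. Peaks whose prominence (height above the higher of the
#' two bounding minima, walking out to the nearest higher ground or the
#' series ends) is below `min_prominence` are dropped. Endpoints are never
#' maxima.
#'
#' @param x Numeric series.
#' @param min_prominence Minimum prominence in the units of `x`; 0 keeps
#'   every strict local maximum.
#' @return Integer indices of the maxima.
#' @export
local_maxima <- function(x, min_prominence = 0) {
  n <- length(x)
  if (n < 3) return(integer(0))
  cand <- integer(0)
  i <- 2L
  while (i <= n - 1L) {
    if (x[i] > x[i - 1L]) {
      j <- i
      while (j < n && x[j + 1L] == x[i]) j <- j + 1L
      if (j < n && x[j + 1L] < x[i]) {
        cand <- c(cand, as.integer(floor((i + j) / 2)))
      }
      i <- j + 1L
    } else {
      i <- i + 1L
    }
  }
  if (min_prominence <= 0 || length(cand) == 0) return(cand)
  keep <- vapply(cand, function(p) {
    lo_l <- min(x[1:p])
    k <- which(x[1:p] > x[p])
    if (length(k)) lo_l <- min(x[max(k):p])
    lo_r <- min(x[p:n])
    k <- which(x[p:n] > x[p])
    if (length(k)) lo_r <- min(x[p:(p + min(k) - 1L)])
    (x[p] - max(lo_l, lo_r)) >= min_prominence
  }, logical(1))
  cand[keep]
}

#' Energy-margin risk metric
#'
#' \deqn{Risk = 1 - \frac{1}{n}\frac{1}{E_{ESC}}\sum_{i=1}^n
#'   E_{MARGIN}(t_i)} over the \eqn{n} ball-angle-magnitude maxima. 0 when
#' the ball is energetically at rest at every maximum, 1 when the mean
#' margin is zero; values above 1 are possible when the total energy
#' exceeded the escape energy and are deliberately not clamped (they mark
#' escapes).
#'
#' @param trace An [energy_trace()].
#' @return Dimensionless risk.
#' @export
risk <- function(trace) {
  stopifnot(inherits(trace, "energy_trace"))
  if (trace$n_maxima < 1) {
    stop("risk: no ball-angle maxima found (ball never oscillates); metric undefined",
         call. = FALSE)
  }
  1 - mean(trace$e_margin[trace$maxima_idx]) / trace$e_esc
}

dominant_frequency <- function(x, fs, nfft_min = 4096, floor_factor = 5) {
  x <- x - mean(x)
  n <- length(x)
  nfft <- max(nfft_min, 2^ceiling(log2(2 * n)))
  M <- Mod(stats::fft(c(x, rep(0, nfft - n))))
  half <- 2:(nfft %/% 2 + 1L) # exclude DC
  M <- M[half]
  f <- (half - 1L) * fs / nfft
  pk <- which.max(M)
  if (M[pk] < floor_factor * stats::median(M)) return(NA_real_)
  f[pk]
}

#' Cup and ball phase series
#'
#' Near-sinusoidal kinematics are represented as phase in normalized state
#' space: \eqn{\phi(t) = \mathrm{atan2}(\dot s/(2\pi f),\; s - \bar s)} for
#' a signal \eqn{s} with characteristic frequency \eqn{f}. The
#' four-quadrant form keeps the phase defined on the full circle. The
#' characteristic frequencies \eqn{f_X} (cup) and \eqn{f_\theta} (ball) are
#' estimated per trial as the dominant non-DC spectral peak of the centered
#' signal on the active segment; when no peak clears the spectral noise
#' floor the ball falls back to the pendulum natural frequency
#' \eqn{\sqrt{g/l}/(2\pi)} and the cup to one cycle per segment.
#'
#' @param kin A [kinematics1d] with segment and (for the ball) angle data.
#' @param system A [cup_ball_system()] for the fallback frequency; defaults
#'   to the one stored in `kin`.
#' @return An object of class `phase_series`: `phi_cup`, `phi_ball`
#'   (radians in \eqn{(-\pi,\pi]}, on the active segment), `f_x`,
#'   `f_theta` (Hz), and the segment used.
#' @export
phase_series <- function(kin, system = kin$system) {
  stopifnot(inherits(kin, "kinematics1d"))
  if (is.null(kin$segment)) stop("phase_series: no active segment",
                                 call. = FALSE)
  if (is.null(kin$theta)) stop("phase_series: ball data absent",
                               call. = FALSE)
  i <- kin$segment[1]:kin$segment[2]
  fs <- kin$sample_rate
  xs <- kin$x[i]; vs <- kin$v[i]
  th <- kin$theta[i]; thd <- kin$theta_dot[i]
  if (stats::sd(xs) == 0 || stats::sd(th) == 0) {
    stop("phase_series: degenerate (constant) signal on segment",
         call. = FALSE)
  }
  seg_dur <- (length(i) - 1) / fs
  f_x <- dominant_frequency(xs, fs)
  if (is.na(f_x)) f_x <- 1 / seg_dur
  f_th <- dominant_frequency(th, fs)
  if (is.na(f_th)) {
    f_th <- if (!is.null(system)) natural_frequency(system) else 1 / seg_dur
  }
  structure(
    list(
      phi_cup = atan2(vs / (2 * pi * f_x), xs - mean(xs)),
      phi_ball = atan2(thd / (2 * pi * f_th), th - mean(th)),
      f_x = f_x, f_theta = f_th, segment = kin$segment,
      t = kin$t[i]
    ),
    class = "phase_series"
  )
}

#' Mutual information between cup and ball phases
#'
#' Histogram estimator of
#' \deqn{MI = \sum_{b,c} P(b,c)\,\ln\frac{P(b,c)}{P(b)P(c)}}
#' over a `bins` x `bins` grid on \eqn{(-\pi,\pi]^2}; empty cells contribute
#' zero; natural log, so the value is in nats. Computed on the same
#' 5\%-velocity active segment as SPARC. High MI means the ball dynamics
#' are predictable from the cup kinematics.
#'
#' @param x A `phase_series`, or a numeric phase vector (then `y` is
#'   required).
#' @param y Second phase vector when `x` is numeric.
#' @param bins Histogram bins per dimension, default 10.
#' @return Mutual information in nats (non-negative up to round-off).
#' @export
mutual_information <- function(x, y = NULL, bins = 10) {
  if (inherits(x, "phase_series")) {
    y <- x$phi_cup
    x <- x$phi_ball
  }
  stopifnot(is.numeric(x), is.numeric(y), length(x) == length(y),
            bins >= 2)
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]; y <- y[ok]
  n <- length(x)
  if (n == 0) stop("mutual_information: empty segment", call. = FALSE)
  if (n < 10 * bins) {
    warning(sprintf(
      "mutual_information: %d samples for %d^2 cells; estimate may be biased",
      n, bins), call. = FALSE)
  }
  bin_of <- function(p) pmin(bins, floor((p + pi) / (2 * pi) * bins) + 1L)
  bx <- bin_of(x); by <- bin_of(y)
  joint <- matrix(0, bins, bins)
  for (k in seq_len(n)) joint[bx[k], by[k]] <- joint[bx[k], by[k]] + 1
  p <- joint / n
  px <- rowSums(p); py <- colSums(p)
  occ <- which(p > 0, arr.ind = TRUE)
  sum(p[occ] * log(p[occ] / (px[occ[, 1]] * py[occ[, 2]])))
}

#' Compute the full per-trial metric set
#'
#' Dispatches the four performance metrics on a preprocessed trial:
#' movement time and SPARC always; energy-margin risk and cup-ball phase
#' mutual information only when ball data are present (absent, not zero,
#' otherwise). Per-metric failures are collected as flags without aborting
#' the remaining metrics. Risk is evaluated over the full recorded trial;
#' movement time, SPARC and MI use the 5\%-velocity active segment.
#'
#' @param kin A [kinematics1d] from [preprocess_trial()].
#' @param system A [cup_ball_system()]; defaults to the one in `kin`.
#' @param mi_bins Histogram bins per dimension for MI, default 10.
#' @param sparc_vbar,sparc_omega_cmax SPARC parameters (see [sparc()]).
#' @param escape_detected Optional logical from the simulator/recording
#'   metadata, stored as a flag.
#' @return An object of class `metric_set`: `movement_time` (s), `sparc`
#'   (a.u.), `risk`, `mutual_information` (nat) (the latter two `NA` when
#'   inapplicable), `segment`, `f_x`, `f_theta`, `mi_bins`, and a character
#'   vector `flags` (subset of `ball_absent`, `escape_detected`,
#'   `short_segment`, `risk_undefined`, `mi_undefined`).
#' @examples
#' rec <- generate_synthetic_trial(seed = 7)
#' m <- compute_metrics(preprocess_trial(rec))
#' m
#' @export
compute_metrics <- function(kin, system = kin$system, mi_bins = 10,
                            sparc_vbar = 0.05, sparc_omega_cmax = 20 * pi,
                            escape_detected = FALSE) {
  stopifnot(inherits(kin, "kinematics1d"))
  if (is.null(kin$segment)) kin <- find_active_segment(kin)
  seg <- kin$segment
  flags <- character(0)
  if (seg[2] - seg[1] < 2) flags <- c(flags, "short_segment")
  if (escape_detected) flags <- c(flags, "escape_detected")

  mt <- movement_time(kin)
  sp <- tryCatch(
    sparc(abs(kin$v[seg[1]:seg[2]]), kin$sample_rate,
          vbar = sparc_vbar, omega_cmax = sparc_omega_cmax),
    error = function(e) NA_real_
  )

  rk <- NA_real_; mi <- NA_real_
  f_x <- NA_real_; f_th <- NA_real_
  if (is.null(kin$theta)) {
    flags <- c(flags, "ball_absent")
  } else {
    rk <- tryCatch(
      risk(energy_trace(kin$theta, kin$theta_dot, kin$t, system)),
      error = function(e) NA_real_
    )
    if (is.na(rk)) flags <- c(flags, "risk_undefined")
    ph <- tryCatch(phase_series(kin, system), error = function(e) NULL)
    if (is.null(ph)) {
      flags <- c(flags, "mi_undefined")
    } else {
      mi <- mutual_information(ph, bins = mi_bins)
      f_x <- ph$f_x; f_th <- ph$f_theta
    }
  }

  structure(
    list(movement_time = mt, sparc = sp, risk = rk,
         mutual_information = mi, segment = seg,
         f_x = f_x, f_theta = f_th, mi_bins = mi_bins, flags = flags,
         subject = kin$subject, hand = kin$hand, condition = kin$condition),
    class = "metric_set"
  )
}

#' @export
print.metric_set <- function(x, ...) {
  cat("<metric_set>\n")
  cat(sprintf("  movement time      : %.3f s\n", x$movement_time))
  cat(sprintf("  SPARC              : %.3f a.u.\n", x$sparc))
  cat(sprintf("  risk               : %s\n",
              if (is.na(x$risk)) "-" else sprintf("%.3f", x$risk)))
  cat(sprintf("  mutual information : %s\n",
              if (is.na(x$mutual_information)) "-" else
                sprintf("%.3f nat", x$mutual_information)))
  cat(sprintf("  segment            : [%d, %d]\n", x$segment[1], x$segment[2]))
  if (length(x$flags)) cat("  flags              :",
                           paste(x$flags, collapse = ", "), "\n")
  invisible(x)
}

#' Serialize a metric set to JSON
#'
#' @param m A `metric_set`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_metrics <- function(m, path) {
  stopifnot(inherits(m, "metric_set"))
  jsonlite::write_json(
    list(
      subject = m$subject, hand = m$hand, condition = m$condition,
      movement_time_s = m$movement_time, sparc = m$sparc,
      risk = if (is.na(m$risk)) NULL else m$risk,
      mutual_information_nat = if (is.na(m$mutual_information)) NULL else
        m$mutual_information,
      segment = m$segment, f_x_hz = m$f_x, f_theta_hz = m$f_theta,
      mi_bins = m$mi_bins, flags = as.list(m$flags),
      segment_indexing = "1-based inclusive"
    ),
    path, auto_unbox = TRUE, digits = NA, null = "null", pretty = TRUE
  )
  invisible(path)
}
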