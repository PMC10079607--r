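# Independent brute-force oracles the implementation is checked against.
# These deliberately use plain loops and direct definitions, not the
# package's vectorized code paths.

# Spectral arc length recomputed with an explicit cutoff scan and a plain
# trapezoid-style loop over the same zero-padded magnitude spectrum.
oracle_sparc <- function(speed, fs, vbar = 0.05, omega_cmax = 20 * pi,
                         pad_min = 65536) {
  n <- length(speed)
  nfft <- max(pad_min, 2^ceiling(log2(4 * n)))
  V <- Mod(stats::fft(c(speed, rep(0, nfft - n))))
  nh <- nfft %/% 2 + 1
  V <- V[1:nh]
  f <- (0:(nh - 1)) * fs / nfft
  Vh <- V / V[1]
  f_max <- omega_cmax / (2 * pi)
  # scan for the last frequency <= f_max whose normalized magnitude >= vbar
  i_cut <- NA
  for (i in seq_len(nh)) {
    if (f[i] > f_max) break
    if (Vh[i] >= vbar) i_cut <- i
  }
  total <- 0
  f_range <- f[i_cut] - f[1]
  for (i in 2:i_cut) {
    df <- (f[i] - f[i - 1]) / f_range
    dv <- Vh[i] - Vh[i - 1]
    total <- total + sqrt(df * df + dv * dv)
  }
  -total
}

# Energy-margin risk recomputed from first principles with a plain scan for
# ball-angle-magnitude maxima (strict neighbours, plateau midpoint,
# prominence by direct definition).
oracle_risk <- function(theta, theta_dot, system,
                        min_prom = 0.5 * pi / 180) {
  m <- system$ball_mass
  l <- system$pendulum_length
  g <- system$gravity
  e_tot <- 0.5 * m * l^2 * theta_dot^2 + m * g * l * (1 - cos(theta))
  e_esc <- m * g * l * (1 - cos(system$escape_angle))
  a <- abs(theta)
  n <- length(a)
  peaks <- integer(0)
  i <- 2
  while (i <= n - 1) {
    if (a[i] > a[i - 1]) {
      j <- i
      while (j < n && a[j + 1] == a[i]) j <- j + 1
      if (j < n && a[j + 1] < a[i]) {
        p <- as.integer(floor((i + j) / 2))
        # prominence: drop to the nearest higher ground on each side
        left <- a[1:p]
        hi <- which(left > a[p])
        lo_l <- if (length(hi)) min(left[max(hi):p]) else min(left)
        right <- a[p:n]
        hi <- which(right > a[p])
        lo_r <- if (length(hi)) min(right[1:min(hi)]) else min(right)
        if (a[p] - max(lo_l, lo_r) >= min_prom) peaks <- c(peaks, p)
      }
      i <- j + 1
    } else {
      i <- i + 1
    }
  }
  if (length(peaks) == 0) return(NA_real_)
  s <- 0
  for (p in peaks) s <- s + (e_esc - e_tot[p])
  1 - (s / length(peaks)) / e_esc
}

# Mutual information by an explicit double loop over histogram cells.
oracle_mi <- function(x, y, bins = 10) {
  n <- length(x)
  bin_of <- function(p) min(bins, floor((p + pi) / (2 * pi) * bins) + 1)
  joint <- matrix(0, bins, bins)
  for (k in 1:n) {
    i <- bin_of(x[k]); j <- bin_of(y[k])
    joint[i, j] <- joint[i, j] + 1
  }
  p <- joint / n
  px <- rowSums(p); py <- colSums(p)
  mi <- 0
  for (i in 1:bins) {
    for (j in 1:bins) {
      if (p[i, j] > 0) mi <- mi + p[i, j] * log(p[i, j] / (px[i] * py[j]))
    }
  }
  mi
}

# Marginal entropy from the same histogram binning as the MI estimator.
oracle_entropy <- function(x, bins = 10) {
  bin_of <- function(p) min(bins, floor((p + pi) / (2 * pi) * bins) + 1)
  counts <- numeric(bins)
  for (k in seq_along(x)) {
    i <- bin_of(x[k])
    counts[i] <- counts[i] + 1
  }
  p <- counts / length(x)
  -sum(p[p > 0] * log(p[p > 0]))
}
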