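# Independent oracles and fixture builders used across the suite.

# Brute-force trigonometric Fourier-series reconstruction keeping harmonics
# with frequency <= cutoff. Deliberately built from explicit cos/sin sums,
# not from an inverse FFT, so it is an independent path from
# truncated_fourier_filter().
fourier_series_oracle <- function(x, fs, cutoff) {
  n <- length(x)
  idx <- 0:(n - 1)
  ks <- seq_len(floor(n / 2))
  ks <- ks[ks * fs / n <= cutoff & ks * fs / n < fs / 2]
  rec <- rep(mean(x), n)
  if (length(ks) == 0L) return(rec)
  ang <- outer(idx, ks) * (2 * pi / n)
  ca <- cos(ang); sa <- sin(ang)
  a <- as.numeric(crossprod(ca, x)) * 2 / n
  b <- as.numeric(crossprod(sa, x)) * 2 / n
  # the k = n/2 bin of an even-length series is not paired; it is never kept
  # because cutoff < fs/2
  rec + as.numeric(ca %*% a) + as.numeric(sa %*% b)
}

# Analytic magnitude response of a single-pass analog Butterworth low-pass.
butterworth_magnitude <- function(f, fc, order) 1 / sqrt(1 + (f / fc)^(2 * order))

# Half-sine stance embedded in a zero trace: F(t) = fmax*sin(pi*(t-t0)/tc)
# on [t0, t0+tc], sampled at fs.
half_sine_force <- function(t0 = 1, tc = 0.28, fmax = 1500, fs = 200,
                            t_end = 2.3, body_mass = 61) {
  t <- seq(0, t_end, by = 1 / fs)
  fz <- ifelse(t >= t0 & t <= t0 + tc, fmax * sin(pi * (t - t0) / tc), 0)
  force_trace(t, fz, body_mass = body_mass, fs = fs)
}

# Analytic threshold-crossing times of the half-sine stance.
half_sine_crossings <- function(t0 = 1, tc = 0.28, fmax = 1500,
                                threshold = 20) {
  dt <- (tc / pi) * asin(threshold / fmax)
  c(fs = t0 + dt, to = t0 + tc - dt)
}

# Stationary accelerometer trace reading a constant 3-vector (in g).
stationary_trace <- function(g_vec, dur = 3, fs = 208, noise = 0) {
  t <- seq(0, dur, by = 1 / fs)
  n <- length(t)
  accel_trace(t,
              ax = g_vec[1] + noise * sin(9999 * t),
              ay = g_vec[2] + noise * cos(7777 * t),
              az = g_vec[3] + noise * sin(5555 * t),
              fs = fs)
}

# Rotation matrix about an arbitrary axis (Rodrigues), independent of the
# package's internal construction.
rotation_about <- function(axis, angle) {
  k <- axis / sqrt(sum(axis^2))
  K <- matrix(c(0, k[3], -k[2], -k[3], 0, k[1], k[2], -k[1], 0), 3)
  diag(3) + sin(angle) * K + (1 - cos(angle)) * (K %*% K)
}

# Periodic-waveform oracle for the IMU method's 5 Hz stance deformation:
# one exact period of the half-sine train at very high resolution, DFT bins
# above `cutoff` zeroed, threshold crossings and peak re-solved on the fine
# grid. Returns the deformed tc (s) and peak (BW).
truncation_deformation_oracle <- function(tc, tf, fzmax_bw, cutoff = 5,
                                          threshold_bw = 20 / (70 * 9.80665),
                                          n = 2^16) {
  period <- tc + tf
  tt <- (0:(n - 1)) * period / n
  w <- ifelse(tt <= tc, fzmax_bw * sin(pi * tt / tc), 0)
  X <- stats::fft(w)
  k <- 0:(n - 1)
  k <- ifelse(k > n / 2, k - n, k)
  X[abs(k) / period > cutoff] <- 0
  wr <- Re(stats::fft(X, inverse = TRUE)) / n
  thr <- threshold_bw
  up <- which(wr[-n] < thr & wr[-1] >= thr)
  dn <- which(wr[-n] >= thr & wr[-1] < thr)
  stopifnot(length(up) == 1L, length(dn) == 1L)
  step <- period / n
  t_up <- tt[up] + (thr - wr[up]) * step / (wr[up + 1] - wr[up])
  t_dn <- tt[dn] + (thr - wr[dn]) * step / (wr[dn + 1] - wr[dn])
  tc_def <- if (t_dn > t_up) t_dn - t_up else t_dn + period - t_up
  list(tc = tc_def, tf = period - tc_def, fzmax = max(wr))
}
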