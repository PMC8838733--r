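#' Truncated Fourier-series low-pass filter
#'
#' Low-pass filters a uniformly sampled series by discrete Fourier transform:
#' every frequency bin whose absolute frequency exceeds `cutoff` is zeroed and
#' the series is reconstructed by the inverse transform. The DC component is
#' always preserved, so the output mean equals the input mean. No taper or
#' padding is applied; the transform acts on the raw window, so a component
#' that is not bin-aligned leaks across bins and some edge ringing is
#' expected. Analyses therefore work in the trial interior, away from the
#' window edges.
#'
#' @param x Numeric series (length >= 2).
#' @param fs Sample rate in Hz.
#' @param cutoff Cutoff frequency in Hz, `0 < cutoff < fs/2`.
#' @param keep_cutoff_bin If `TRUE` (default) a bin lying exactly at `cutoff`
#'   is kept (comparison `<=`); if `FALSE` it is dropped (`<`).
#' @return Real numeric series of the same length as `x`.
#' @examples
#' t <- seq(0, 10 - 1/208, by = 1/208)
#' x <- sin(2 * pi * 2 * t) + sin(2 * pi * 8 * t)
#' y <- truncated_fourier_filter(x, fs = 208, cutoff = 5)  # keeps only 2 Hz
#' @export
truncated_fourier_filter <- function(x, fs, cutoff, keep_cutoff_bin = TRUE) {
  n <- length(x)
  if (n < 2L) stop("input series must have at least 2 samples")
  if (anyNA(x)) stop("input series contains NA")
  if (!is.finite(fs) || fs <= 0) stop("fs must be positive")
  if (cutoff <= 0) stop("cutoff must be positive")
  if (cutoff >= fs / 2) stop("cutoff above Nyquist")
  k <- 0:(n - 1L)
  k <- ifelse(k > n / 2, k - n, k)      # signed bin index
  freq <- abs(k) * fs / n
  keep <- if (keep_cutoff_bin) freq <= cutoff else freq < cutoff
  X <- stats::fft(x)
  X[!keep] <- 0
  Re(stats::fft(X, inverse = TRUE)) / n
}

#' Estimate sensor tilt from the gravity direction
#'
#' Recovers the orientation of a body-worn accelerometer relative to the
#' laboratory vertical. Each axis is low-pass filtered with a truncated
#' Fourier series (default 0.5 Hz) so only the quasi-static gravity component
#' survives, the per-axis medians form the gravity direction in the sensor
#' frame, and the minimal (axis-angle) rotation mapping that direction onto
#' the laboratory vertical `[0, 0, 1]` is returned.
#'
#' @param trace An [accel_trace] longer than 2 s (so the 0.5 Hz truncation is
#'   meaningful).
#' @param cutoff Truncation frequency in Hz for the gravity extraction
#'   (default 0.5).
#' @param keep_cutoff_bin Passed to [truncated_fourier_filter()].
#' @return An object of class `rotation3`: list with `matrix` (3x3 orthonormal,
#'   det +1) and `tilt_angle` (radians in `[0, pi]` between the sensor z-axis
#'   and the laboratory vertical).
#' @details The antipodal case (sensor exactly upside down, tilt pi) has no
#'   unique minimal axis; the laboratory x-axis is used. A median gravity
#'   vector with norm below 0.1 g (e.g. a sensor in sustained free fall)
#'   carries no usable reference and is an error.
#' @export
estimate_tilt <- function(trace, cutoff = 0.5, keep_cutoff_bin = TRUE) {
  stopifnot(inherits(trace, "accel_trace"))
  if (diff(range(trace$t)) <= 2)
    stop("trace must be longer than 2 s to estimate tilt")
  g_med <- vapply(c("ax", "ay", "az"), function(axis) {
    stats::median(truncated_fourier_filter(trace[[axis]], trace$fs, cutoff,
                                           keep_cutoff_bin))
  }, 0)
  nrm <- sqrt(sum(g_med^2))
  if (nrm < 0.1) stop("no gravity reference")
  g_hat <- g_med / nrm
  cosang <- max(-1, min(1, g_hat[3]))
  ang <- acos(cosang)
  axis <- c(g_hat[2], -g_hat[1], 0)          # g_hat x e3
  axis_norm <- sqrt(sum(axis^2))
  if (axis_norm < 1e-12) {
    if (cosang > 0) {                         # already aligned
      return(structure(list(matrix = diag(3), tilt_angle = ang),
                       class = "rotation3"))
    }
    axis <- c(1, 0, 0)                        # antipodal: rotate about lab x
  } else {
    axis <- axis / axis_norm
  }
  K <- matrix(c(0, axis[3], -axis[2],
                -axis[3], 0, axis[1],
                axis[2], -axis[1], 0), nrow = 3)   # column-major skew(axis)
  R <- diag(3) + sin(ang) * K + (1 - cos(ang)) * (K %*% K)
  structure(list(matrix = R, tilt_angle = ang), class = "rotation3")
}

#' @export
print.rotation3 <- function(x, ...) {
  cat(sprintf("<rotation3> tilt angle %.4f rad (%.2f deg)\n",
              x$tilt_angle, x$tilt_angle * 180 / pi))
  invisible(x)
}

#' Reorient an acceleration trace
#'
#' Applies a rigid rotation to every 3-axis sample, typically the output of
#' [estimate_tilt()], aligning the sensor z-axis with the laboratory
#' vertical. Time stamps and sample rate are unchanged; per-sample vector
#' norms are preserved.
#'
#' @param trace An [accel_trace].
#' @param rot A `rotation3` from [estimate_tilt()], or any 3x3 orthonormal
#'   matrix.
#' @return A reoriented [accel_trace].
#' @export
reorient <- function(trace, rot) {
  stopifnot(inherits(trace, "accel_trace"))
  R <- if (inherits(rot, "rotation3")) rot$matrix else rot
  if (!is.matrix(R) || !all(dim(R) == c(3, 3)))
    stop("rot must be a rotation3 or a 3x3 matrix")
  if (max(abs(crossprod(R) - diag(3))) > 1e-8)
    stop("rotation matrix is not orthonormal")
  A <- cbind(trace$ax, trace$ay, trace$az) %*% t(R)
  new_accel_trace(trace$t, A[, 1], A[, 2], A[, 3], trace$fs,
                  trace$saturation_g)
}

#' Convert vertical acceleration to vertical ground reaction force
#'
#' Applies Newton's second law to a proper-acceleration signal: a sensor
#' reading of `a` g corresponds to a vertical ground reaction force
#' `a * g0 * body_mass` N, so a static sensor (1 g) yields exactly body
#' weight and free fall (0 g) yields 0 N. Negative values are not clipped;
#' whether sub-zero reconstructed force matters is the event detector's
#' concern.
#'
#' @param az_g Vertical acceleration series in g (typically the reoriented,
#'   5 Hz-truncated z-axis).
#' @param t Sample times in seconds matching `az_g`.
#' @param body_mass Body mass in kg.
#' @param g0 Gravitational acceleration in m/s^2 (default 9.80665).
#' @param fs Sample rate in Hz; inferred from `t` when `NULL`.
#' @return A [force_trace] with `fz = az_g * g0 * body_mass`.
#' @examples
#' accel_to_vgrf(rep(1, 3), t = c(0, 0.005, 0.01), body_mass = 70, g0 = 9.81)
#' @export
accel_to_vgrf <- function(az_g, t, body_mass, g0 = 9.80665, fs = NULL) {
  if (body_mass <= 0) stop("body_mass must be positive")
  if (g0 <= 0) stop("g0 must be positive")
  force_trace(t = t, fz = az_g * g0 * body_mass, body_mass = body_mass,
              fs = fs)
}
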