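#' Three-axis accelerometer trace
#'
#' Container for a time-stamped 3-axis acceleration recording in g. Axes
#' follow the sacral-IMU convention: `ax` medio-lateral, `ay`
#' posterior-anterior, `az` inferior-superior. A sensor at rest reads 1 g
#' along its vertical axis (proper acceleration); free fall reads 0 g.
#'
#' @param t Sample times in seconds, strictly increasing.
#' @param ax,ay,az Acceleration in g along the x/y/z sensor axes.
#' @param fs Nominal sample rate in Hz; inferred as `1/median(diff(t))` when
#'   `NULL`.
#' @param saturation_g Symmetric clip bound of the sensor in g (default 8).
#'   Samples exceeding it are rejected; samples exactly at it are accepted
#'   (and flagged by readers as saturated).
#' @return An object of class `accel_trace`: a list with elements `t`, `ax`,
#'   `ay`, `az`, `fs`, `saturation_g`.
#' @examples
#' tr <- accel_trace(t = seq(0, 1, by = 1/208),
#'                   ax = 0, ay = 0, az = 1)
#' tr$fs
#' @export
accel_trace <- function(t, ax, ay, az, fs = NULL, saturation_g = 8) {
  t <- as.numeric(t)
  n <- length(t)
  if (n < 2L) stop("accel_trace needs at least 2 samples")
  axes <- lapply(list(ax = ax, ay = ay, az = az), function(a) {
    a <- as.numeric(a)
    if (length(a) == 1L) a <- rep(a, n)
    a
  })
  lens <- vapply(axes, length, 0L)
  if (any(lens != n)) stop("t, ax, ay, az must have equal length")
  if (anyNA(t) || anyNA(axes$ax) || anyNA(axes$ay) || anyNA(axes$az))
    stop("accel_trace contains NA values")
  if (is.unsorted(t, strictly = TRUE)) stop("t must be strictly increasing")
  if (is.null(fs)) fs <- 1 / stats::median(diff(t))
  if (!is.finite(fs) || fs <= 0) stop("fs must be positive")
  if (saturation_g <= 0) stop("saturation_g must be positive")
  amax <- max(abs(axes$ax), abs(axes$ay), abs(axes$az))
  if (amax > saturation_g + 1e-9)
    stop(sprintf("acceleration %.3f g exceeds saturation range +/-%g g",
                 amax, saturation_g))
  structure(list(t = t, ax = axes$ax, ay = axes$ay, az = axes$az,
                 fs = fs, saturation_g = saturation_g),
            class = "accel_trace")
}

# internal rebuild that skips the saturation check: a rigid rotation preserves
# per-sample norms but can move a single component past the clip bound
new_accel_trace <- function(t, ax, ay, az, fs, saturation_g) {
  structure(list(t = t, ax = ax, ay = ay, az = az,
                 fs = fs, saturation_g = saturation_g),
            class = "accel_trace")
}

#' @export
print.accel_trace <- function(x, ...) {
  cat(sprintf("<accel_trace> %d samples, %.4g-%.4g s, fs = %.5g Hz, +/-%g g\n",
              length(x$t), x$t[1], x$t[length(x$t)], x$fs, x$saturation_g))
  invisible(x)
}

#' Vertical ground reaction force trace
#'
#' Container for a time-stamped vertical force signal in newtons, either
#' measured by a force plate or reconstructed from acceleration. Body mass is
#' carried so peak force can be expressed in body weights (BW).
#'
#' @param t Sample times in seconds, strictly increasing.
#' @param fz Vertical force in N.
#' @param body_mass Body mass in kg (> 0).
#' @param fs Nominal sample rate in Hz; inferred from `t` when `NULL`.
#' @return An object of class `force_trace`.
#' @examples
#' ft <- force_trace(t = seq(0, 1, by = 1/200), fz = 700, body_mass = 70)
#' @export
force_trace <- function(t, fz, body_mass, fs = NULL) {
  t <- as.numeric(t)
  fz <- as.numeric(fz)
  if (length(fz) == 1L) fz <- rep(fz, length(t))
  if (length(t) < 2L) stop("force_trace needs at least 2 samples")
  if (length(t) != length(fz)) stop("t and fz must have equal length")
  if (anyNA(t) || anyNA(fz)) stop("force_trace contains NA values")
  if (is.unsorted(t, strictly = TRUE)) stop("t must be strictly increasing")
  if (!is.numeric(body_mass) || length(body_mass) != 1L || body_mass <= 0)
    stop("body_mass must be a single positive number")
  if (is.null(fs)) fs <- 1 / stats::median(diff(t))
  if (!is.finite(fs) || fs <= 0) stop("fs must be positive")
  structure(list(t = t, fz = fz, fs = fs, body_mass = body_mass),
            class = "force_trace")
}

#' @export
print.force_trace <- function(x, ...) {
  cat(sprintf("<force_trace> %d samples, %.4g-%.4g s, fs = %.5g Hz, mass = %g kg\n",
              length(x$t), x$t[1], x$t[length(x$t)], x$fs, x$body_mass))
  invisible(x)
}

#' Ordered foot-strike / toe-off event times
#'
#' Alternating gait events detected on a vertical force signal. `to_times`
#' may be one shorter than `fs_times` (a trailing stance whose toe-off falls
#' outside the trace, or a deliberately trimmed stride selection).
#'
#' @param fs_times Foot-strike times in seconds, increasing.
#' @param to_times Toe-off times in seconds; `to_times[i]` follows
#'   `fs_times[i]`.
#' @param source Label for the detecting method, `"GSM"` (force plate) or
#'   `"IMUM"` (accelerometer reconstruction).
#' @return An object of class `gait_events`.
#' @export
gait_events <- function(fs_times, to_times, source = c("GSM", "IMUM")) {
  source <- match.arg(source)
  fs_times <- as.numeric(fs_times)
  to_times <- as.numeric(to_times)
  nf <- length(fs_times); nt <- length(to_times)
  if (nf < 1L || nt < 1L) stop("no strides detected")
  if (!(nt == nf || nt == nf - 1L))
    stop("to_times must pair with fs_times (equal length or one shorter)")
  # strict alternation: fs[i] < to[i] < fs[i+1]
  if (any(to_times - fs_times[seq_len(nt)] <= 0))
    stop("every stance duration must be positive")
  if (nf > 1L && any(fs_times[2:nf] - to_times[seq_len(nf - 1L)] <= 0))
    stop("every flight duration must be positive")
  structure(list(fs_times = fs_times, to_times = to_times, source = source),
            class = "gait_events")
}

#' @export
print.gait_events <- function(x, ...) {
  cat(sprintf("<gait_events:%s> %d foot-strikes, %d toe-offs (%.3f-%.3f s)\n",
              x$source, length(x$fs_times), length(x$to_times),
              x$fs_times[1], max(x$fs_times, x$to_times)))
  invisible(x)
}

#' Duty factor of a running step
#'
#' Stance duration as a fraction of the full gait cycle. With events pooled
#' from both feet (a single sacral sensor cannot lateralize), one full cycle
#' spans two steps, so the duty factor is `tc / (2 * (tc + tf))`. Running is
#' characterised by a duty factor below 50%, i.e. the presence of a flight
#' phase.
#'
#' @param tc Contact time(s) in seconds.
#' @param tf Flight time(s) in seconds.
#' @return Duty factor(s), dimensionless.
#' @export
duty_factor <- function(tc, tf) tc / (2 * (tc + tf))
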