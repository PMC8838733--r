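#' Butterworth low-pass filter for force signals
#'
#' Conventional force-plate preprocessing: a 20 Hz low-pass 4th-order
#' Butterworth filter. By default it is applied zero-phase
#' (forward-backward) with an order-compensated design — each pass uses an
#' `order/2` filter so the combined magnitude response is of the requested
#' order, and the design cutoff is raised by Winter's dual-pass correction
#' factor `(sqrt(2) - 1)^(-1/(2 * (order/2)))` so the effective -3 dB point
#' of the two-pass response sits at the requested cutoff (the convention of
#' standard motion-analysis pipelines) — because a single-pass filter would
#' delay every detected event by a speed-dependent lag. A single-pass mode
#' is available.
#'
#' @param force A [force_trace].
#' @param cutoff Cutoff frequency in Hz (default 20).
#' @param order Filter order (default 4); must be even in zero-phase mode.
#' @param zero_phase Apply forward-backward (default `TRUE`).
#' @param cutoff_correction Apply Winter's dual-pass cutoff correction in
#'   zero-phase mode (default `TRUE`).
#' @return A [force_trace] with filtered `fz`.
#' @export
butterworth_lowpass <- function(force, cutoff = 20, order = 4,
                                zero_phase = TRUE,
                                cutoff_correction = TRUE) {
  stopifnot(inherits(force, "force_trace"))
  if (order < 1) stop("order must be >= 1")
  if (cutoff <= 0 || cutoff >= force$fs / 2) stop("cutoff above Nyquist")
  if (zero_phase) {
    if (order %% 2 != 0)
      stop("zero-phase mode needs an even order (order/2 per pass)")
    fc <- if (cutoff_correction) {
      cutoff / (sqrt(2) - 1)^(1 / (2 * (order / 2)))
    } else {
      cutoff
    }
    if (fc >= force$fs / 2)
      stop("cutoff above Nyquist after dual-pass correction")
    bf <- signal::butter(order / 2, fc / (force$fs / 2), type = "low")
    fz <- signal::filtfilt(bf, force$fz)
  } else {
    bf <- signal::butter(order, cutoff / (force$fs / 2), type = "low")
    fz <- as.numeric(signal::filter(bf, force$fz))
  }
  force_trace(t = force$t, fz = fz, body_mass = force$body_mass,
              fs = force$fs)
}

#' Detect foot-strike and toe-off events by force threshold
#'
#' Foot-strikes are upward crossings of the threshold (force rises from
#' below to at-or-above), toe-offs the subsequent downward crossings.
#' Crossing times are refined by linear interpolation between the bracketing
#' samples (or taken as the midpoint of the bracketing interval when
#' `interpolate = FALSE`, bounding the error at half a sample period). An
#' incomplete leading stance (trace starts above threshold) and incomplete
#' trailing phases are discarded. Flights shorter than `min_flight_s` are
#' treated as threshold chatter and merged into one stance; stances shorter
#' than `min_stance_s` are rejected as noise. Both debounce bounds sit far
#' below physiological minima.
#'
#' @param force A [force_trace]; for the gold standard this is the 20 Hz
#'   filtered plate signal, for the IMU method the reconstructed force.
#' @param threshold Detection threshold in N (default 20).
#' @param interpolate Refine crossing times by linear interpolation
#'   (default `TRUE`).
#' @param min_stance_s,min_flight_s Debounce durations in seconds.
#' @param source Label stored on the result (`"GSM"` or `"IMUM"`).
#' @return A [gait_events] with paired events (`to_times[i]` follows
#'   `fs_times[i]`).
#' @export
detect_events_threshold <- function(force, threshold = 20,
                                    interpolate = TRUE,
                                    min_stance_s = 0.025,
                                    min_flight_s = 0.010,
                                    source = c("GSM", "IMUM")) {
  stopifnot(inherits(force, "force_trace"))
  source <- match.arg(source)
  if (threshold <= 0) stop("threshold must be positive")
  t <- force$t; fz <- force$fz
  n <- length(fz)
  above <- fz >= threshold
  idx_up <- which(!above[-n] & above[-1L])
  idx_dn <- which(above[-n] & !above[-1L])
  cross_time <- function(i) {
    if (interpolate) {
      t[i] + (threshold - fz[i]) * (t[i + 1L] - t[i]) / (fz[i + 1L] - fz[i])
    } else {
      (t[i] + t[i + 1L]) / 2
    }
  }
  ups <- vapply(idx_up, cross_time, 0)
  dns <- vapply(idx_dn, cross_time, 0)
  if (length(ups) == 0L) stop("no strides detected")
  dns <- dns[dns > ups[1L]]              # drop incomplete leading stance
  nst <- min(length(ups), length(dns))   # drop incomplete trailing stance
  if (nst == 0L) stop("no strides detected")
  ups <- ups[seq_len(nst)]
  dns <- dns[seq_len(nst)]
  # debounce: first merge chatter flights, then reject chatter stances
  repeat {
    if (length(ups) < 2L) break
    flight <- ups[-1L] - dns[-length(dns)]
    short <- which(flight < min_flight_s)
    if (length(short) == 0L) break
    j <- short[1L]
    dns <- dns[-j]
    ups <- ups[-(j + 1L)]
  }
  keep <- (dns - ups) >= min_stance_s
  ups <- ups[keep]; dns <- dns[keep]
  if (length(ups) == 0L) stop("no strides detected")
  gait_events(fs_times = ups, to_times = dns, source = source)
}

#' Per-stride contact time, flight time, and peak force
#'
#' For stride i (foot-strike i to foot-strike i+1 in the pooled event
#' stream): contact time `tc = to[i] - fs[i]`, flight time
#' `tf = fs[i+1] - to[i]`, and `fz_max` the maximum force sample within the
#' stance, expressed in body weights (`body_mass * g0`). A trailing stance
#' without a following foot-strike has no flight time; trial means are taken
#' over strides with all three values.
#'
#' @param events A [gait_events].
#' @param force The [force_trace] the events were detected on (or the
#'   unfiltered plate signal, if peaks are to be read off the raw force).
#' @param g0 Gravitational acceleration used for BW normalization.
#' @return An object of class `stride_variables`: list with `strides` (data
#'   frame `stride, tc_s, tf_s, fzmax_bw`), `tc_mean`, `tf_mean`,
#'   `fzmax_mean`, `n_strides`.
#' @export
compute_stride_variables <- function(events, force, g0 = 9.80665) {
  stopifnot(inherits(events, "gait_events"), inherits(force, "force_trace"))
  fs_t <- events$fs_times; to_t <- events$to_times
  if (max(to_t) < force$t[1] || min(fs_t) > force$t[length(force$t)])
    stop("events and force trace cover disjoint time ranges")
  bw <- force$body_mass * g0
  n_stance <- length(to_t)
  tc <- to_t - fs_t[seq_len(n_stance)]
  fzmax <- vapply(seq_len(n_stance), function(i) {
    sel <- force$t >= fs_t[i] & force$t <= to_t[i]
    if (!any(sel)) stop(sprintf("no force samples within stance %d", i))
    max(force$fz[sel])
  }, 0) / bw
  n_complete <- min(n_stance, length(fs_t) - 1L)
  if (n_complete < 1L) stop("no complete strides (need a following foot-strike)")
  tf <- fs_t[2L:(n_complete + 1L)] - to_t[seq_len(n_complete)]
  strides <- data.frame(stride = seq_len(n_complete),
                        tc_s = tc[seq_len(n_complete)],
                        tf_s = tf,
                        fzmax_bw = fzmax[seq_len(n_complete)])
  structure(list(strides = strides,
                 tc_mean = mean(strides$tc_s),
                 tf_mean = mean(strides$tf_s),
                 fzmax_mean = mean(strides$fzmax_bw),
                 n_strides = n_complete),
            class = "stride_variables")
}

#' @export
print.stride_variables <- function(x, ...) {
  cat(sprintf(paste0("<stride_variables> %d strides: tc %.1f ms, tf %.1f ms, ",
                     "Fz,max %.3f BW (means)\n"),
              x$n_strides, 1000 * x$tc_mean, 1000 * x$tf_mean, x$fzmax_mean))
  invisible(x)
}

#' Select the analysis strides of a trial
#'
#' Returns the first `n` complete strides (foot-strike, toe-off, next
#' foot-strike) whose foot-strike time is at or after `t_start`, e.g. the 10
#' strides following the 30 s mark of a treadmill trial. The returned events
#' hold `n + 1` foot-strikes and `n` toe-offs, so downstream stride variables
#' cover exactly `n` strides.
#'
#' @param events A [gait_events].
#' @param t_start Earliest admissible foot-strike time in seconds.
#' @param n Number of strides to keep.
#' @return A trimmed [gait_events].
#' @export
select_strides <- function(events, t_start = 30, n = 10) {
  stopifnot(inherits(events, "gait_events"))
  if (n < 1) stop("n must be >= 1")
  fs_t <- events$fs_times; to_t <- events$to_times
  i0 <- match(TRUE, fs_t >= t_start)
  n_avail <- if (is.na(i0)) 0L else min(length(to_t), length(fs_t) - 1L) - i0 + 1L
  if (is.na(i0) || n_avail < n)
    stop(sprintf("insufficient strides: %d complete strides at t >= %g, %d requested",
                 max(n_avail, 0L), t_start, n))
  gait_events(fs_times = fs_t[i0:(i0 + n)],
              to_times = to_t[i0:(i0 + n - 1L)],
              source = events$source)
}
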