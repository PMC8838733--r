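#' Pipeline configuration
#'
#' Bundles every tunable constant of the gold-standard (GSM) and IMU (IMUM)
#' pipelines with its conventional default: 20 N event threshold, 5 Hz
#' Fourier truncation of the motion signal, 0.5 Hz truncation for tilt
#' estimation, 20 Hz 4th-order Butterworth for the force plate, analysis of
#' 10 strides after the 30 s mark. Unknown arguments are rejected, so config
#' typos fail loudly.
#'
#' @param threshold_n Event detection threshold in N.
#' @param fourier_cutoff_hz Truncation frequency for the reoriented
#'   acceleration, Hz.
#' @param tilt_cutoff_hz Truncation frequency for gravity extraction, Hz.
#' @param butter_cutoff_hz,butter_order Force-plate Butterworth settings.
#' @param butter_zero_phase Forward-backward plate filtering (default `TRUE`).
#' @param butter_cutoff_correction Winter's dual-pass cutoff correction
#'   (default `TRUE`).
#' @param g0 Gravitational acceleration, m/s^2.
#' @param t_start_s Start of the analysis window, s.
#' @param n_strides Number of analysis strides.
#' @param interp_crossings Sub-sample crossing interpolation (default `TRUE`).
#' @param min_stance_s,min_flight_s Debounce durations, s.
#' @param keep_cutoff_bin Keep a DFT bin lying exactly at the cutoff.
#' @param fzmax_from_filtered Read the GSM peak force off the filtered signal
#'   (default) rather than the raw plate signal.
#' @return A list of class `pipeline_config`.
#' @export
pipeline_config <- function(threshold_n = 20,
                            fourier_cutoff_hz = 5,
                            tilt_cutoff_hz = 0.5,
                            butter_cutoff_hz = 20,
                            butter_order = 4,
                            butter_zero_phase = TRUE,
                            butter_cutoff_correction = TRUE,
                            g0 = 9.80665,
                            t_start_s = 30,
                            n_strides = 10,
                            interp_crossings = TRUE,
                            min_stance_s = 0.025,
                            min_flight_s = 0.010,
                            keep_cutoff_bin = TRUE,
                            fzmax_from_filtered = TRUE) {
  cfg <- list(threshold_n = threshold_n,
              fourier_cutoff_hz = fourier_cutoff_hz,
              tilt_cutoff_hz = tilt_cutoff_hz,
              butter_cutoff_hz = butter_cutoff_hz,
              butter_order = butter_order,
              butter_zero_phase = butter_zero_phase,
              butter_cutoff_correction = butter_cutoff_correction,
              g0 = g0,
              t_start_s = t_start_s,
              n_strides = n_strides,
              interp_crossings = interp_crossings,
              min_stance_s = min_stance_s,
              min_flight_s = min_flight_s,
              keep_cutoff_bin = keep_cutoff_bin,
              fzmax_from_filtered = fzmax_from_filtered)
  for (key in c("threshold_n", "fourier_cutoff_hz", "tilt_cutoff_hz",
                "butter_cutoff_hz", "g0"))
    if (!is.numeric(cfg[[key]]) || cfg[[key]] <= 0)
      stop(sprintf("%s must be positive", key))
  if (cfg$n_strides < 1) stop("n_strides must be >= 1")
  if (cfg$t_start_s < 0) stop("t_start_s must be >= 0")
  structure(cfg, class = "pipeline_config")
}

#' Build a pipeline_config from a named list
#'
#' Used by the config-file loader; any key that is not a
#' [pipeline_config()] argument is an error.
#'
#' @param values Named list of overrides.
#' @return A `pipeline_config`.
#' @export
as_pipeline_config <- function(values) {
  if (inherits(values, "pipeline_config")) return(values)
  known <- names(formals(pipeline_config))
  unknown <- setdiff(names(values), known)
  if (length(unknown) > 0L)
    stop(sprintf("unknown config key(s): %s", paste(unknown, collapse = ", ")))
  do.call(pipeline_config, values)
}

#' Gold-standard pipeline: force plate to stride variables
#'
#' Filters the vertical ground reaction force with a 20 Hz 4th-order
#' Butterworth, detects foot-strike/toe-off events with a 20 N threshold,
#' keeps the analysis strides, and computes per-stride contact time, flight
#' time, and peak force in body weights.
#'
#' @param force A [force_trace] with body mass set.
#' @param cfg A [pipeline_config()].
#' @return List with `events` ([gait_events]) and `strides`
#'   (`stride_variables`).
#' @export
run_gsm <- function(force, cfg = pipeline_config()) {
  cfg <- as_pipeline_config(cfg)
  filt <- butterworth_lowpass(force, cfg$butter_cutoff_hz, cfg$butter_order,
                              cfg$butter_zero_phase,
                              cfg$butter_cutoff_correction)
  ev <- detect_events_threshold(filt, cfg$threshold_n, cfg$interp_crossings,
                                cfg$min_stance_s, cfg$min_flight_s,
                                source = "GSM")
  sel <- select_strides(ev, cfg$t_start_s, cfg$n_strides)
  peak_src <- if (cfg$fzmax_from_filtered) filt else force
  sv <- compute_stride_variables(sel, peak_src, cfg$g0)
  list(events = sel, strides = sv)
}

#' IMU pipeline: sacral acceleration to stride variables
#'
#' The single-sensor estimation pipeline: estimate the sensor tilt from the
#' 0.5 Hz-truncated gravity direction, reorient the trace so its z-axis is
#' the laboratory vertical, truncate the vertical axis to 5 Hz, convert
#' acceleration to vertical ground reaction force via Newton's second law,
#' then detect events with the same 20 N threshold and stride selection as
#' the gold standard.
#'
#' @param imu An [accel_trace] from a sacrum-mounted sensor.
#' @param body_mass Body mass in kg.
#' @param cfg A [pipeline_config()].
#' @return List with `events`, `strides`, `rotation` (the estimated
#'   `rotation3`), and `force` (the reconstructed [force_trace]).
#' @export
run_imum <- function(imu, body_mass, cfg = pipeline_config()) {
  cfg <- as_pipeline_config(cfg)
  if (body_mass <= 0) stop("body_mass must be positive")
  rot <- estimate_tilt(imu, cfg$tilt_cutoff_hz, cfg$keep_cutoff_bin)
  reo <- reorient(imu, rot)
  azf <- truncated_fourier_filter(reo$az, reo$fs, cfg$fourier_cutoff_hz,
                                  cfg$keep_cutoff_bin)
  frc <- accel_to_vgrf(azf, reo$t, body_mass, cfg$g0, fs = reo$fs)
  ev <- detect_events_threshold(frc, cfg$threshold_n, cfg$interp_crossings,
                                cfg$min_stance_s, cfg$min_flight_s,
                                source = "IMUM")
  sel <- select_strides(ev, cfg$t_start_s, cfg$n_strides)
  sv <- compute_stride_variables(sel, frc, cfg$g0)
  list(events = sel, strides = sv, rotation = rot, force = frc)
}
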