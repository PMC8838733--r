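#' Default per-speed stride-parameter distributions
#'
#' Means and standard deviations of contact time, flight time (s), and peak
#' force (BW) used when drawing a synthetic cohort, one row per treadmill
#' speed. They loosely emulate gold-standard group values reported for
#' recreational runners at 9-13 km/h (contact time shortens and peak force
#' grows with speed); they are an emulation for testing, not a claim of
#' reproducing any study population.
#'
#' @return Data frame with columns `speed_kmh`, `tc_mean`, `tc_sd`,
#'   `tf_mean`, `tf_sd`, `fzmax_mean`, `fzmax_sd`.
#' @export
default_speed_params <- function() {
  data.frame(
    speed_kmh  = c(9, 11, 13),
    tc_mean    = c(0.2783, 0.2497, 0.2276),
    tc_sd      = c(0.0222, 0.0192, 0.0165),
    tf_mean    = c(0.0928, 0.1115, 0.1228),
    tf_sd      = c(0.0224, 0.0197, 0.0175),
    fzmax_mean = c(2.37, 2.51, 2.62),
    fzmax_sd   = c(0.19, 0.19, 0.20))
}

#' Generate a synthetic running cohort
#'
#' Draws per-participant body mass and stride parameters (latent standard
#' normal scores shared across speeds, so individuals keep their rank
#' ordering across conditions as in a repeated-measures design) and
#' generates one paired trial per participant and speed. Draws are truncated
#' to running gaits (`tc >= 0.15 s`, `tf >= 0.04 s`, mass in 45-100 kg).
#' Per-trial sensor tilt is uniform on `[0, tilt_max_deg]` and the clock
#' offset uniform on `[-sync_offset_max_s, sync_offset_max_s]`. Fully
#' seeded: the same seed reproduces the cohort exactly.
#'
#' @param n_participants Number of participants.
#' @param speeds Treadmill speeds in km/h.
#' @param seed Master RNG seed.
#' @param noise_sd_g,impact_amp_g,impact_freq_hz,stride_jitter_cv,n_strides
#'   Passed to every trial's [sim_config()].
#' @param tilt_max_deg Upper bound of the per-trial sensor tilt, degrees.
#' @param sync_offset_max_s Upper bound of the per-trial |clock offset|, s.
#' @param mass_mean,mass_sd Body-mass distribution, kg.
#' @param speed_params Data frame as returned by [default_speed_params()].
#' @return List of class `gait_cohort`: `trials` (list of `imu_trial`) and
#'   `manifest` (data frame, one row per trial with the drawn parameters).
#' @export
generate_cohort <- function(n_participants, speeds = c(9, 11, 13),
                            seed = 1L,
                            noise_sd_g = 0.05, impact_amp_g = 1,
                            impact_freq_hz = 25,
                            stride_jitter_cv = 0.02,
                            n_strides = 10,
                            tilt_max_deg = 10, sync_offset_max_s = 0.05,
                            mass_mean = 70, mass_sd = 10,
                            speed_params = default_speed_params()) {
  if (n_participants < 1) stop("n_participants must be >= 1")
  if (sync_offset_max_s < 0 || sync_offset_max_s > 0.05)
    stop("sync_offset_max_s must be in [0, 0.05]")
  missing_sp <- setdiff(speeds, speed_params$speed_kmh)
  if (length(missing_sp) > 0L)
    stop(sprintf("no distribution parameters for speed(s): %s",
                 paste(missing_sp, collapse = ", ")))
  if (any(speed_params$tc_sd < 0 | speed_params$tf_sd < 0 |
          speed_params$fzmax_sd < 0) || mass_sd < 0)
    stop("distribution SDs must be non-negative")
  drawn <- local_seed(seed, {
    mass <- pmin(pmax(stats::rnorm(n_participants, mass_mean, mass_sd), 45), 100)
    z <- matrix(stats::rnorm(3 * n_participants), ncol = 3,
                dimnames = list(NULL, c("tc", "tf", "fz")))
    rows <- list()
    for (p in seq_len(n_participants)) {
      for (sp in speeds) {
        par <- speed_params[speed_params$speed_kmh == sp, ]
        rows[[length(rows) + 1L]] <- data.frame(
          participant = p, speed_kmh = sp, body_mass = mass[p],
          tc_true = max(par$tc_mean + z[p, "tc"] * par$tc_sd, 0.15),
          tf_true = max(par$tf_mean + z[p, "tf"] * par$tf_sd, 0.04),
          fzmax_true = max(par$fzmax_mean + z[p, "fz"] * par$fzmax_sd, 1.2),
          tilt_deg = stats::runif(1, 0, tilt_max_deg),
          sync_offset_s = stats::runif(1, -sync_offset_max_s, sync_offset_max_s),
          seed = sample.int(.Machine$integer.max - 1L, 1L))
      }
    }
    do.call(rbind, rows)
  })
  trials <- lapply(seq_len(nrow(drawn)), function(i) {
    r <- drawn[i, ]
    generate_trial(sim_config(
      speed_kmh = r$speed_kmh, tc_true = r$tc_true, tf_true = r$tf_true,
      fzmax_true = r$fzmax_true, body_mass = r$body_mass,
      n_strides = n_strides, stride_jitter_cv = stride_jitter_cv,
      tilt_deg = r$tilt_deg, impact_amp_g = impact_amp_g,
      impact_freq_hz = impact_freq_hz, noise_sd_g = noise_sd_g,
      sync_offset_s = r$sync_offset_s, seed = r$seed))
  })
  structure(list(trials = trials, manifest = drawn), class = "gait_cohort")
}

#' @export
print.gait_cohort <- function(x, ...) {
  cat(sprintf("<gait_cohort> %d trials (%d participants x %d speeds)\n",
              length(x$trials), length(unique(x$manifest$participant)),
              length(unique(x$manifest$speed_kmh))))
  invisible(x)
}

#' Run both pipelines over a cohort
#'
#' Applies the gold-standard pipeline to every force trace and the IMU
#' pipeline to every accelerometer trace, then assembles the per-trial mean
#' table a method-comparison analysis consumes. Contact and flight times are
#' reported in ms, peak force in BW.
#'
#' @param cohort A `gait_cohort` from [generate_cohort()].
#' @param cfg A [pipeline_config()].
#' A trial on which a pipeline fails (e.g. a marginal-flight gait whose 5 Hz
#' reconstruction never crosses the detection threshold) is reported with a
#' warning and contributes `NA` values, which [validate_agreement()] in turn
#' excludes with a warning. The comparison protocol assumes both methods
#' measured the same strides, so pairs whose mean stride durations
#' (`tc + tf`) disagree by more than `max_stride_mismatch` (a merged or
#' split stance; matched recordings differ by well under 5%) are likewise
#' excluded with a warning.
#'
#' @param max_stride_mismatch Maximum tolerated relative difference between
#'   the methods' mean stride durations before a pair is declared invalid
#'   (default 0.25).
#' @return List with `pairs` (columns `participant`, `speed_kmh`,
#'   `variable`, `gold`, `est`; ready for [validate_agreement()]) and
#'   `per_trial` (the same plus `truth`).
#' @export
run_cohort <- function(cohort, cfg = pipeline_config(),
                       max_stride_mismatch = 0.25) {
  stopifnot(inherits(cohort, "gait_cohort"))
  cfg <- as_pipeline_config(cfg)
  means_or_na <- function(expr, meta, label) {
    tryCatch(expr, error = function(e) {
      warning(sprintf("%s failed for participant %d at %g km/h (%s); excluded",
                      label, meta$participant, meta$speed_kmh,
                      conditionMessage(e)), call. = FALSE)
      list(strides = list(fzmax_mean = NA_real_, tc_mean = NA_real_,
                          tf_mean = NA_real_))
    })
  }
  rows <- lapply(seq_along(cohort$trials), function(i) {
    trial <- cohort$trials[[i]]
    meta <- cohort$manifest[i, ]
    gsm <- means_or_na(run_gsm(trial$force, cfg), meta, "GSM")
    imum <- means_or_na(run_imum(trial$imu, trial$force$body_mass, cfg),
                        meta, "IMUM")
    dur_g <- gsm$strides$tc_mean + gsm$strides$tf_mean
    dur_i <- imum$strides$tc_mean + imum$strides$tf_mean
    if (is.finite(dur_g) && is.finite(dur_i) &&
        abs(dur_i - dur_g) / dur_g > max_stride_mismatch) {
      warning(sprintf(paste0("participant %d at %g km/h: methods did not ",
                             "measure the same strides (mean stride duration ",
                             "%.0f vs %.0f ms); excluded"),
                      meta$participant, meta$speed_kmh, 1000 * dur_g,
                      1000 * dur_i), call. = FALSE)
      imum$strides <- list(fzmax_mean = NA_real_, tc_mean = NA_real_,
                           tf_mean = NA_real_)
    }
    tru <- truth_stride_means(trial$truth, cfg$t_start_s, cfg$n_strides)
    data.frame(participant = meta$participant, speed_kmh = meta$speed_kmh,
               variable = c("fz_max", "tc", "tf"),
               units = c("BW", "ms", "ms"),
               truth = c(tru$fzmax_mean, 1000 * tru$tc_mean, 1000 * tru$tf_mean),
               gold = c(gsm$strides$fzmax_mean, 1000 * gsm$strides$tc_mean,
                        1000 * gsm$strides$tf_mean),
               est = c(imum$strides$fzmax_mean, 1000 * imum$strides$tc_mean,
                       1000 * imum$strides$tf_mean))
  })
  per_trial <- do.call(rbind, rows)
  rownames(per_trial) <- NULL
  list(pairs = per_trial[, c("participant", "speed_kmh", "variable",
                             "gold", "est")],
       per_trial = per_trial)
}
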