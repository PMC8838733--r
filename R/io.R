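# CSV layer. Numbers are written with 17 significant digits so every
# round-trip restores the exact double; time is plain seconds from trial
# start (trials are short, precision is not a concern).

fmt_num <- function(x) {
  out <- sprintf("%.17g", x)
  out[x == floor(x) & abs(x) < 1e15] <- sprintf("%.0f", x[x == floor(x) & abs(x) < 1e15])
  out
}

write_num_csv <- function(df, path) {
  cols <- lapply(df, function(col) if (is.numeric(col)) fmt_num(col) else as.character(col))
  lines <- c(paste(names(df), collapse = ","),
             do.call(paste, c(cols, sep = ",")))
  writeLines(lines, path)
  invisible(path)
}

read_num_csv <- function(path, expected_header) {
  if (!file.exists(path)) stop(sprintf("file not found: %s", path))
  header <- strsplit(readLines(path, n = 1L), ",", fixed = TRUE)[[1]]
  if (!identical(trimws(header), expected_header))
    stop(sprintf("malformed header in %s: expected '%s', found '%s'",
                 path, paste(expected_header, collapse = ","),
                 paste(header, collapse = ",")))
  df <- utils::read.csv(path, colClasses = "character")
  if (nrow(df) == 0L) stop(sprintf("empty file: %s", path))
  for (col in expected_header) {
    v <- suppressWarnings(as.numeric(df[[col]]))
    bad <- which(is.na(v))
    if (length(bad) > 0L)   # +1: file rows count the header
      stop(sprintf("non-numeric value in column '%s' of %s at row %d",
                   col, path, bad[1] + 1L))
    df[[col]] <- v
  }
  df
}

check_time_column <- function(t, path) {
  d <- diff(t)
  bad <- which(d <= 0)
  if (length(bad) > 0L)   # offending sample is d-index + 1; +1 more for header
    stop(sprintf("non-increasing time in %s at row %d%s", path, bad[1] + 2L,
                 if (d[bad[1]] == 0) " (duplicated timestamp)" else ""))
  invisible(TRUE)
}

#' Read a 3-axis accelerometer CSV
#'
#' Expects header `t,ax,ay,az` (seconds, g, g, g), UTF-8, `.` decimal
#' separator, one row per sample. The nominal sample rate is inferred as
#' `1/median(diff(t))`. Samples at the saturation bound are reported with a
#' message; samples beyond it are an error.
#'
#' @param path CSV file path.
#' @param saturation_g Declared sensor clip bound in g.
#' @return An [accel_trace].
#' @export
read_accel_csv <- function(path, saturation_g = 8) {
  df <- read_num_csv(path, c("t", "ax", "ay", "az"))
  check_time_column(df$t, path)
  amax <- pmax(abs(df$ax), abs(df$ay), abs(df$az))
  if (any(amax > saturation_g + 1e-9)) {
    bad <- which(amax > saturation_g + 1e-9)[1]
    stop(sprintf("row %d of %s exceeds saturation range +/-%g g",
                 bad + 1L, path, saturation_g))
  }
  n_sat <- sum(amax >= saturation_g - 1e-9)
  if (n_sat > 0L)
    message(sprintf("%s: %d sample(s) at the +/-%g g saturation bound",
                    path, n_sat, saturation_g))
  accel_trace(df$t, df$ax, df$ay, df$az, saturation_g = saturation_g)
}

#' Read a vertical-force CSV
#'
#' Expects header `t,fz` (seconds, N).
#'
#' @param path CSV file path.
#' @param body_mass Body mass in kg, attached to the trace.
#' @return A [force_trace].
#' @export
read_force_csv <- function(path, body_mass) {
  df <- read_num_csv(path, c("t", "fz"))
  check_time_column(df$t, path)
  force_trace(df$t, df$fz, body_mass = body_mass)
}

#' @rdname read_accel_csv
#' @param trace Trace to write.
#' @export
write_accel_csv <- function(trace, path) {
  stopifnot(inherits(trace, "accel_trace"))
  write_num_csv(data.frame(t = trace$t, ax = trace$ax, ay = trace$ay,
                           az = trace$az), path)
}

#' @rdname read_force_csv
#' @param trace Trace to write.
#' @export
write_force_csv <- function(trace, path) {
  stopifnot(inherits(trace, "force_trace"))
  write_num_csv(data.frame(t = trace$t, fz = trace$fz), path)
}

#' Write detected events to CSV
#'
#' Header `event,time_s` with `event` in `{FS, TO}`, sorted by time.
#'
#' @param events A [gait_events].
#' @param path Output path.
#' @export
write_events_csv <- function(events, path) {
  stopifnot(inherits(events, "gait_events"))
  df <- data.frame(event = c(rep("FS", length(events$fs_times)),
                             rep("TO", length(events$to_times))),
                   time_s = c(events$fs_times, events$to_times))
  df <- df[order(df$time_s), ]
  write_num_csv(df, path)
}

#' Write per-stride variables to CSV
#'
#' Header `stride,tc_s,tf_s,fzmax_bw`.
#'
#' @param sv A `stride_variables` object.
#' @param path Output path.
#' @export
write_strides_csv <- function(sv, path) {
  stopifnot(inherits(sv, "stride_variables"))
  write_num_csv(sv$strides, path)
}

#' Write a simulated trial to disk
#'
#' Emits `<prefix>_imu.csv`, `<prefix>_force.csv`, and `<prefix>_truth.csv`
#' (per-stride ground truth: `stride,fs_time_s,to_time_s,tc_s,tf_s,fzmax_bw`).
#'
#' @param trial An `imu_trial` from [generate_trial()].
#' @param dir Output directory (created if missing).
#' @param prefix File-name prefix.
#' @return Invisibly, the three file paths.
#' @export
write_trial <- function(trial, dir, prefix = "trial") {
  stopifnot(inherits(trial, "imu_trial"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  paths <- file.path(dir, paste0(prefix, c("_imu.csv", "_force.csv",
                                           "_truth.csv")))
  write_accel_csv(trial$imu, paths[1])
  write_force_csv(trial$force, paths[2])
  tr <- trial$truth
  write_num_csv(data.frame(stride = seq_along(tr$fs_times_true),
                           fs_time_s = tr$fs_times_true,
                           to_time_s = tr$to_times_true,
                           tc_s = tr$tc_true_i, tf_s = tr$tf_true_i,
                           fzmax_bw = tr$fzmax_true_i), paths[3])
  invisible(paths)
}

#' Write a cohort to disk
#'
#' One trial triplet per (participant, speed) named
#' `p<participant>_s<speed>_{imu,force,truth}.csv`, plus `manifest.csv`.
#'
#' @param cohort A `gait_cohort`.
#' @param dir Output directory.
#' @return Invisibly, the manifest path.
#' @export
write_cohort <- function(cohort, dir) {
  stopifnot(inherits(cohort, "gait_cohort"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  for (i in seq_along(cohort$trials)) {
    meta <- cohort$manifest[i, ]
    write_trial(cohort$trials[[i]], dir,
                sprintf("p%03d_s%g", meta$participant, meta$speed_kmh))
  }
  path <- file.path(dir, "manifest.csv")
  write_num_csv(cohort$manifest, path)
  invisible(path)
}

#' Read a paired per-trial table
#'
#' Header `participant,speed_kmh,variable,gold,est`, the input of
#' [validate_agreement()].
#'
#' @param path CSV path.
#' @return Data frame.
#' @export
read_pairs_csv <- function(path) {
  if (!file.exists(path)) stop(sprintf("file not found: %s", path))
  df <- utils::read.csv(path, colClasses = "character")
  need <- c("participant", "speed_kmh", "variable", "gold", "est")
  if (!all(need %in% names(df)))
    stop(sprintf("pairs file must have columns %s", paste(need, collapse = ",")))
  for (col in c("speed_kmh", "gold", "est")) {
    v <- suppressWarnings(as.numeric(df[[col]]))
    bad <- which(is.na(v) & !is.na(df[[col]]))
    if (length(bad) > 0L)
      stop(sprintf("non-numeric value in column '%s' at row %d", col, bad[1]))
    df[[col]] <- v
  }
  df
}

#' Write or read an agreement report
#'
#' JSON reports are nested `variable -> speed -> fields` (with `loa` and
#' `ci_bias` as `[lower, upper]` pairs); CSV reports are the flat
#' [validate_agreement()] table. Both preserve full double precision, so a
#' write/read round trip reproduces every numeric field exactly.
#'
#' @param report An `agreement_table` from [validate_agreement()].
#' @param path Output path.
#' @param format `"json"` or `"csv"`; default follows the file extension.
#' @return Invisibly, `path`.
#' @export
write_report <- function(report, path, format = c("auto", "json", "csv")) {
  format <- match.arg(format)
  if (format == "auto")
    format <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "csv" else "json"
  if (format == "csv") {
    write_num_csv(as.data.frame(report), path)
  } else {
    nested <- list()
    for (i in seq_len(nrow(report))) {
      r <- report[i, ]
      nested[[r$variable]][[as.character(r$speed_kmh)]] <- list(
        bias = r$bias, loa = c(r$loa_lower, r$loa_upper),
        ci_bias = c(r$ci_bias_lower, r$ci_bias_upper),
        ci_loa_lower = c(r$ci_loa_lower_lower, r$ci_loa_lower_upper),
        ci_loa_upper = c(r$ci_loa_upper_lower, r$ci_loa_upper_upper),
        srd = r$srd, sd_diff = r$sd_diff,
        rmse_abs = r$rmse_abs, rmse_rel_pct = r$rmse_rel_pct,
        prop_slope = r$prop_slope, prop_se = r$prop_se, prop_p = r$prop_p,
        cohens_d = r$cohens_d, effect_band = r$effect_band,
        gold_mean = r$gold_mean, gold_sd = r$gold_sd,
        est_mean = r$est_mean, est_sd = r$est_sd, n = r$n)
    }
    jsonlite::write_json(nested, path, auto_unbox = TRUE, digits = I(17),
                         pretty = TRUE)
  }
  invisible(path)
}

#' @rdname write_report
#' @export
read_report <- function(path, format = c("auto", "json", "csv")) {
  format <- match.arg(format)
  if (format == "auto")
    format <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "csv" else "json"
  if (format == "csv") {
    df <- utils::read.csv(path, colClasses = "character")
    for (col in setdiff(names(df), c("variable", "effect_band")))
      df[[col]] <- as.numeric(df[[col]])
    class(df) <- c("agreement_table", "data.frame")
    df
  } else {
    jsonlite::read_json(path, simplifyVector = TRUE)
  }
}
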