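#' Simulation configuration for a treadmill running trial
#'
#' Parameters of the spring-mass running simulator that emits a paired
#' force-plate and sacral-IMU recording with known ground truth. Defaults
#' emulate a treadmill run at 11 km/h recorded with a 208 Hz, +/-8 g
#' accelerometer and a 200 Hz instrumented treadmill, with an inter-device
#' synchronization offset of at most 50 ms.
#'
#' @param speed_kmh Nominal belt speed label, km/h.
#' @param tc_true,tf_true Mean contact and flight time, s.
#' @param fzmax_true Mean peak vertical force, body weights.
#' @param body_mass Runner mass, kg.
#' @param n_strides Number of analysis strides the trial must cover beyond
#'   the 30 s selection mark (the trial is generated ~5 strides longer).
#' @param stride_jitter_cv Coefficient of variation of the multiplicative
#'   lognormal cycle-to-cycle jitter on `tc` and `tf` (default 0.02, a
#'   typical treadmill stride-time variability).
#' @param tilt_deg Sensor tilt about the medio-lateral axis, degrees.
#' @param impact_amp_g,impact_freq_hz Damped foot-strike transient added to
#'   the accelerometer's vertical channel: amplitude in g and oscillation
#'   frequency in Hz (20 ms decay constant).
#' @param noise_sd_g White accelerometer noise SD per axis, g.
#' @param sync_offset_s Constant clock offset between devices, s
#'   (|offset| <= 0.05): the IMU sample stamped `t` holds the physical
#'   signal at `t + sync_offset_s`.
#' @param fs_imu,fs_force Sample rates, Hz.
#' @param saturation_g Accelerometer clip bound, g.
#' @param balance If `TRUE`, override `fzmax_true` per cycle with
#'   `pi * (tc + tf) / (2 * tc)` so the half-sine stance impulse exactly
#'   balances body weight over the cycle (the half-sine model does not
#'   balance for arbitrary `fzmax`).
#' @param seed Integer RNG seed; every stochastic element is derived from it.
#' @return List of class `sim_config`.
#' @export
sim_config <- function(speed_kmh = 11,
                       tc_true = 0.28, tf_true = 0.12, fzmax_true = 2.5,
                       body_mass = 70, n_strides = 10,
                       stride_jitter_cv = 0.02,
                       tilt_deg = 0,
                       impact_amp_g = 0, impact_freq_hz = 25,
                       noise_sd_g = 0,
                       sync_offset_s = 0,
                       fs_imu = 208, fs_force = 200,
                       saturation_g = 8,
                       balance = FALSE,
                       seed = 1L) {
  cfg <- as.list(environment())
  if (cfg$tc_true <= 0 || cfg$tf_true <= 0)
    stop("tc_true and tf_true must be positive")
  if (duty_factor(cfg$tc_true, cfg$tf_true) >= 0.5)
    stop("duty factor must be below 0.5 (running requires a flight phase)")
  if (abs(cfg$sync_offset_s) > 0.05)
    stop("|sync_offset_s| must be <= 0.05 s")
  if (cfg$body_mass <= 0) stop("body_mass must be positive")
  if (cfg$fzmax_true <= 0) stop("fzmax_true must be positive")
  if (cfg$fs_imu <= 0 || cfg$fs_force <= 0) stop("sample rates must be positive")
  if (cfg$stride_jitter_cv < 0 || cfg$noise_sd_g < 0 || cfg$impact_amp_g < 0)
    stop("jitter, noise, and impact amplitudes must be non-negative")
  if (cfg$saturation_g <= 0) stop("saturation_g must be positive")
  structure(cfg, class = "sim_config")
}

#' Half-sine stance force of the spring-mass running model
#'
#' Vertical ground reaction force of a single stance phase:
#' `F(t) = fzmax * body_mass * g0 * sin(pi * t / tc)` for `0 <= t <= tc`,
#' zero outside stance. A single smooth active peak, as a sacral (centre of
#' mass) load profile shows once impact transients are excluded.
#'
#' @param t_in_stance Time since foot-strike, s (vectorized).
#' @param tc Contact time, s.
#' @param fzmax Peak force in body weights.
#' @param body_mass Mass, kg.
#' @param g0 Gravitational acceleration, m/s^2.
#' @return Force in N.
#' @export
stance_force_model <- function(t_in_stance, tc, fzmax, body_mass,
                               g0 = 9.80665) {
  ifelse(t_in_stance >= 0 & t_in_stance <= tc,
         fzmax * body_mass * g0 * sin(pi * t_in_stance / tc), 0)
}

# run code under a seed without disturbing the caller's RNG stream
local_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  code
}

# mean-preserving multiplicative lognormal jitter
jitter_lognormal <- function(n, mean, cv) {
  if (cv == 0) return(rep(mean, n))
  sdlog <- sqrt(log(1 + cv^2))
  mean * stats::rlnorm(n, meanlog = -sdlog^2 / 2, sdlog = sdlog)
}

#' Generate one paired force-plate / IMU running trial
#'
#' Builds a continuous-time gait-cycle sequence with per-cycle jittered
#' contact and flight times, samples the half-sine stance force on the
#' force-plate clock, and constructs the sacral accelerometer's proper
#' acceleration: `F/(m*g0)` g during stance, 0 g in flight (free fall), plus
#' a damped impact transient at each foot-strike, rotated by the sensor tilt
#' (gravity redistributes onto the y/z axes), with white noise added in the
#' sensor frame, clipped at the saturation bound, and sampled on the IMU
#' clock shifted by the synchronization offset. The trial is long enough
#' that the "10 strides after 30 s" selection rule can be exercised.
#'
#' @param cfg A [sim_config()].
#' @return List of class `imu_trial`: `force` ([force_trace]), `imu`
#'   ([accel_trace]), `truth` (list with `fs_times_true`, `to_times_true`,
#'   per-stride `tc_true_i`, `tf_true_i`, `fzmax_true_i` in BW), and `cfg`.
#' @export
generate_trial <- function(cfg = sim_config()) {
  if (!inherits(cfg, "sim_config")) cfg <- do.call(sim_config, cfg)
  cycle <- cfg$tc_true + cfg$tf_true
  duration <- 35 + (cfg$n_strides + 5) * cycle
  n_cycles <- ceiling(duration / cycle) + 10L
  local_seed(cfg$seed, {
    tc_i <- jitter_lognormal(n_cycles, cfg$tc_true, cfg$stride_jitter_cv)
    tf_i <- jitter_lognormal(n_cycles, cfg$tf_true, cfg$stride_jitter_cv)
    fz_i <- if (cfg$balance) pi * (tc_i + tf_i) / (2 * tc_i)
            else rep(cfg$fzmax_true, n_cycles)
    fs_times <- 0.5 + c(0, cumsum(tc_i + tf_i))[seq_len(n_cycles)]
    to_times <- fs_times + tc_i
    m <- cfg$body_mass
    g0 <- 9.80665
    model_force <- function(tau) {
      k <- findInterval(tau, fs_times)
      f <- numeric(length(tau))
      in_cycle <- k >= 1L
      kk <- k[in_cycle]
      dt <- tau[in_cycle] - fs_times[kk]
      f[in_cycle] <- stance_force_model(dt, tc = tc_i[kk], fzmax = fz_i[kk],
                                        body_mass = m, g0 = g0)
      pmax(f, 0)
    }
    impact <- function(tau) {
      k <- findInterval(tau, fs_times)
      a <- numeric(length(tau))
      in_cycle <- k >= 1L
      dt <- tau[in_cycle] - fs_times[k[in_cycle]]
      a[in_cycle] <- cfg$impact_amp_g * exp(-dt / 0.02) *
        sin(2 * pi * cfg$impact_freq_hz * dt)
      a
    }
    t_force <- seq(0, duration, by = 1 / cfg$fs_force)
    force <- force_trace(t = t_force, fz = model_force(t_force),
                         body_mass = m, fs = cfg$fs_force)
    t_imu <- seq(0, duration, by = 1 / cfg$fs_imu)
    tau <- t_imu + cfg$sync_offset_s
    az_lab <- model_force(tau) / (m * g0) + impact(tau)
    ay_lab <- 0.05 * sin(2 * pi * tau / cycle)   # small AP sway, free choice
    ax_lab <- numeric(length(tau))
    th <- cfg$tilt_deg * pi / 180
    ax_s <- ax_lab
    ay_s <- cos(th) * ay_lab + sin(th) * az_lab
    az_s <- -sin(th) * ay_lab + cos(th) * az_lab
    nsamp <- length(tau)
    noise <- matrix(stats::rnorm(3 * nsamp), ncol = 3) * cfg$noise_sd_g
    clip <- function(x) pmin(pmax(x, -cfg$saturation_g), cfg$saturation_g)
    imu <- accel_trace(t = t_imu,
                       ax = clip(ax_s + noise[, 1]),
                       ay = clip(ay_s + noise[, 2]),
                       az = clip(az_s + noise[, 3]),
                       fs = cfg$fs_imu, saturation_g = cfg$saturation_g)
    in_trial <- fs_times <= duration
    truth <- list(fs_times_true = fs_times[in_trial],
                  to_times_true = to_times[in_trial],
                  tc_true_i = tc_i[in_trial],
                  tf_true_i = tf_i[in_trial],
                  fzmax_true_i = fz_i[in_trial])
    structure(list(force = force, imu = imu, truth = truth, cfg = cfg),
              class = "imu_trial")
  })
}

#' @export
print.imu_trial <- function(x, ...) {
  cat(sprintf("<imu_trial> %.0f s at %g km/h: %d cycles, mass %g kg, tilt %g deg\n",
              max(x$force$t), x$cfg$speed_kmh, length(x$truth$fs_times_true),
              x$cfg$body_mass, x$cfg$tilt_deg))
  invisible(x)
}

#' Ground-truth means over the analysis strides
#'
#' Applies the same stride-selection rule as the pipelines (first `n`
#' complete strides with foot-strike at or after `t_start`) to the
#' simulator's ground truth.
#'
#' @param truth The `truth` element of an `imu_trial`.
#' @param t_start,n Stride-selection parameters.
#' @return List with `tc_mean`, `tf_mean`, `fzmax_mean` (s, s, BW) and the
#'   per-stride vectors `tc`, `tf`, `fzmax`.
#' @export
truth_stride_means <- function(truth, t_start = 30, n = 10) {
  i0 <- match(TRUE, truth$fs_times_true >= t_start)
  if (is.na(i0) || length(truth$fs_times_true) < i0 + n - 1L)
    stop("ground truth does not cover the requested strides")
  idx <- i0:(i0 + n - 1L)
  list(tc_mean = mean(truth$tc_true_i[idx]),
       tf_mean = mean(truth$tf_true_i[idx]),
       fzmax_mean = mean(truth$fzmax_true_i[idx]),
       tc = truth$tc_true_i[idx],
       tf = truth$tf_true_i[idx],
       fzmax = truth$fzmax_true_i[idx])
}
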