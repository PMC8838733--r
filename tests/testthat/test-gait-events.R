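test_that("Butterworth low-pass has the expected magnitude behaviour", {
  t <- seq(0, 10, by = 1 / 200)
  mid <- t > 3 & t < 7

  const <- force_trace(t, 700, body_mass = 70)
  expect_lt(max(abs(butterworth_lowpass(const)$fz[mid] - 700)), 1e-6)

  # uncorrected order-compensated dual pass: 50 Hz attenuated by more than
  # the analytic single-pass 4th-order magnitude, 1 Hz preserved within 1%
  s50 <- force_trace(t, 500 + 100 * sin(2 * pi * 50 * t), body_mass = 70)
  f50 <- butterworth_lowpass(s50, cutoff_correction = FALSE)
  amp50 <- max(f50$fz[mid]) - 500
  expect_lt(amp50, 100 * butterworth_magnitude(50, 20, 4))

  s1 <- force_trace(t, 500 + 100 * sin(2 * pi * 1 * t), body_mass = 70)
  f1 <- butterworth_lowpass(s1, cutoff_correction = FALSE)
  expect_equal(max(f1$fz[mid]) - 500, 100, tolerance = 0.01)

  # with the dual-pass cutoff correction the -3 dB point sits at the
  # requested cutoff
  s20 <- force_trace(t, 500 + 100 * sin(2 * pi * 20 * t), body_mass = 70)
  f20 <- butterworth_lowpass(s20)
  expect_equal(max(f20$fz[mid]) - 500, 100 / sqrt(2), tolerance = 0.03)

  expect_error(butterworth_lowpass(const, cutoff = 100), "Nyquist")
  expect_error(butterworth_lowpass(const, order = 3), "even order")
})

test_that("threshold detection matches the analytic half-sine crossings", {
  ft <- half_sine_force()
  an <- half_sine_crossings()

  ev <- detect_events_threshold(ft, 20)
  expect_length(ev$fs_times, 1)
  expect_lt(abs(ev$fs_times - an["fs"]), 0.3e-3)
  expect_lt(abs(ev$to_times - an["to"]), 0.3e-3)

  ev_raw <- detect_events_threshold(ft, 20, interpolate = FALSE)
  expect_lt(abs(ev_raw$fs_times - an["fs"]), 2.5e-3)
  expect_lt(abs(ev_raw$to_times - an["to"]), 2.5e-3)
})

test_that("threshold detection handles degenerate traces per contract", {
  t <- seq(0, 2, by = 1 / 200)
  expect_error(detect_events_threshold(force_trace(t, 0, body_mass = 70), 20),
               "no strides detected")

  # trace begins mid-stance: leading incomplete stance discarded, first
  # reported event is the next foot-strike
  tc <- 0.28
  fz <- ifelse(t < 0.1, 800,
               ifelse(t >= 0.5 & t <= 0.5 + tc,
                      1500 * sin(pi * (t - 0.5) / tc), 0))
  ev <- detect_events_threshold(force_trace(t, fz, body_mass = 70), 20)
  expect_length(ev$fs_times, 1)
  expect_gt(ev$fs_times, 0.5)
})

test_that("stride variables follow their defining arithmetic", {
  ev <- gait_events(fs_times = c(1.0, 1.4), to_times = 1.28, source = "GSM")
  ft <- half_sine_force(t0 = 1, tc = 0.28, fmax = 1500, fs = 200, t_end = 1.6)
  sv <- compute_stride_variables(ev, ft, g0 = 9.81)
  expect_equal(sv$strides$tc_s, 0.28)
  expect_equal(sv$strides$tf_s, 0.12)
  expect_equal(sv$strides$fzmax_bw, 1500 / (61 * 9.81), tolerance = 1e-12)
  expect_equal(sv$n_strides, 1)

  # time-translation invariance
  dlt <- 3.7
  ev2 <- gait_events(c(1.0, 1.4) + dlt, 1.28 + dlt, source = "GSM")
  ft2 <- force_trace(ft$t + dlt, ft$fz, body_mass = 61)
  sv2 <- compute_stride_variables(ev2, ft2, g0 = 9.81)
  expect_equal(sv2$strides$tc_s, sv$strides$tc_s)
  expect_equal(sv2$strides$tf_s, sv$strides$tf_s)

  # force linearity: doubling force doubles the peak, times unchanged
  ft3 <- force_trace(ft$t, 2 * ft$fz, body_mass = 61)
  sv3 <- compute_stride_variables(ev, ft3, g0 = 9.81)
  expect_equal(sv3$strides$fzmax_bw, 2 * sv$strides$fzmax_bw)
  expect_equal(sv3$strides$tc_s, sv$strides$tc_s)

  # disjoint time ranges are an error
  ft4 <- force_trace(seq(10, 11, by = 0.005), 100, body_mass = 61)
  expect_error(compute_stride_variables(ev, ft4), "disjoint")
})

test_that("stride selection picks the first n complete strides after t_start", {
  fs_t <- (0:19) * 0.75
  to_t <- fs_t + 0.3
  ev <- gait_events(fs_t, to_t, source = "GSM")

  sel <- select_strides(ev, t_start = 5, n = 10)
  expect_equal(sel$fs_times[1], 5.25)        # stride index 8 onward
  expect_length(sel$fs_times, 11)
  expect_length(sel$to_times, 10)
  expect_equal(sel$fs_times, fs_t[8:18])

  all19 <- select_strides(ev, t_start = 0, n = 19)
  expect_equal(all19$fs_times, fs_t)

  expect_error(select_strides(ev, t_start = 100, n = 1), "insufficient")
  expect_error(select_strides(ev, t_start = 5, n = 13),
               "12 complete strides")
})

test_that("gold-standard pipeline recovers the simulated stance parameters", {
  trial <- generate_trial(sim_config(stride_jitter_cv = 0, seed = 3))
  res <- run_gsm(trial$force)
  tru <- truth_stride_means(trial$truth)
  expect_equal(res$strides$fzmax_mean, tru$fzmax_mean, tolerance = 0.01)
  # the 20 Hz zero-phase filter smears the stance corner ~3 ms per side, so
  # tc is recovered within two plate samples, not exactly
  expect_lt(abs(res$strides$tc_mean - tru$tc_mean), 0.010)
  expect_lt(abs(res$strides$tf_mean - tru$tf_mean), 0.010)
  expect_equal(res$strides$n_strides, 10)

  # determinism
  res2 <- run_gsm(trial$force)
  expect_identical(res$strides, res2$strides)

  # a trial with a single stance cannot supply 10 strides
  short <- half_sine_force(t0 = 31, t_end = 33)
  expect_error(run_gsm(short), "insufficient|no strides")
})

test_that("IMU pipeline matches the periodic truncation oracle and cancels tilt", {
  trial <- generate_trial(sim_config(stride_jitter_cv = 0, seed = 3))
  res <- run_imum(trial$imu, 70)
  orc <- truncation_deformation_oracle(0.28, 0.12, 2.5,
                                       threshold_bw = 20 / (70 * 9.80665))
  # the 5 Hz truncation deforms the half-sine stance; the pipeline must
  # reproduce the analytically deformed tc/tf/peak, not the raw truth
  expect_lt(abs(res$strides$tc_mean - orc$tc), 1.5e-3)
  expect_lt(abs(res$strides$tf_mean - orc$tf), 1.5e-3)
  expect_lt(abs(res$strides$fzmax_mean - orc$fzmax), 0.01)

  tilted <- generate_trial(sim_config(stride_jitter_cv = 0, tilt_deg = 10,
                                      seed = 3))
  res10 <- run_imum(tilted$imu, 70)
  expect_equal(res10$rotation$tilt_angle * 180 / pi, 10, tolerance = 0.1)
  expect_lt(abs(res10$strides$tc_mean - res$strides$tc_mean), 1e-6)
  expect_lt(abs(res10$strides$tf_mean - res$strides$tf_mean), 1e-6)
  expect_lt(abs(res10$strides$fzmax_mean - res$strides$fzmax_mean), 1e-6)

  expect_error(run_imum(trial$imu, 70,
                        pipeline_config(t_start_s = 1e4)), "insufficient")
})

test_that("event stream obeys alternation, time partition, and monotone threshold", {
  trial <- generate_trial(sim_config(seed = 5, noise_sd_g = 0.05,
                                     impact_amp_g = 1))
  res <- run_gsm(trial$force)
  ev <- res$events
  nf <- length(ev$fs_times)
  expect_true(all(ev$to_times > ev$fs_times[seq_along(ev$to_times)]))
  expect_true(all(ev$fs_times[-1] > ev$to_times[seq_len(nf - 1)]))

  # partition of time: sum of tc+tf telescopes to the foot-strike span
  sv <- res$strides$strides
  expect_lt(abs(sum(sv$tc_s + sv$tf_s) - (ev$fs_times[nf] - ev$fs_times[1])),
            1e-9)

  # raising the threshold never lengthens a stance on a smooth profile
  filt <- butterworth_lowpass(trial$force)
  tc_at <- vapply(c(20, 50, 100, 200), function(thr) {
    e <- select_strides(detect_events_threshold(filt, thr), 30, 10)
    mean(e$to_times - e$fs_times[seq_along(e$to_times)])
  }, 0)
  expect_true(all(diff(tc_at) <= 1e-12))
})

test_that("contact/flight biases are antisymmetric over a long trial", {
  trial <- generate_trial(sim_config(n_strides = 100, noise_sd_g = 0.05,
                                     impact_amp_g = 1, tilt_deg = 5,
                                     sync_offset_s = 0.03, seed = 9))
  cfg <- pipeline_config(n_strides = 100)
  g <- run_gsm(trial$force, cfg)
  m <- run_imum(trial$imu, 70, cfg)
  bias_tc <- m$strides$tc_mean - g$strides$tc_mean
  bias_tf <- m$strides$tf_mean - g$strides$tf_mean
  expect_lt(abs(bias_tc + bias_tf), 2e-3)
  # running gait throughout: duty factor below one half
  expect_true(all(duty_factor(g$strides$strides$tc_s,
                              g$strides$strides$tf_s) < 0.5))
})
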