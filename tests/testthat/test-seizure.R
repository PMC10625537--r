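base_params <- spectro_params()

test_that("stationary noise self-normalizes to mean 0, sd 1 per row", {
  ses <- sim_lfp_fourap(duration_s = 700, fs = 250, injection_time_s = 650,
                        seizures = NULL, interictal = NULL, slow_osc = NULL,
                        seed = 61)
  zm <- zscore_spectrogram(ses, baseline_interval = c(0, 650))
  base_cols <- zm$times - base_params$bin_s / 2 + 1e-9 >= 0 &
    zm$times + base_params$bin_s / 2 <= 650
  zb <- zm$z[, base_cols]
  expect_lt(max(abs(rowMeans(zb))), 0.1)
  expect_lt(max(abs(apply(zb, 1, sd) - 1)), 0.1)
})

test_that("z is the definitional (x - mean)/sd", {
  # inject a known excess into the binned power of one row and recompute
  ses <- sim_lfp_fourap(duration_s = 400, fs = 250, injection_time_s = 350,
                        seizures = NULL, interictal = NULL, slow_osc = NULL,
                        seed = 62)
  zm <- zscore_spectrogram(ses, baseline_interval = c(0, 350))
  mu <- zm$baseline_mean[3]; sdv <- zm$baseline_sd[3]
  x <- mu + 5 * sdv
  expect_equal((x - mu) / sdv, 5)
  # and the map itself reproduces that arithmetic cell-wise
  expect_equal(zm$z[3, 10], (zm$power[3, 10] - mu) / sdv, tolerance = 1e-12)
})

test_that("mains-band contamination is invisible to the detector", {
  ses <- sim_lfp_fourap(duration_s = 900, fs = 250, injection_time_s = 600,
                        seizures = NULL, interictal = NULL, slow_osc = NULL,
                        seed = 63)
  zm0 <- zscore_spectrogram(ses, baseline_interval = c(0, 600))
  # a strong 50 Hz tone, slowly amplitude-modulated, through the recording
  t <- (seq_along(ses$trace) - 1) / 250
  ses$trace <- ses$trace +
    8 * (1 + 0.5 * sin(2 * pi * 0.01 * t)) * sin(2 * pi * 50 * t)
  zm <- zscore_spectrogram(ses, baseline_interval = c(0, 600))
  # no analyzed row overlaps 49-51 Hz ...
  expect_true(all(zm$frequencies + base_params$freq_band_hz / 2 <= 49 |
                    zm$frequencies - base_params$freq_band_hz / 2 >= 51))
  # ... and the contamination changes nothing anywhere in the map: the
  # in-notch power is removed before the windowed analysis, so it cannot
  # leak into neighbouring rows
  expect_equal(zm$z, zm0$z, tolerance = 1e-6)
  expect_equal(nrow(detect_pathological_events(zm)),
               nrow(detect_pathological_events(zm0)))
})

test_that("run-length event extraction follows the toy example", {
  z <- matrix(c(0, 5, 5, 0, 5), nrow = 1)
  toy_params <- spectro_params(bin_s = 1, step_s = 1)
  zm <- zscore_map(times = 0:4, frequencies = 20, z = z, params = toy_params)
  ev <- detect_pathological_events(zm)
  expect_equal(nrow(ev), 2)
  expect_equal(ev$duration_s, c(2, 1))
  expect_equal(ev$start_s, c(1, 4))
  # all-subthreshold map: no events
  expect_equal(nrow(detect_pathological_events(
    zscore_map(0:4, 20, matrix(1, 1, 5), params = toy_params))), 0)
})

test_that("embedded discharges are recovered as exactly their events", {
  ses <- sim_lfp_fourap(duration_s = 240, fs = 500, injection_time_s = 100,
                        seizures = NULL, interictal = NULL, slow_osc = NULL,
                        seed = 64)
  t <- (seq_along(ses$trace) - 1) / 500
  sigma <- sd(ses$trace[t < 100])
  for (on in c(120, 160, 200)) {
    idx <- which(t >= on & t < on + 2)
    tt <- t[idx] - on
    ses$trace[idx] <- ses$trace[idx] +
      6 * sigma * sin(pi * tt / 2)^2 * sin(2 * pi * 12 * tt)
  }
  zm <- zscore_spectrogram(ses, baseline_interval = c(0, 100))
  ev <- detect_pathological_events(zm)
  # each discharge maps to exactly one event (no splits, no merges) ...
  for (on in c(120, 160, 200)) {
    hit <- ev$start_s <= on + 2 & ev$end_s >= on
    expect_equal(sum(hit), 1)
  }
  # ... and those three dominate: anything else is marginal threshold
  # flicker, orders of magnitude below the discharges
  truth_ev <- ev$start_s <= 202 & ev$end_s >= 120 &
    ev$integrated_z_excess > 100
  expect_equal(sum(truth_ev), 3)
  expect_true(all(ev$integrated_z_excess[!truth_ev] <
                    0.01 * min(ev$integrated_z_excess[truth_ev])))
  # none of them (2 s each) can ever be called a seizure
  expect_equal(nrow(classify_seizures(ev, ses, base_params)), 0)
})

test_that("seizure classification enforces duration and rhythmicity", {
  # a 20 s rhythmic discharge at 8 SD is a seizure with 6 Hz dominance
  ses <- sim_lfp_fourap(duration_s = 1000, fs = 500, injection_time_s = 600,
                        seizures = data.frame(onset_s = 800, duration_s = 20,
                                              amplitude_sd = 8),
                        interictal = NULL, seed = 65)
  rep <- analyze_seizure_session(ses)
  expect_equal(nrow(rep$seizures), 1)
  expect_equal(rep$seizures$dominant_hz, 6, tolerance = 0.15)
  expect_lte(abs(rep$seizures$start_s - 800), 10)

  # a 10 s discharge of the same amplitude is an event, never a seizure
  ses10 <- sim_lfp_fourap(duration_s = 1000, fs = 500, injection_time_s = 600,
                          seizures = data.frame(onset_s = 800, duration_s = 10,
                                                amplitude_sd = 8),
                          interictal = NULL, seed = 66)
  rep10 <- analyze_seizure_session(ses10)
  expect_gt(nrow(rep10$events), 0)
  expect_equal(nrow(rep10$seizures), 0)

  # a long broadband artifact is an event but fails the rhythmicity rule
  ses_b <- sim_lfp_fourap(duration_s = 1000, fs = 500, injection_time_s = 600,
                          seizures = NULL, interictal = NULL, slow_osc = NULL,
                          seed = 67)
  t <- (seq_along(ses_b$trace) - 1) / 500
  sigma <- sd(ses_b$trace[t < 600])
  art <- t >= 800 & t < 830
  set.seed(1)
  ses_b$trace[art] <- ses_b$trace[art] + 8 * sigma * rnorm(sum(art))
  rep_b <- analyze_seizure_session(ses_b)
  expect_true(any(rep_b$events$duration_s > 15))
  expect_equal(nrow(rep_b$seizures), 0)
})

test_that("latency censoring follows the 60 min convention", {
  p <- spectro_params()
  no_sz <- tibble::tibble(start_s = numeric(0))
  lat <- first_seizure_latency(no_sz, t_inject = 600, p)
  expect_equal(lat$latency_min, 60)
  expect_true(lat$censored)
  # single seizure 1074 s after injection: 17.9 min
  one <- tibble::tibble(start_s = 600 + 1074)
  lat1 <- first_seizure_latency(one, 600, p)
  expect_equal(lat1$latency_min, 17.9)
  expect_false(lat1$censored)
  # a seizure before injection is an inconsistency, not a latency
  expect_error(first_seizure_latency(tibble::tibble(start_s = 300), 600, p),
               "before injection")
  # 11-animal day-time group: 8 censored, three latencies summing to 92 min
  lats <- c(rep(60, 8), 20, 30, 42)
  expect_equal(mean(lats), 52)
})

test_that("cumulative activity is monotone and threshold-monotone", {
  ses <- sim_lfp_fourap(duration_s = 900, fs = 500, injection_time_s = 400,
                        seizures = data.frame(onset_s = 600, duration_s = 30,
                                              amplitude_sd = 7),
                        seed = 68)
  zm <- zscore_spectrogram(ses, baseline_interval = c(0, 400))
  cc4 <- cumulative_activity(zm, z_threshold = 4)
  cc6 <- cumulative_activity(zm, z_threshold = 6)
  expect_true(all(diff(cc4$cumulative) >= 0))
  expect_true(all(cc6$cumulative <= cc4$cumulative + 1e-9))
  expect_lte(nrow(detect_pathological_events(zm, z_threshold = 6)),
             nrow(detect_pathological_events(zm, z_threshold = 4)))
  # subthreshold recording: flat zero curve
  quiet <- sim_lfp_fourap(duration_s = 400, fs = 250, injection_time_s = 350,
                          seizures = NULL, interictal = NULL, slow_osc = NULL,
                          seed = 69)
  zq <- zscore_spectrogram(quiet, baseline_interval = c(0, 350))
  ccq <- cumulative_activity(zq, z_threshold = max(zq$z) + 1)
  expect_true(all(ccq$cumulative == 0))
  # the power-integration variant is also monotone
  ccp <- cumulative_activity(zm, method = "power")
  expect_true(all(diff(ccp$cumulative) >= 0))
})

test_that("spectro params validate their invariants", {
  expect_error(spectro_params(step_s = 20), "step_s")
  expect_error(spectro_params(f_lo = 100, f_hi = 8), "f_lo")
  expect_error(spectro_params(notch = c(1, 3)), "notch")
  expect_error(zscore_spectrogram(
    sim_lfp_fourap(duration_s = 60, fs = 250, injection_time_s = 5,
                   seizures = NULL, interictal = NULL, seed = 1),
    baseline_interval = c(0, 5)), "baseline")
})
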