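mk_lfp <- function(trace, fs, onsets) {
  structure(list(trace = trace, fs = fs, duration_s = length(trace) / fs,
                 mode = "visual",
                 annotations = tibble::tibble(onset_s = onsets, kind = "stimulus"),
                 truth = NULL),
            class = "clop_lfp")
}

test_that("a pure sinusoid peaks at the nearest frequency bin", {
  fs <- 500
  t <- (0:(20 * fs - 1)) / fs
  lfp <- mk_lfp(sin(2 * pi * 28 * t), fs, onsets = c(2, 6, 10))
  s <- epoch_power_spectrum(lfp, smooth_span = 0)
  expect_equal(s$frequency_hz[which.max(s$power_db)], 28, tolerance = 0.03)
})

test_that("averaging identical trials equals the single-trial spectrum", {
  fs <- 500
  set.seed(4)
  seg <- rnorm(4 * fs)
  trace <- c(rep(0, fs), rep(seg, 3), rep(0, fs))
  onsets <- 1 + (0:2) * 4
  s3 <- epoch_power_spectrum(mk_lfp(trace, fs, onsets))
  s1 <- epoch_power_spectrum(mk_lfp(trace, fs, onsets[1]))
  expect_equal(s3$power_db, s1$power_db, tolerance = 1e-12)
  expect_equal(attr(s3, "n_trials"), 3)
})

test_that("white-noise stimulus and baseline spectra are indistinguishable", {
  ses <- sim_lfp_visual(n_trials = 40, fs = 500,
                        gamma = list(center_hz = 28, amplitude_db = 0,
                                     bandwidth_hz = 8),
                        background = list(exponent = 0, sd = 1), seed = 19)
  d <- stimulus_power_change(epoch_power_spectrum(ses),
                             epoch_power_spectrum(ses, mode = "baseline"))
  expect_lt(abs(mean(d$delta_db)), 0.3)
})

test_that("the aperiodic fit recovers an exact power law", {
  f <- seq(1.25, 120, by = 1.25)
  s <- structure(tibble::tibble(frequency_hz = f,
                                power_db = 10 * log10(100 * f^-2)),
                 class = c("clop_spectrum", "tbl_df", "tbl", "data.frame"))
  fit <- fit_aperiodic(s)
  expect_equal(fit$exponent, 20, tolerance = 1e-9)
  expect_equal(fit$offset, 20, tolerance = 1e-9)   # 10*log10(100)
  expect_lt(fit$residual_rms, 1e-9)
  # a bump outside the fit bands does not move the fit
  s2 <- s
  s2$power_db <- s2$power_db + 8 * exp(-(f - 30)^2 / (2 * 2^2))
  fit2 <- fit_aperiodic(s2)
  expect_equal(fit2$exponent, fit$exponent, tolerance = 1e-3)
  # an affine +3 dB offset moves only the offset
  s3 <- s
  s3$power_db <- s3$power_db + 3
  fit3 <- fit_aperiodic(s3)
  expect_equal(fit3$offset, fit$offset + 3, tolerance = 1e-9)
  expect_equal(fit3$exponent, fit$exponent, tolerance = 1e-9)
})

test_that("prominence of a pure aperiodic spectrum is exactly zero", {
  f <- seq(1.25, 120, by = 1.25)
  s <- structure(tibble::tibble(frequency_hz = f,
                                power_db = 30 - 25 * log10(f)),
                 class = c("clop_spectrum", "tbl_df", "tbl", "data.frame"))
  p <- gamma_peak_prominence(s)
  expect_lt(p$prominence_db, 1e-9)
})

test_that("prominence is invariant to affine-in-log10(f) additions", {
  ses <- sim_lfp_visual(n_trials = 20, fs = 500, seed = 25)
  s <- epoch_power_spectrum(ses)
  p0 <- gamma_peak_prominence(s)$prominence_db
  s2 <- s
  s2$power_db <- s2$power_db + 4 - 7 * log10(s2$frequency_hz)
  expect_equal(gamma_peak_prominence(s2)$prominence_db, p0, tolerance = 1e-9)
})

test_that("injected gamma bumps are recovered across the relevant range", {
  # the reported day/night prominence range; median across simulated animals
  for (h in c(5.3, 6.9)) {
    est <- vapply(1:5, function(s) {
      ses <- sim_lfp_visual(n_trials = 40, fs = 500,
                            gamma = list(center_hz = 28, amplitude_db = h,
                                         bandwidth_hz = 8),
                            seed = 300 * h + s)
      analyze_gamma_session(ses)$prominence$prominence_db
    }, numeric(1))
    expect_equal(median(est), h, tolerance = 0.5 / h)
  }
})

test_that("estimator variance shrinks with trial count", {
  est <- function(n_trials, seed) {
    ses <- sim_lfp_visual(n_trials = n_trials, fs = 500,
                          gamma = list(center_hz = 28, amplitude_db = 6,
                                       bandwidth_hz = 8),
                          seed = seed)
    analyze_gamma_session(ses)$prominence$prominence_db
  }
  e10 <- vapply(1:12, function(s) est(10, 900 + s), numeric(1))
  e60 <- vapply(1:12, function(s) est(60, 950 + s), numeric(1))
  expect_lt(stats::var(e60), stats::var(e10))
})

test_that("day-on vs night-off gamma separates across 9 animals", {
  n_mice <- 9
  delta_in_band <- vapply(seq_len(n_mice), function(m) {
    day <- sim_lfp_visual(n_trials = 30, fs = 500,
                          gamma = list(center_hz = 28, amplitude_db = 6.9,
                                       bandwidth_hz = 8),
                          seed = 7100 + m)
    night <- sim_lfp_visual(n_trials = 30, fs = 500,
                            gamma = list(center_hz = 28, amplitude_db = 0,
                                         bandwidth_hz = 8),
                            seed = 7200 + m)
    gd <- analyze_gamma_session(day)
    gn <- analyze_gamma_session(night)
    sel <- gd$delta$frequency_hz >= 20 & gd$delta$frequency_hz <= 40
    mean(gd$delta$delta_db[sel]) - mean(gn$delta$delta_db[sel])
  }, numeric(1))
  r <- rank_tests(delta_in_band, rep(0, n_mice), paired = TRUE)
  expect_lt(r$p_value, 0.01)
  expect_true(all(delta_in_band > 0))
})

test_that("grid mismatches and bad bands are rejected", {
  ses <- sim_lfp_visual(n_trials = 5, fs = 500, seed = 2)
  s <- epoch_power_spectrum(ses)
  s_short <- s[-1, ]
  expect_error(stimulus_power_change(s, s_short), "grids")
  expect_error(fit_aperiodic(s, bands = list(c(8, 20), c(15, 30))),
               "non-overlapping")
  expect_error(fit_aperiodic(s, bands = list(c(8, 20), c(80, 500))), "range")
})
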