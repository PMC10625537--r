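# ---- spectral synthesis helpers ------------------------------------------

# Gaussian noise with prescribed amplitude spectrum shape(f) (f > 0, Hz).
# Coefficients are complex-normal, so the expected periodogram is
# proportional to shape(f)^2 and the theoretical sd is known in closed form;
# `target_sd` rescales deterministically (no data-dependent normalization).
.fft_noise <- function(n, fs, shape, target_sd = NULL, scale = NULL) {
  nf <- floor(n / 2)
  f <- (1:nf) * fs / n
  amp <- shape(f)
  z <- complex(real = rnorm(nf), imaginary = rnorm(nf)) / sqrt(2) * amp
  if (n %% 2 == 0) z[nf] <- complex(real = rnorm(1)) * amp[nf]
  Z <- complex(length.out = n)
  Z[2:(nf + 1)] <- z
  idx <- if (n %% 2 == 0) seq_len(nf - 1) else seq_len(nf)
  Z[n + 1 - idx] <- Conj(Z[idx + 1])
  x <- Re(fft(Z, inverse = TRUE)) / n
  theo_sd <- sqrt(2 * sum(amp^2)) / n
  if (!is.null(target_sd)) {
    scale <- target_sd / theo_sd
  }
  list(x = x * scale, scale = scale)
}

# aperiodic 1/f^exponent background; flat below 1 Hz to keep variance finite
.background_shape <- function(exponent) {
  function(f) pmax(f, 1)^(-exponent / 2)
}

# two-state semi-Markov UP/DOWN gain envelope, smoothed with a short ramp
.up_state_envelope <- function(n, fs, rate_hz, up_fraction, up_gain,
                               ramp_s = 0.05) {
  if (up_gain == 1 || rate_hz <= 0) return(rep(1, n))
  mean_up <- up_fraction / rate_hz
  mean_down <- (1 - up_fraction) / rate_hz
  up0 <- runif(1) < up_fraction
  # draw enough alternating state durations in one go, top up if short
  lens <- integer(0); vals <- numeric(0)
  while (sum(lens) < n) {
    k <- max(16L, ceiling(2 * rate_hz * (n - sum(lens)) / fs))
    up_seq <- xor(up0, (seq_len(2 * k) + length(lens)) %% 2 == 0)
    dur <- rexp(2 * k, 1 / ifelse(up_seq, mean_up, mean_down))
    lens <- c(lens, pmax(1L, as.integer(round(dur * fs))))
    vals <- c(vals, ifelse(up_seq, up_gain, 1))
  }
  g <- rep(vals, lens)[seq_len(n)]
  k <- max(1L, round(ramp_s * fs))
  as.numeric(stats::filter(g, rep(1 / k, k), sides = 2, circular = TRUE))
}

# raised-cosine gate equal to 1 on [on, off], with `edge` s transitions
.cos_gate <- function(t, on, off, edge = 0.1) {
  g <- numeric(length(t))
  g[t >= on & t <= off] <- 1
  rise <- t > on - edge & t < on
  g[rise] <- 0.5 * (1 + cos(pi * (on - t[rise]) / edge))
  fall <- t > off & t < off + edge
  g[fall] <- 0.5 * (1 + cos(pi * (t[fall] - off) / edge))
  g
}

.new_lfp <- function(trace, fs, mode, annotations, truth) {
  structure(list(trace = trace, fs = fs,
                 duration_s = length(trace) / fs,
                 mode = mode, annotations = annotations, truth = truth),
            class = "clop_lfp")
}

#' @export
print.clop_lfp <- function(x, ...) {
  cat(sprintf("<clop_lfp> %s session: %.1f s at %g Hz, %d annotations\n",
              x$mode, x$duration_s, x$fs, nrow(x$annotations)))
  invisible(x)
}

# ---- visual (drifting-grating) sessions ----------------------------------

#' Simulate an LFP session with visually evoked gamma oscillations
#'
#' Generates a 1/f-background LFP with repeated visual-stimulation trials:
#' each trial is `stim_s` seconds of drifting-grating "stimulation" followed
#' by `gap_s` seconds of equiluminant grey. During stimulation a narrowband
#' gamma component is added whose power spectral density sits
#' `amplitude_db` dB above the aperiodic background over a flat-top band of
#' width `bandwidth_hz` centred on `center_hz` (Gaussian shoulders, 1.5 Hz
#' SD). The injected bump height in dB is therefore the generator's ground
#' truth for downstream peak-prominence recovery. `amplitude_db = 0` yields
#' stimulus epochs statistically identical to grey epochs.
#'
#' @param n_trials Number of stimulation trials.
#' @param fs Sample rate, Hz (must exceed twice the highest simulated
#'   frequency component).
#' @param stim_s,gap_s Stimulus-on and grey durations per trial (s).
#' @param first_onset_s Time of the first stimulus onset (s).
#' @param gamma `list(center_hz=, amplitude_db=, bandwidth_hz=)`.
#' @param background `list(exponent=, sd=)`: aperiodic 1/f exponent
#'   (power-law of power vs frequency) and trace SD.
#' @param slow_osc Optional `list(rate_hz=, up_fraction=, up_gain=)`
#'   UP/DOWN-state gating of the broadband background (urethane-like);
#'   `NULL` (awake-like) disables it.
#' @param mains_hz Optional mains frequency; adds a constant tone of SD
#'   `mains_sd`.
#' @param mains_sd SD of the mains tone when `mains_hz` is set.
#' @param seed Integer seed (mandatory).
#' @return A `clop_lfp` object: `trace`, `fs`, `annotations` (tibble of
#'   stimulus `onset_s`), and `truth` (the gamma parameters).
#' @examples
#' ses <- sim_lfp_visual(n_trials = 5, fs = 500, seed = 1)
#' @export
sim_lfp_visual <- function(n_trials = 40, fs = 10000,
                           stim_s = 2, gap_s = 2, first_onset_s = 4,
                           gamma = list(center_hz = 28, amplitude_db = 6.9,
                                        bandwidth_hz = 8),
                           background = list(exponent = 2, sd = 1),
                           slow_osc = NULL,
                           mains_hz = NULL, mains_sd = 0.5,
                           seed) {
  if (missing(seed)) abort("seed is mandatory")
  f_max <- max(gamma$center_hz + gamma$bandwidth_hz / 2 + 5, mains_hz %||% 0)
  if (fs <= 2 * f_max) abort("fs must exceed twice the highest simulated frequency")
  set.seed(seed)
  duration_s <- first_onset_s + n_trials * (stim_s + gap_s) + gap_s
  n <- round(duration_s * fs)
  t <- (seq_len(n) - 1) / fs

  shape_bg <- .background_shape(background$exponent)
  bg <- .fft_noise(n, fs, shape_bg, target_sd = background$sd)
  x <- bg$x
  if (!is.null(slow_osc)) {
    x <- x * .up_state_envelope(n, fs, slow_osc$rate_hz,
                                slow_osc$up_fraction, slow_osc$up_gain)
  }

  onsets <- first_onset_s + (seq_len(n_trials) - 1) * (stim_s + gap_s)
  if (gamma$amplitude_db > 0) {
    bump_db <- function(f) {
      d <- pmax(abs(f - gamma$center_hz) - gamma$bandwidth_hz / 2, 0)
      gamma$amplitude_db * exp(-d^2 / (2 * 1.5^2))
    }
    shape_gamma <- function(f) shape_bg(f) * sqrt(pmax(10^(bump_db(f) / 10) - 1, 0))
    carrier <- .fft_noise(n, fs, shape_gamma, scale = bg$scale)$x
    gate <- numeric(n)
    for (on in onsets) gate <- pmax(gate, .cos_gate(t, on, on + stim_s))
    x <- x + carrier * gate
  }
  if (!is.null(mains_hz)) {
    x <- x + sqrt(2) * mains_sd * sin(2 * pi * mains_hz * t + runif(1, 0, 2 * pi))
  }
  .new_lfp(x, fs, "visual",
           annotations = tibble(onset_s = onsets, kind = "stimulus"),
           truth = list(gamma = gamma, stim_s = stim_s, gap_s = gap_s,
                        background = background))
}

# ---- 4-AP (epileptiform) sessions ----------------------------------------

#' Simulate a 4-AP-like epileptiform LFP session with ground-truth seizures
#'
#' Generates a urethane-like baseline (1/f background gated by slow UP/DOWN
#' alternation) followed, after `injection_time_s`, by interictal discharges
#' whose rate ramps up, and by ground-truth seizures: continual large-
#' amplitude rhythmic discharges (amplitude-modulated `discharge_hz`
#' fundamental plus harmonics, ramped envelope) of the configured duration,
#' each followed by post-ictal suppression of the background. Amplitudes are
#' expressed in units of the realized baseline SD.
#'
#' @param duration_s Total session length (s).
#' @param fs Sample rate (Hz).
#' @param injection_time_s Time of the simulated intracortical injection (s);
#'   the segment before it is pure baseline.
#' @param seizures A data frame with columns `onset_s`, `duration_s`,
#'   `amplitude_sd` (sorted, non-overlapping, all after injection), or `NULL`
#'   for none.
#' @param discharge_hz Fundamental frequency of ictal/interictal discharges.
#' @param interictal `list(rate_per_min=, ramp_s=, amplitude_sd=,
#'   duration_s=)`: post-injection discharge rate ramps linearly from 0 to
#'   `rate_per_min` over `ramp_s`; `NULL` disables.
#' @param postictal_s Post-ictal suppression duration after each seizure (s);
#'   background is attenuated to 20% for that long.
#' @param background,slow_osc,mains_hz,mains_sd,seed As in
#'   [sim_lfp_visual()]; `slow_osc` defaults to UP-state gating.
#' @return A `clop_lfp` object whose `truth` holds `injection_time_s`, the
#'   seizure table, the interictal discharge times, and the realized
#'   baseline SD.
#' @examples
#' ses <- sim_lfp_fourap(duration_s = 300, fs = 500, injection_time_s = 120,
#'                       seizures = data.frame(onset_s = 200, duration_s = 30,
#'                                             amplitude_sd = 8),
#'                       seed = 1)
#' @export
sim_lfp_fourap <- function(duration_s = 4200, fs = 10000,
                           injection_time_s = 600,
                           seizures = data.frame(onset_s = injection_time_s + 1074,
                                                 duration_s = 60,
                                                 amplitude_sd = 8),
                           discharge_hz = 6,
                           interictal = list(rate_per_min = 2, ramp_s = 600,
                                             amplitude_sd = 5, duration_s = 2,
                                             min_gap_s = 15),
                           postictal_s = 30,
                           background = list(exponent = 2, sd = 1),
                           slow_osc = list(rate_hz = 1, up_fraction = 0.4,
                                           up_gain = 2),
                           mains_hz = NULL, mains_sd = 0.5,
                           seed) {
  if (missing(seed)) abort("seed is mandatory")
  f_max <- max(5 * discharge_hz, mains_hz %||% 0)
  if (fs <= 2 * f_max) abort("fs must exceed twice the highest simulated frequency")
  if (injection_time_s <= 0 || injection_time_s >= duration_s) {
    abort("injection_time_s must lie inside the recording")
  }
  sz <- if (is.null(seizures) || nrow(as.data.frame(seizures)) == 0) {
    tibble(onset_s = numeric(0), duration_s = numeric(0),
           amplitude_sd = numeric(0))
  } else as_tibble(as.data.frame(seizures))
  if (nrow(sz) > 0) {
    sz <- dplyr::arrange(sz, .data$onset_s)
    if (any(sz$duration_s <= 0)) abort("seizure durations must be > 0")
    if (any(sz$onset_s < injection_time_s)) {
      abort("seizures must start after injection_time_s")
    }
    if (any(sz$onset_s + sz$duration_s > duration_s)) {
      abort("seizure extends past the end of the recording")
    }
    ends <- sz$onset_s + sz$duration_s
    if (nrow(sz) > 1 &&
        any(sz$onset_s[-1] < ends[-nrow(sz)] + postictal_s)) {
      abort("a seizure overlaps the post-ictal suppression window of the previous one")
    }
  }
  set.seed(seed)
  n <- round(duration_s * fs)
  t <- (seq_len(n) - 1) / fs

  bg <- .fft_noise(n, fs, .background_shape(background$exponent),
                   target_sd = background$sd)$x
  if (!is.null(slow_osc)) {
    bg <- bg * .up_state_envelope(n, fs, slow_osc$rate_hz,
                                  slow_osc$up_fraction, slow_osc$up_gain)
  }
  base_idx <- t < injection_time_s
  sigma_base <- sd(bg[base_idx])

  # post-ictal suppression of the background
  supp <- rep(1, n)
  for (i in seq_len(nrow(sz))) {
    e0 <- sz$onset_s[i] + sz$duration_s[i]
    supp <- supp * (1 - 0.8 * .cos_gate(t, e0, e0 + postictal_s, edge = 1))
  }
  x <- bg * supp

  # seizures: amplitude-modulated rhythmic discharge with harmonics
  for (i in seq_len(nrow(sz))) {
    on <- sz$onset_s[i]; dur <- sz$duration_s[i]
    idx <- which(t >= on & t < on + dur)
    tt <- t[idx] - on
    ramp <- pmin(1, tt / 2, (dur - tt) / 2)
    am <- 1 + 0.25 * sin(2 * pi * 0.4 * tt + runif(1, 0, 2 * pi))
    ph <- runif(3, 0, 2 * pi)
    carrier <- sin(2 * pi * discharge_hz * tt + ph[1]) +
      0.5 * sin(2 * pi * 2 * discharge_hz * tt + ph[2]) +
      0.25 * sin(2 * pi * 3 * discharge_hz * tt + ph[3])
    x[idx] <- x[idx] + sz$amplitude_sd[i] * sigma_base * ramp * am * carrier
  }

  # interictal discharges: inhomogeneous Poisson (thinning), kept clear of
  # seizures and post-ictal windows
  ii_times <- numeric(0)
  if (!is.null(interictal) && interictal$rate_per_min > 0) {
    rate_max <- interictal$rate_per_min / 60
    t_cand <- injection_time_s
    repeat {
      t_cand <- t_cand + rexp(1, rate_max)
      if (t_cand > duration_s - interictal$duration_s) break
      r <- rate_max * min(1, (t_cand - injection_time_s) / interictal$ramp_s)
      if (runif(1) > r / rate_max) next
      blocked <- FALSE
      for (i in seq_len(nrow(sz))) {
        if (t_cand + interictal$duration_s > sz$onset_s[i] - 1 &&
            t_cand < sz$onset_s[i] + sz$duration_s[i] + postictal_s) {
          blocked <- TRUE; break
        }
      }
      if (blocked) next
      min_gap <- interictal$min_gap_s %||% 0
      if (length(ii_times) > 0 && t_cand - tail(ii_times, 1) < min_gap) next
      ii_times <- c(ii_times, t_cand)
      idx <- which(t >= t_cand & t < t_cand + interictal$duration_s)
      tt <- t[idx] - t_cand
      env <- sin(pi * tt / interictal$duration_s)^2
      ph <- runif(2, 0, 2 * pi)
      burst <- sin(2 * pi * discharge_hz * tt + ph[1]) +
        0.5 * sin(2 * pi * 2 * discharge_hz * tt + ph[2])
      x[idx] <- x[idx] + interictal$amplitude_sd * sigma_base * env * burst
    }
  }
  if (!is.null(mains_hz)) {
    x <- x + sqrt(2) * mains_sd * sin(2 * pi * mains_hz * t + runif(1, 0, 2 * pi))
  }
  ann <- tibble(onset_s = injection_time_s, kind = "injection")
  .new_lfp(x, fs, "fourap", annotations = ann,
           truth = list(injection_time_s = injection_time_s, seizures = sz,
                        interictal_times = ii_times, sigma_base = sigma_base,
                        discharge_hz = discharge_hz))
}
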