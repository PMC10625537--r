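# ---- periodogram helpers -------------------------------------------------

.hann <- function(n) 0.5 - 0.5 * cos(2 * pi * (seq_len(n) - 1) / n)

# one-sided Hann periodogram, density scaling (power per Hz)
.periodogram <- function(x, fs) {
  n <- length(x)
  w <- .hann(n)
  X <- fft(x * w)
  nf <- floor(n / 2)
  p <- (Mod(X[2:(nf + 1)])^2) * 2 / (fs * sum(w^2))
  list(frequency_hz = (1:nf) * fs / n, power = p)
}

# moving-average smoothing with a symmetric kernel, edge-renormalized
.smooth_vec <- function(x, weights) {
  if (length(weights) <= 1) return(x)
  m <- (length(weights) - 1) / 2
  n <- length(x)
  out <- numeric(n)
  for (i in seq_len(n)) {
    j <- max(1, i - m):min(n, i + m)
    w <- weights[j - i + m + 1]
    out[i] <- sum(x[j] * w) / sum(w)
  }
  out
}

.daniell_weights <- function(span) {
  if (span <= 0) return(1)
  k <- stats::kernel("modified.daniell", span)
  k[-span:span]
}

.new_spectrum <- function(frequency_hz, power_db, n_trials, epoch, mode,
                          smooth_span) {
  out <- tibble(frequency_hz = frequency_hz, power_db = power_db)
  structure(out, class = c("clop_spectrum", class(out)),
            n_trials = n_trials, epoch = epoch, mode = mode,
            smooth_span = smooth_span)
}

# ---- operations ----------------------------------------------------------

#' Trial-averaged power spectrum of stimulus or baseline epochs
#'
#' Computes, for each trial, a single Hann-windowed periodogram (density
#' scaling) of the analysis epoch — by default the 800 ms window from 200 ms
#' to 1 s after stimulus onset — averages across trials in *linear* power,
#' smooths the averaged periodogram with a modified Daniell kernel (span
#' `smooth_span`; periodogram-variance reduction), and converts to dB
#' (10*log10). In `"baseline"` mode the same-length window is taken inside
#' the grey period that follows each stimulus (offset by `stim_duration_s`).
#'
#' @param lfp A `clop_lfp` object (or `list(trace =, fs =)`).
#' @param onsets Stimulus onset times (s); defaults to the session's
#'   annotations.
#' @param epoch `c(start, end)` seconds relative to stimulus onset.
#' @param mode `"stimulus"` or `"baseline"`.
#' @param stim_duration_s Stimulus duration, used to locate grey epochs.
#' @param smooth_span Modified Daniell span (0 disables smoothing).
#' @return A `clop_spectrum` tibble (`frequency_hz`, `power_db`) with
#'   `n_trials`, `epoch`, `mode` attributes. Frequency resolution is
#'   `1/(epoch length)` (1.25 Hz for 800 ms).
#' @export
epoch_power_spectrum <- function(lfp, onsets = NULL, epoch = c(0.2, 1.0),
                                 mode = c("stimulus", "baseline"),
                                 stim_duration_s = 2, smooth_span = 2) {
  mode <- match.arg(mode)
  fs <- lfp$fs
  onsets <- onsets %||% lfp$annotations$onset_s
  if (length(onsets) < 1) abort("need at least one trial")
  offs <- if (mode == "baseline") stim_duration_s else 0
  t0 <- onsets + offs + epoch[1]
  n <- round((epoch[2] - epoch[1]) * fs)
  i0 <- round(t0 * fs) + 1
  ok <- i0 >= 1 & (i0 + n - 1) <= length(lfp$trace)
  if (any(!ok)) {
    warn(sprintf("%d trial(s) extend outside the recording; dropped", sum(!ok)))
  }
  i0 <- i0[ok]
  if (length(i0) == 0) abort("all trials fall outside the recording")
  acc <- NULL
  for (i in i0) {
    pg <- .periodogram(lfp$trace[i:(i + n - 1)], fs)
    acc <- if (is.null(acc)) pg$power else acc + pg$power
  }
  p <- .smooth_vec(acc / length(i0), .daniell_weights(smooth_span))
  .new_spectrum(pg$frequency_hz, 10 * log10(p),
                n_trials = length(i0), epoch = epoch, mode = mode,
                smooth_span = smooth_span)
}

#' Aperiodic (1/f) fit to a power spectrum on flanking bands
#'
#' Least-squares line in (log10 f, power_dB) space fitted over the union of
#' the given bands only — by default 8-20 Hz and 80-110 Hz, straddling but
#' excluding the gamma band — and extrapolated over the whole spectrum. The
#' model is `P_dB(f) = offset - exponent * log10(f)`, i.e. `exponent` is the
#' spectral slope in dB/decade (a `1/f^a` power law has exponent `10*a`).
#'
#' @param spectrum A `clop_spectrum`.
#' @param bands List of `c(lo, hi)` frequency bands (Hz) to fit on.
#' @param exclude Optional `c(lo, hi)` band to drop from the fit (e.g.
#'   `c(49, 51)` when mains contamination is present).
#' @return A `clop_aperiodic_fit` object (offset dB, exponent dB/decade,
#'   residual RMS over the fit bins, the bands used).
#' @export
fit_aperiodic <- function(spectrum, bands = list(c(8, 20), c(80, 110)),
                          exclude = NULL) {
  f <- spectrum$frequency_hz
  lo <- vapply(bands, `[`, numeric(1), 1)
  hi <- vapply(bands, `[`, numeric(1), 2)
  if (any(hi > max(f)) || any(lo < min(f))) abort("fit bands outside spectrum range")
  for (i in seq_along(bands)[-1]) {
    if (lo[i] < hi[i - 1]) abort("fit bands must be non-overlapping and ordered")
  }
  sel <- Reduce(`|`, lapply(bands, function(b) f >= b[1] & f <= b[2]))
  if (!is.null(exclude)) sel <- sel & !(f >= exclude[1] & f <= exclude[2])
  for (b in bands) {
    if (sum(f >= b[1] & f <= b[2] & sel) < 3) abort("each fit band needs >= 3 bins")
  }
  lf <- log10(f[sel])
  if (diff(range(lf)) < 1e-12) abort("degenerate fit: constant frequency")
  m <- lm(spectrum$power_db[sel] ~ lf)
  res <- spectrum$power_db[sel] - unname(predict(m))
  structure(list(offset = unname(coef(m)[1]), exponent = -unname(coef(m)[2]),
                 bands = bands, exclude = exclude,
                 residual_rms = sqrt(mean(res^2)), n_bins = sum(sel)),
            class = "clop_aperiodic_fit")
}

#' @export
print.clop_aperiodic_fit <- function(x, ...) {
  cat(sprintf("<clop_aperiodic_fit> P_dB(f) = %.2f - %.2f*log10(f); RMS %.3f dB over %d bins\n",
              x$offset, x$exponent, x$residual_rms, x$n_bins))
  invisible(x)
}

#' @param object A `clop_aperiodic_fit`.
#' @param frequency_hz Frequencies at which to evaluate the fitted line.
#' @param ... Unused.
#' @rdname fit_aperiodic
#' @export
predict.clop_aperiodic_fit <- function(object, frequency_hz, ...) {
  object$offset - object$exponent * log10(frequency_hz)
}

#' Gamma-band peak prominence above the aperiodic fit
#'
#' Subtracts the extrapolated 1/f fit from the spectrum and returns the
#' maximum residual within the gamma search band, floored at 0 dB (a
#' spectrum at or below its aperiodic fit has no peak). Because both the
#' spectrum and the fit are in dB, the prominence is invariant to any
#' rescaling of the raw signal and to adding any affine-in-log10(f)
#' component.
#'
#' @param spectrum A `clop_spectrum`.
#' @param fit A `clop_aperiodic_fit`; computed from `spectrum` with default
#'   bands when `NULL`.
#' @param band `c(lo, hi)` gamma search band in Hz (default 20-40).
#' @return A one-row tibble: `prominence_db`, `peak_hz`, `band_lo`,
#'   `band_hi`.
#' @export
gamma_peak_prominence <- function(spectrum, fit = NULL, band = c(20, 40)) {
  if (is.null(fit)) fit <- fit_aperiodic(spectrum)
  f <- spectrum$frequency_hz
  if (band[1] < min(f) || band[2] > max(f)) abort("band outside spectrum")
  sel <- f >= band[1] & f <= band[2]
  r <- spectrum$power_db[sel] - predict(fit, f[sel])
  i <- which.max(r)
  tibble(prominence_db = max(r[i], 0),
         peak_hz = if (r[i] > 0) f[sel][i] else NA_real_,
         band_lo = band[1], band_hi = band[2])
}

#' Stimulus-minus-baseline spectral power change
#'
#' Per-frequency dB difference between a stimulus-epoch spectrum and its
#' grey-screen baseline spectrum from the same session.
#'
#' @param stim,base `clop_spectrum` objects on identical frequency grids.
#' @return A tibble (`frequency_hz`, `delta_db`).
#' @export
stimulus_power_change <- function(stim, base) {
  if (length(stim$frequency_hz) != length(base$frequency_hz) ||
      any(abs(stim$frequency_hz - base$frequency_hz) > 1e-9)) {
    abort("frequency grids do not match")
  }
  tibble(frequency_hz = stim$frequency_hz,
         delta_db = stim$power_db - base$power_db)
}

#' Full gamma analysis of one visual session
#'
#' Convenience wrapper: stimulus and baseline epoch spectra, aperiodic fit
#' on the stimulus spectrum, gamma peak prominence, and the
#' stimulus-baseline dB difference.
#'
#' @inheritParams epoch_power_spectrum
#' @inheritParams gamma_peak_prominence
#' @param fit_bands Bands for [fit_aperiodic()].
#' @return A list of class `clop_gamma_session`: `stim`, `base`, `fit`,
#'   `prominence` (tibble), `delta`.
#' @export
analyze_gamma_session <- function(lfp, epoch = c(0.2, 1.0), band = c(20, 40),
                                  fit_bands = list(c(8, 20), c(80, 110)),
                                  stim_duration_s = 2, smooth_span = 2) {
  stim <- epoch_power_spectrum(lfp, epoch = epoch, mode = "stimulus",
                               stim_duration_s = stim_duration_s,
                               smooth_span = smooth_span)
  base <- epoch_power_spectrum(lfp, epoch = epoch, mode = "baseline",
                               stim_duration_s = stim_duration_s,
                               smooth_span = smooth_span)
  fit <- fit_aperiodic(stim, bands = fit_bands)
  structure(list(stim = stim, base = base, fit = fit,
                 prominence = gamma_peak_prominence(stim, fit, band = band),
                 delta = stimulus_power_change(stim, base)),
            class = "clop_gamma_session")
}
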