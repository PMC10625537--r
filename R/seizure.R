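#' Parameters of the z-score spectrogram seizure quantification
#'
#' Collects every tunable of the epileptiform-activity pipeline. Defaults
#' follow the quantification design: 10 s spectrogram bins shifted by 1 s,
#' 8-100 Hz with the 49-51 Hz mains region omitted, a 4 SD threshold on the
#' baseline-normalized power, seizures defined as suprathreshold events
#' lasting more than 15 s that satisfy a rhythmicity criterion, and a 60 min
#' censoring horizon for the latency to the first seizure.
#'
#' The per-bin spectrum is Welch-averaged (Hann sub-windows of
#' `sub_window_s` s, 50% overlap) and aggregated into `freq_band_hz`-wide
#' rows, which stabilizes the per-cell Z distribution enough for a 4 SD
#' "any frequency exceeds" rule to be meaningful (a single 10 s periodogram
#' per bin would have exponential-tailed cells and fire continuously).
#'
#' @param bin_s Spectrogram bin width (s).
#' @param step_s Bin time shift (s); must be <= `bin_s`.
#' @param f_lo,f_hi Frequency range analyzed (Hz).
#' @param notch `c(lo, hi)` mains band omitted from all statistics.
#' @param z_threshold Threshold in baseline SDs.
#' @param seizure_min_s Minimum seizure duration (s, strict).
#' @param censor_min Latency censoring horizon (minutes).
#' @param sub_window_s Welch sub-window inside each bin (s).
#' @param freq_band_hz Width of aggregated frequency rows (Hz).
#' @param cumulate `"z_excess"` (sum of Z - threshold over suprathreshold
#'   cells) or `"power"` (sum of raw binned power over suprathreshold cells)
#'   for [cumulative_activity()].
#' @param rhythm_subwindow_s Sub-window for the (finer) rhythmicity spectra.
#' @param rhythm_peak_band `c(lo, hi)` Hz in which the dominant discharge
#'   frequency is sought.
#' @param rhythm_frac Minimum fraction of 8-100 Hz power at harmonics of the
#'   dominant frequency for a bin to count as rhythmic.
#' @param rhythm_bin_frac Minimum fraction of rhythmic bins within an event.
#' @return A `clop_spectro_params` list.
#' @export
spectro_params <- function(bin_s = 10, step_s = 1, f_lo = 8, f_hi = 100,
                           notch = c(49, 51), z_threshold = 4,
                           seizure_min_s = 15, censor_min = 60,
                           sub_window_s = 0.5, freq_band_hz = 4,
                           cumulate = c("z_excess", "power"),
                           rhythm_subwindow_s = 2,
                           rhythm_peak_band = c(2, 20),
                           rhythm_frac = 0.5, rhythm_bin_frac = 0.7) {
  cumulate <- match.arg(cumulate)
  if (step_s > bin_s) abort("step_s must be <= bin_s")
  if (f_lo >= f_hi) abort("f_lo must be < f_hi")
  if (notch[1] < f_lo || notch[2] > f_hi) abort("notch must lie inside [f_lo, f_hi]")
  structure(as.list(environment()), class = "clop_spectro_params")
}

# ---- internals -----------------------------------------------------------

# periodograms of Hann sub-windows (50% overlap) across the whole trace;
# returns power matrix [freq x segment] and segment start times
.segment_periodograms <- function(trace, fs, sub_window_s) {
  ns <- round(sub_window_s * fs)
  hop <- ns %/% 2
  starts <- seq(1, length(trace) - ns + 1, by = hop)
  w <- .hann(ns)
  nf <- floor(ns / 2)
  scale <- 2 / (fs * sum(w^2))
  P <- matrix(0, nf, length(starts))
  for (s in seq_along(starts)) {
    X <- fft(trace[starts[s]:(starts[s] + ns - 1)] * w)
    P[, s] <- Mod(X[2:(nf + 1)])^2 * scale
  }
  list(P = P, freq = (1:nf) * fs / ns, t_start = (starts - 1) / fs,
       sub_s = sub_window_s)
}

# average segment periodograms into sliding bins of bin_s every step_s
.bin_segments <- function(seg, duration_s, bin_s, step_s) {
  t_lo <- seq(0, duration_s - bin_s, by = step_s)
  seg_end <- seg$t_start + seg$sub_s
  cols <- lapply(t_lo, function(t0) {
    which(seg$t_start >= t0 - 1e-9 & seg_end <= t0 + bin_s + 1e-9)
  })
  P <- vapply(cols, function(j) rowMeans(seg$P[, j, drop = FALSE]),
              numeric(nrow(seg$P)))
  list(P = P, times = t_lo + bin_s / 2, t_lo = t_lo)
}

# aggregate frequency rows into bands of width band_hz over [f_lo, f_hi],
# dropping bands that touch the notch
.band_rows <- function(P, freq, f_lo, f_hi, band_hz, notch) {
  edges <- seq(f_lo, f_hi, by = band_hz)
  if (tail(edges, 1) < f_hi) edges <- c(edges, f_hi)
  lo <- edges[-length(edges)]; hi <- edges[-1]
  keep <- !(lo < notch[2] & hi > notch[1])
  rows <- lapply(seq_along(lo), function(i) {
    which(freq >= lo[i] & freq < hi[i] + ifelse(i == length(lo), 1e-9, 0))
  })
  B <- t(vapply(rows[keep], function(r) colMeans(P[r, , drop = FALSE]),
                numeric(ncol(P))))
  list(B = B, centers = (lo[keep] + hi[keep]) / 2,
       masked = tibble(lo = lo[!keep], hi = hi[!keep]))
}

# remove the mains band at full-recording resolution before any windowed
# analysis: short Welch sub-windows would otherwise leak in-notch power into
# neighbouring bands (Hann main lobe ~ 2 bins)
.spectral_notch <- function(trace, fs, notch) {
  n <- length(trace)
  f <- (seq_len(n) - 1) * fs / n
  f <- pmin(f, fs - f)
  X <- fft(trace)
  X[f >= notch[1] & f <= notch[2]] <- 0
  Re(fft(X, inverse = TRUE)) / n
}

.zscore_rows <- function(P, baseline_cols) {
  mu <- rowMeans(P[, baseline_cols, drop = FALSE])
  sdv <- apply(P[, baseline_cols, drop = FALSE], 1, sd)
  list(z = (P - mu) / sdv, mu = mu, sd = sdv)
}

#' Construct a z-score map directly
#'
#' Low-level constructor, mostly for programmatic and testing use;
#' [zscore_spectrogram()] is the normal entry point.
#'
#' @param times Bin-center times (s).
#' @param frequencies Row frequencies (Hz, band centers).
#' @param z Matrix `[frequency x time]` of z-scores.
#' @param params A [spectro_params()].
#' @param power Optional raw binned power matrix (same shape).
#' @param baseline_interval `c(start, end)` seconds.
#' @return A `clop_zscore_map`.
#' @export
zscore_map <- function(times, frequencies, z, params = spectro_params(),
                       power = NULL, baseline_interval = NULL) {
  stopifnot(nrow(z) == length(frequencies), ncol(z) == length(times))
  structure(list(times = times, frequencies = frequencies, z = z,
                 power = power, params = params,
                 baseline_interval = baseline_interval,
                 masked_bands = tibble(lo = params$notch[1], hi = params$notch[2])),
            class = "clop_zscore_map")
}

#' @export
print.clop_zscore_map <- function(x, ...) {
  cat(sprintf("<clop_zscore_map> %d frequency rows (%.0f-%.0f Hz) x %d bins (%.0f-%.0f s)\n",
              length(x$frequencies), min(x$frequencies), max(x$frequencies),
              length(x$times), min(x$times), max(x$times)))
  invisible(x)
}

#' Baseline-normalized (z-score) spectrogram of an LFP recording
#'
#' Computes a sliding-bin power spectrogram of the whole recording
#' (`bin_s`-wide bins every `step_s`; Welch-averaged Hann sub-windows inside
#' each bin), restricts it to `f_lo`-`f_hi` excluding the mains notch, and
#' normalizes every frequency row to its baseline mean and standard
#' deviation: `Z = (x - mean)/sd`, so each element is the excess power at
#' that frequency and time in baseline SDs.
#'
#' @param lfp A `clop_lfp` (or `list(trace =, fs =)`).
#' @param baseline_interval `c(start, end)` seconds of baseline (must
#'   precede the injection/manipulation); defaults to everything before the
#'   session's annotated injection.
#' @param params A [spectro_params()].
#' @return A `clop_zscore_map`: bin-center `times`, row `frequencies`,
#'   matrices `z` and `power`, the baseline interval, masked bands and
#'   params.
#' @export
zscore_spectrogram <- function(lfp, baseline_interval = NULL,
                               params = spectro_params()) {
  fs <- lfp$fs
  duration_s <- length(lfp$trace) / fs
  if (is.null(baseline_interval)) {
    inj <- lfp$annotations$onset_s[lfp$annotations$kind == "injection"][1]
    if (is.na(inj %||% NA)) abort("no baseline_interval given and no injection annotation")
    baseline_interval <- c(0, inj)
  }
  if (diff(baseline_interval) < params$bin_s) {
    abort("baseline shorter than one spectrogram bin")
  }
  trace <- .spectral_notch(lfp$trace, fs, params$notch)
  seg <- .segment_periodograms(trace, fs, params$sub_window_s)
  bins <- .bin_segments(seg, duration_s, params$bin_s, params$step_s)
  bands <- .band_rows(bins$P, seg$freq, params$f_lo, params$f_hi,
                      params$freq_band_hz, params$notch)
  base_cols <- which(bins$t_lo >= baseline_interval[1] &
                       bins$t_lo + params$bin_s <= baseline_interval[2])
  if (length(base_cols) < 2) abort("baseline contains fewer than two bins")
  zs <- .zscore_rows(bands$B, base_cols)
  bad <- !is.finite(zs$sd) | zs$sd <= 0
  if (any(bad)) {
    warn(sprintf("%d zero-variance frequency row(s) masked", sum(bad)))
  }
  structure(list(times = bins$times, frequencies = bands$centers[!bad],
                 z = zs$z[!bad, , drop = FALSE],
                 power = bands$B[!bad, , drop = FALSE],
                 params = params, baseline_interval = baseline_interval,
                 masked_bands = bands$masked,
                 baseline_mean = zs$mu[!bad], baseline_sd = zs$sd[!bad]),
            class = "clop_zscore_map")
}

#' Detect epileptiform events from a z-score map
#'
#' A time bin is suprathreshold iff the maximum of Z over frequencies
#' exceeds `z_threshold`; maximal runs of consecutive suprathreshold bins
#' are single events (runs separated by at least one subthreshold bin stay
#' distinct).
#'
#' @param zmap A `clop_zscore_map`.
#' @param z_threshold Threshold in baseline SDs; defaults to the map's
#'   params.
#' @return A tibble of events: `start_s`, `end_s` (bin-center based;
#'   `duration_s = n_bins * step_s`), `n_bins`, `peak_z`,
#'   `integrated_z_excess`.
#' @export
detect_pathological_events <- function(zmap, z_threshold = NULL) {
  thr <- z_threshold %||% zmap$params$z_threshold
  step <- zmap$params$step_s
  supra <- apply(zmap$z, 2, max) > thr
  r <- rle(supra)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1
  keep <- which(r$values)
  bin_s <- zmap$params$bin_s
  purrr::map_dfr(keep, function(k) {
    i <- starts[k]:ends[k]
    zz <- zmap$z[, i, drop = FALSE]
    # deconvolve the bin width: a continuous discharge of length L marks
    # ~ (L + bin_s)/step_s consecutive bins, so the active span is
    # n*step - (bin - step), centred inside the marked-bin envelope
    dur <- max(length(i) * step - (bin_s - step), step)
    t0 <- zmap$times[starts[k]] + (bin_s - step) / 2
    tibble(start_s = t0,
           end_s = t0 + dur,
           duration_s = dur,
           n_bins = length(i),
           peak_z = max(zz),
           integrated_z_excess = sum(pmax(zz - thr, 0)))
  })
}

#' Classify events as electrographic seizures
#'
#' An event is a seizure iff (1) it lasts strictly longer than
#' `seizure_min_s` and (2) it is rhythmic: in at least `rhythm_bin_frac` of
#' its spectrogram bins, the power concentrated at harmonics of the event's
#' dominant discharge frequency (the spectral peak in `rhythm_peak_band`,
#' harmonic windows of half-width `min(0.75, 0.15*f0)` Hz intersected with
#' the 8-100 Hz analysis range) accounts for at least `rhythm_frac` of the
#' 8-100 Hz band power (notch excluded). A broadband artifact of any
#' duration fails (2); a brief discharge of any amplitude fails (1).
#'
#' @param events Event tibble from [detect_pathological_events()].
#' @param lfp The recording the events came from.
#' @param params A [spectro_params()].
#' @return The subset of `events` classified as seizures, with extra columns
#'   `dominant_hz` and `rhythm_score` (fraction of rhythmic bins).
#' @export
classify_seizures <- function(events, lfp, params = spectro_params()) {
  long <- events[events$duration_s > params$seizure_min_s, , drop = FALSE]
  if (nrow(long) == 0) {
    return(dplyr::mutate(events[0, ], dominant_hz = numeric(0),
                         rhythm_score = numeric(0)))
  }
  fs <- lfp$fs
  res <- purrr::map_dfr(seq_len(nrow(long)), function(i) {
    i0 <- max(1, round(long$start_s[i] * fs) + 1)
    i1 <- min(length(lfp$trace), round(long$end_s[i] * fs))
    seg <- .segment_periodograms(lfp$trace[i0:i1], fs, params$rhythm_subwindow_s)
    span <- (i1 - i0 + 1) / fs
    bin_s <- min(params$bin_s, span)
    bins <- .bin_segments(seg, span, bin_s, params$step_s)
    f <- seg$freq
    pk <- f >= params$rhythm_peak_band[1] & f <= params$rhythm_peak_band[2]
    f0 <- f[pk][which.max(rowMeans(bins$P)[pk])]
    delta <- min(0.75, 0.15 * f0)
    denom_sel <- f >= params$f_lo & f <= params$f_hi &
      !(f >= params$notch[1] & f <= params$notch[2])
    harm <- outer(f, f0 * seq_len(floor(params$f_hi / f0)),
                  function(ff, h) abs(ff - h) <= delta)
    num_sel <- denom_sel & apply(harm, 1, any)
    frac <- colSums(bins$P[num_sel, , drop = FALSE]) /
      colSums(bins$P[denom_sel, , drop = FALSE])
    tibble(dominant_hz = f0, rhythm_score = mean(frac >= params$rhythm_frac))
  })
  out <- dplyr::bind_cols(long, res)
  out[out$rhythm_score >= params$rhythm_bin_frac, , drop = FALSE]
}

#' Latency to the first seizure, censored at the observation horizon
#'
#' Latency is `(first seizure start - injection time)/60` minutes; when no
#' seizure occurs within `censor_min` minutes the latency is set to
#' `censor_min` and flagged censored (the convention for terminated
#' recordings).
#'
#' @param seizures Seizure tibble from [classify_seizures()].
#' @param t_inject Injection time (s).
#' @param params A [spectro_params()] (supplies `censor_min`).
#' @return A one-row tibble: `latency_min`, `censored`.
#' @export
first_seizure_latency <- function(seizures, t_inject, params = spectro_params()) {
  if (nrow(seizures) > 0 && any(seizures$start_s < t_inject)) {
    abort("seizure before injection: annotation/simulation inconsistency")
  }
  if (nrow(seizures) == 0) {
    return(tibble(latency_min = params$censor_min, censored = TRUE))
  }
  lat <- (min(seizures$start_s) - t_inject) / 60
  if (lat >= params$censor_min) {
    tibble(latency_min = params$censor_min, censored = TRUE)
  } else {
    tibble(latency_min = lat, censored = FALSE)
  }
}

#' Cumulative pathological activity
#'
#' Per time bin, sums the suprathreshold excess over frequencies — either
#' `Z - z_threshold` floored at 0 (`cumulate = "z_excess"`, the default,
#' keeping the curve in z-score units) or the raw binned power of
#' suprathreshold cells (`"power"`) — then accumulates over time. The curve
#' is monotone non-decreasing by construction and pointwise non-increasing
#' in the threshold.
#'
#' @inheritParams detect_pathological_events
#' @param method Overrides the params' `cumulate` choice.
#' @return A `clop_cumcurve` tibble (`time_s`, `rate`, `cumulative`) with a
#'   `total` attribute.
#' @export
cumulative_activity <- function(zmap, z_threshold = NULL, method = NULL) {
  thr <- z_threshold %||% zmap$params$z_threshold
  method <- method %||% zmap$params$cumulate
  rate <- if (method == "power") {
    if (is.null(zmap$power)) abort("map carries no raw power; use method = 'z_excess'")
    colSums(zmap$power * (zmap$z > thr))
  } else {
    colSums(pmax(zmap$z - thr, 0))
  }
  out <- tibble(time_s = zmap$times, rate = rate, cumulative = cumsum(rate))
  structure(out, class = c("clop_cumcurve", class(out)),
            total = sum(rate), method = method, z_threshold = thr)
}

#' End-to-end seizure quantification of one session
#'
#' Runs [zscore_spectrogram()], [detect_pathological_events()],
#' [classify_seizures()], [first_seizure_latency()] and
#' [cumulative_activity()] on a 4-AP-like session.
#'
#' @inheritParams zscore_spectrogram
#' @param t_inject Injection time (s); defaults to the session annotation.
#' @return A list of class `clop_seizure_report`: `zmap`, `events`,
#'   `seizures`, `latency`, `cumulative`.
#' @export
analyze_seizure_session <- function(lfp, t_inject = NULL,
                                    params = spectro_params()) {
  t_inject <- t_inject %||%
    lfp$annotations$onset_s[lfp$annotations$kind == "injection"][1]
  if (is.na(t_inject %||% NA)) abort("injection time required")
  zmap <- zscore_spectrogram(lfp, baseline_interval = c(0, t_inject),
                             params = params)
  events <- detect_pathological_events(zmap)
  seizures <- classify_seizures(events, lfp, params)
  structure(list(zmap = zmap, events = events, seizures = seizures,
                 latency = first_seizure_latency(seizures, t_inject, params),
                 cumulative = cumulative_activity(zmap)),
            class = "clop_seizure_report")
}
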