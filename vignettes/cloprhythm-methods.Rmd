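---
title: "Methods: models, estimators and design choices in cloprhythm"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: models, estimators and design choices in cloprhythm}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cloprhythm)
```

cloprhythm quantifies a daily rhythm of intracellular chloride in cortical
pyramidal neurons and its downstream physiology. This vignette documents the
models each stage assumes, the parameters that matter, what the synthetic
generators do and do not emulate, and the numerical choices made where the
design was genuinely open.

## 1. Sensor model

The biosensor couples a chloride/pH-sensitive green fluorophore
(E2GFP-derived) to a chloride- and pH-insensitive red reference, read out
at several two-photon excitation wavelengths (default
800/830/860/910/960 nm) through green and red emission channels. The
forward model for a cell of pH `p`, chloride `C` (mM) and brightness `b`:

* red(λ) = `b · S_red(λ)`
* green(λ) = `b · [S_acid(λ)·θ + S_base(λ)·(1−θ)] · q` with protonated
  fraction `θ = 1/(1 + 10^((p − pKa)/γ))` and static Stern–Volmer quench
  `q = 1/(1 + C/Kd(p))`, `Kd(p) = Kd_ref · 10^(kd_ph_slope·(pH_ref − p))`.

Inversion proceeds in two steps. pH comes from the green/green excitation
ratio `R = green(910)/green(830)` via the two-point titration formula
`p = pKa + γ·log10((R − R_A)/(R_B − R))`, where `R_A`, `R_B` are the acid
and base asymptotes derived from the spectra. Both the chloride quench and
the brightness cancel in a green/green ratio, so the pH estimate is
independent of both. Chloride then comes from the green/red ratio at the
pH-isosbestic excitation (860 nm, where acid and base forms are equally
excited): `C = Kd(p)·(R0 − R_Cl)/R_Cl`, floored at 0 mM.

**Calibration assumptions.** The constants (pKa 7.0, γ 1.0, Kd_ref 30 mM at
pH 7.0, kd_ph_slope 0.5 per pH unit, R_A 0.3, R_B 2.4, R0 1.8) are
stand-ins of realistic magnitude: in practice they come from ionophore
calibration experiments, and every value is a field of
`sensor_calibration()`. Correctness of the package is therefore defined by
round-trip recovery — inverting the forward model must return the inputs to
below 1e−9 relative error — not by any particular literature constant. The
default calibration sets `S_acid = S_base` at the pH-ratio denominator
wavelength (830 nm); for a two-state chromophore this is exactly the
condition under which the two-point formula above is exact with `pKa` the
ratio-titration midpoint. For calibrations that violate it, `pKa` must be
interpreted as the apparent midpoint of the measured ratio titration (the
quantity a calibration experiment actually fits).

Out-of-range cells — pH ratios at or beyond the titration asymptotes,
non-positive chloride ratios — are flagged and excluded from summaries,
never silently clipped; the single exception is the chloride floor at 0 mM
for ratios above R0 (flagged "below detection").

`nernst_potential()` uses CODATA constants with a default of 300 K and
125 mM extracellular chloride; at these values the day/night medians of
8.9 and 18.4 mM map to −68.3 and −49.5 mV. The 300 K default is the unique
temperature consistent with that triple and is exposed as an argument.

## 2. Imaging simulator and pipeline

`sim_imaging_field()` renders somata as soft-edged disks (logistic edge,
0.7 px scale) whose per-wavelength intensities come from the forward model;
per-cell pH is normal (default 7.15 ± 0.05), chloride log-normal
parameterized by its median — strictly positive and right-skewed, as
in-vivo chloride distributions are; within-animal log-SD defaults to 0.35,
giving interquartile ranges of a few mM at day-time medians and wider at
night, consistent with tighter day-time dispersions. Noise is Poisson
(photon shot noise, `poisson_gain` counts/photon) plus additive Gaussian
read noise on top of a uniform background offset. The generator does *not*
emulate motion, optical blur beyond the soft edge, depth-dependent
scattering, neuropil contamination, bleaching, or spatially varying
background — so passing recovery tests demonstrate correctness of the
estimator chain under the stated noise model, not robustness to every
artifact of real two-photon data.

Detection runs on the red channel summed over wavelengths, because the red
reference is independent of chloride and pH — detecting on green would bias
sampling toward low-quench (low-chloride) cells. The detector is
difference-of-Gaussians at the soma scale (σ = r/2 and r), local maxima
above `median + 8·MAD` of the DoG image, greedy non-overlap suppression by
descending peak value (minimum separation 1.5 r), and sub-pixel refinement
by parabolic interpolation. Ordering is deterministic (peak desc, y, x).

ROI intensities are disk means after per-page background subtraction. The
background level is a low percentile (default 10th) of the pixels outside
all dilated ROIs, *corrected* by `qnorm(0.9)·MAD` of those pixels: the raw
low percentile sits systematically below the true background under noise,
which inflates both channels additively and biases ratios toward 1 (and
recovered chloride upward); the MAD correction removes that bias while
keeping the estimator robust to bright contamination in the upper tail, and
reduces to the exact background on noise-free images. Edge ROIs average
in-bounds pixels only and are flagged; saturated ROIs are flagged.

Group statistics use the animal, not the cell, as the unit: animal medians
are computed first and all group-level statistics (including the
Mann–Whitney contrasts) operate on them. Duplicating every cell within an
animal provably leaves group summaries unchanged. `sim_cell_table()` adds a
between-animal log-normal spread of medians (default log-SD 0.18, chosen
once to resemble the spread of animal medians within a time point) for
group-power simulations. Paired pre/post-drug fields are matched by greedy
nearest-centroid assignment under a 3 px tolerance, ties broken by distance
then cell id.

## 3. Visually evoked gamma

Epoch spectra are single Hann periodograms of the 800 ms window from 200 ms
to 1 s after stimulus onset (1.25 Hz resolution), averaged across trials in
linear power, then smoothed with a modified Daniell kernel of span 2
(weights 1/8, 1/4, 1/4, 1/4, 1/8) before conversion to dB. The smoothing is
a standard periodogram-variance reduction: the trial-averaged single-segment
periodogram has a per-bin dB standard deviation of ≈ 10/(ln10·√n_trials)
(≈ 0.7 dB at 40 trials), which a max-over-band statistic would convert into
an upward bias of over 1 dB; the kernel reduces that roughly 2-fold while
remaining narrow enough (±2.5 Hz) not to attenuate band-limited peaks.
Baseline spectra use the same-length window inside the grey period that
follows each stimulus.

The aperiodic component is a least-squares line in (log10 f, dB) space
fitted over 8–20 and 80–110 Hz only — bands that flank the gamma range —
and extrapolated across the whole spectrum; an exact `1/f^a` power law is
recovered with exponent `10·a` dB/decade and zero residual. Gamma peak
prominence is the maximum of the residual spectrum within the search band
(default 20–40 Hz; the band is a parameter because the informative range
shifts by a few Hz between preparations), floored at 0. For single-bump
residuals this coincides with a peak-prominence measure on the residual
curve. Prominence is invariant under intensity rescaling and under adding
any affine-in-log10(f) component. The 50 Hz bin can be excluded from the
fit via the `exclude` argument when mains contamination is present.

The generator injects gamma as a multiplicative spectral bump on the
aperiodic background: within a flat-top band (default 8 Hz wide, Gaussian
shoulders of 1.5 Hz SD) centred on 28 Hz, the stimulus-epoch power spectral
density is raised by exactly `amplitude_db` dB. The flat top is wider than
the smoothing kernel support, so the injected height is the ground truth
the estimator should return; the bump height in dB — not a waveform
amplitude — is the controlled quantity. Trials are 2 s of stimulation
followed by 2 s of grey, with raised-cosine gating so the analysis window
sits in a stationary segment.

## 4. Epileptiform activity

The quantification follows the z-score-spectrogram procedure: a sliding
spectrogram (10 s bins, 1 s shift) restricted to 8–100 Hz with 49–51 Hz
omitted, normalized per frequency row to the baseline mean and SD
(`Z = (x − mean)/sd`), a 4 SD threshold applied to the per-bin maximum over
rows, maximal runs of suprathreshold bins as events, and seizures as events
lasting more than 15 s that are rhythmic.

Three estimator choices deserve note:

* **Within-bin averaging.** Each 10 s bin's spectrum is a Welch average of
  0.5 s Hann sub-windows (50% overlap) aggregated into 4 Hz rows. A single
  10 s periodogram at 0.1 Hz resolution would make each (bin, frequency)
  cell exponentially distributed, and "any of ~900 rows above 4 SD" would
  fire on essentially every baseline bin; the averaging brings the
  false-alarm rate of the 4 SD rule down to a few marginal events per hour
  (the residual rate is set by the chi-squared tail skew and is documented
  as the detector's operating characteristic; seizure calls are protected
  additionally by the duration and rhythmicity rules and are zero on pure
  baseline in the validation sweeps). The sub-window and row width are
  `spectro_params()` fields, calibrated once on the generator's baseline
  noise floor.
* **Exact mains notch.** In-notch power is removed by zeroing the 49–51 Hz
  band of the full-recording FFT before any windowed analysis. The 0.5 s
  sub-windows have a ±2 bin Hann main lobe that would otherwise leak strong
  mains into neighbouring rows and defeat the omission. Notch-overlapping
  rows are also dropped from the map.
* **Active-span deconvolution.** Overlapping bins smear a discharge of
  length L into ≈ (L + bin)/step marked bins; events therefore report
  `n·step − (bin − step)` as their duration (centred within the marked-bin
  envelope), which reduces to `n·step` when bin = step and prevents a 10 s
  discharge from being misclassified as a >15 s seizure. Onset estimates
  inherit ≤ bin-width accuracy.

The rhythmicity criterion quantifies "continual large-amplitude rhythmic
discharges": the dominant discharge frequency f0 is the 2–20 Hz peak of the
event's own spectrum (0.5 Hz resolution), and a bin is rhythmic when the
power within `min(0.75, 0.15·f0)` Hz of the harmonics `k·f0` — intersected
with the 8–100 Hz analysis range — holds at least 50% of the 8–100 Hz band
power. A seizure requires ≥70% rhythmic bins. Harmonics (rather than the
fundamental) carry the criterion because a discharge fundamental below 8 Hz
contributes no rows inside the analysis band; a flat-spectrum artifact
fails because the harmonic windows cover only ~25–35% of the band. All
thresholds are `spectro_params()` fields.

Latency to the first seizure is reported in minutes and censored at 60 min
(the observation horizon convention); a seizure annotated before the
injection raises an error rather than a negative latency. Cumulative
pathological activity sums, per bin, the suprathreshold z-excess
(`Z − 4`, floored at 0) over rows and accumulates over time; an alternative
`cumulate = "power"` switch integrates raw suprathreshold power instead.
The z-excess default keeps the curve in z-score units, matching how such
curves are axis-labelled; the curve is monotone by construction and
pointwise non-increasing in the threshold.

The 4-AP-like generator builds a urethane-like baseline (1/f² Gaussian
background gated by a two-state semi-Markov UP/DOWN envelope, ~1 Hz
alternation, gain 2), then after the injection time adds interictal bursts
(6 Hz with one harmonic, 2 s, rate ramping to 2/min, 15 s refractory) and
ground-truth seizures: amplitude-modulated 6 Hz discharges with 2nd and 3rd
harmonics, 2 s envelope ramps, amplitudes in realized-baseline-SD units,
followed by post-ictal suppression (background attenuated to 20% for 30 s).
It does not model electrode drift, movement artifacts, spike waveforms, or
seizure propagation/evolution in frequency.

## 5. Behavior

`sim_locomotion()` emulates 12:12 light/dark entrainment (lights on 7:00,
off 19:00): phase-specific mean displacement rates (defaults 5 cm/min light,
25 cm/min dark), a dark-onset surge (×2.5 for 60 min, the post-lights-off
activity peak), Poisson immobility bouts with exponential durations
(defaults: light 9 bouts/h × 300 s ≈ 53% immobile; dark 12/h × 60 s ≈ 18%),
and an optional extended-darkness override that keeps the lights off past
ZT24. Configured rates are *realized* rates: mobile-frame displacements
(gamma, shape 2) are rescaled by the stationary immobile fraction of the
bout process, so the expected dark/light contrast equals the configured
ratio regardless of immobility settings.

Actograms sum displacement into left-closed 10 min bins aligned to ZT0;
partial trailing bins are kept and flagged, and binned distances exactly
conserve the cumulative distance. Immobility counts only stillness
(speed < 0.1 cm/s) sustained for ≥ 40 s — both thresholds are declared
assumptions, exposed as arguments, since video-tracking immobility criteria
vary between laboratories.

`rank_tests()` wraps the group statistics used throughout: two-sided
Mann–Whitney (exact enumeration when n₁+n₂ ≤ 12 and tie-free — group sizes
in this kind of study are 4–11, where the normal approximation is poor —
tie-corrected normal approximation otherwise), Wilcoxon signed-rank with
zero differences dropped (all-zero differences return p = 1 with a flag),
and the paired t-test for behavioral contrasts. `densitometry_ratios()`
implements the immunoblot arithmetic
`(phospho-dimer + phospho-monomer)/(total dimer + total monomer)` and
total/tubulin loading normalization, with group means ± SEM and the percent
change between two groups.

## 6. Reproducibility and problem sizes

Every generator requires an explicit integer seed and uses a single PRNG
stream, so identical configurations are bit-identical; `run_pipeline()`
writes a manifest with a configuration hash. The validation suite and the
acceptance script run the LFP stages at 250–500 Hz sampling with all
simulated components below 110 Hz — the estimator chain is
sample-rate-agnostic above Nyquist, and these rates keep full validation
sweeps (hundreds of simulated sessions, including one-hour baselines)
comfortably fast; the config default remains 10 kHz, the acquisition rate
such recordings are digitized at. Imaging validation uses 200-cell
512 × 512 px fields; group-power simulations draw measurement tables
directly from the generator's chloride truth model rather than rendering
thousands of image fields, because detection and extraction are validated
separately on rendered fields.

## 7. Known limitations

* The sensor model is two-state + static quench; photophysics beyond that
  (lifetime effects, bleaching, dual-quencher interactions) is out of scope.
* Detection assumes roughly circular somata of a known scale; dendrites,
  overlapping cells and non-uniform illumination are not modelled, and the
  synthetic validation cannot speak to them.
* The event detector's 4 SD rule retains a small, quantified false-alarm
  rate at the event level on realistic spectral estimates; downstream
  quantities (seizure calls, latencies, cumulative activity) are designed to
  be robust to it.
* The gamma prominence estimator assumes a single band-limited peak over an
  affine-in-log-f background within the fitted range; multi-peak spectra
  would need the residual curve itself (`stimulus_power_change()`, the
  spectra tables) rather than the scalar summary.
* Group simulations model between-animal variability as a log-normal shift
  of medians; real inter-animal structure (phase differences of the daily
  cycle, strain effects) is richer.
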