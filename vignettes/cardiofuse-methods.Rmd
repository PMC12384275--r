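---
title: "Methods: multimodal HR/BR estimation and its synthetic test bed"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: multimodal HR/BR estimation and its synthetic test bed}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cardiofuse)
```

## The estimation problem

An arm-worn device samples five channels at 100 Hz — PPG at green, red and
infrared wavelengths, tetrapolar bioimpedance (BioZ), and a single-sided ECG
(SS-ECG) — alongside a 130 Hz chest reference ECG. Each cardiac signal
carries the heart rate directly and the breathing rate indirectly, through
three respiratory signatures:

* **BW** (baseline wander): respiration shifts the quasi-DC level; blood
  volume moves away from the periphery on inhale, so the PPG baseline falls
  while tissue impedance rises — opposite signs in PPG and BioZ. No BW is
  observable on the upper-arm ECG.
* **AM**: the pulse (PPG/BioZ) or R-wave (ECG) amplitude is modulated at the
  respiratory frequency.
* **FM** (respiratory sinus arrhythmia): the instantaneous heart rate rises
  on inhale and falls on exhale, modulating the inter-beat intervals (IBIs).

The pipeline estimates HR per modality per window, fuses the five estimates
hierarchically, extracts 14 per-channel BR estimates (BW from the four
pulsatile channels, AM and FM from all five) and fuses those with a
regression model, evaluated leave-one-subject-out (LOSO).

## The synthetic test bed

Real recordings of this kind are not generally shareable, so the package
treats a simulator as a first-class module: every downstream stage is
validated against known ground truth.

**What it emulates.** Beats are the integer level-crossings of the
integrated instantaneous rate $r(t) = \mathrm{HR} + d_{FM}\sin\phi(t)$,
where $\phi$ is the respiratory phase (piecewise-constant rate profiles are
supported so the paced task — one minute at 6 then one at 10 breaths/min —
is a single continuous recording whose trimmed 90 s span splits exactly at
the rate switch). Pulsatile channels render a fixed two-Gaussian
systolic/diastolic template per beat, *negative-going* (optical absorption
and tissue impedance both drop at systolic volume peaks — this sign is what
makes the envelope-subtract-and-invert preprocessing meaningful); ECG
channels render a five-Gaussian PQRST template, the single-sided channel at
0.4× chest amplitude. AM scales each beat's amplitude by
$1 + d_{AM}\sin\phi(t_k)$; BW adds $\mp b\sin\phi(t)$ (PPG −, BioZ +);
inhale is the rising half-cycle of $\sin\phi$. PPG AC amplitudes are
multiplied by a melanin attenuation factor linear in the Monk Skin Tone
value with per-wavelength slopes 0.075 (green) > 0.040 (red) > 0.022 (IR)
per MST step — only the *ordering* is physiologically established, so the
slopes are package constants chosen to give a strong green deficit
(factor ≈ 0.33 at MST 10) and a mild IR one. Noise is routed by mechanism:
white noise everywhere; 50 Hz powerline and Hann-windowed 20–45 Hz
band-limited EMG bursts on BioZ and SS-ECG only; smooth (0.3 s-sd Gaussian
bump) motion transients on all device channels; electrode pop-off as
saturation plateaus on SS-ECG, drawn per 15 s block with a configurable
probability. Everything is deterministic given the config seed.

**What it does not emulate.** Respiration is sinusoidal (an optional IBI
jitter parameter exists, but breath-to-breath variability is not modeled);
pulse morphology does not vary with posture or blood pressure; there is no
hemodynamic (Windkessel) realism, no SpO2 physiology, no arrhythmia, and
the chest reference is perfectly synchronous with the device. Passing tests
therefore demonstrate correctness of the *signal-processing chain* under
the stated signal model, not clinical performance on real recordings.

**Default study conditions.** A protocol of back-to-back two-minute tasks
(`study_task_spans()`); cohorts of 16 subjects with the study's skin-tone
composition (8 light, 4 medium, 4 dark), resting HR drawn from 60–95 bpm,
RSA depth 2–4 bpm, AM depth 0.10–0.25, BW 0.3–0.6 of the unit pulse
amplitude — values a physiologist would call typical for a healthy resting
adult, fixed once in `simulate_cohort()`.

## Preprocessing choices

* "Fifth-order zero-phase Butterworth" is read as the *design* order; the
  forward–backward application (`signal::filtfilt`) makes the effective
  magnitude order ten and the phase exactly zero.
* Detrending is linear least squares over the full task segment — the
  simplest reading; polynomial detrending is not needed because the 15 s
  trimmed at each task boundary also absorbs filter edge transients.
* The upper envelope joins local maxima at least 0.33 s apart (one peak per
  beat up to ~180 bpm) with a monotone Fritsch–Carlson cubic — shape
  preserving, so interpolation cannot manufacture oscillations that would
  alias into the respiratory band. Peak *heights* are refined with a
  three-point parabola: without this, sample-grid quantization of peak
  values (up to ~10⁻³ of the amplitude at 100 Hz) leaks into the
  respiratory band and would defeat the absence rule below. Ends are held
  at the nearest peak value; a signal with no local maxima gets its constant
  maximum as envelope.

## Estimator choices

* **Spectral HR/BR**: single Hann-windowed periodogram, zero-padded so the
  grid is finer than 0.1 bpm (HR) or 0.03 breaths/min (BR). Welch averaging
  is deliberately not the default: the windows are short (15 s / 45 s) and
  a single zero-padded periodogram keeps the estimator identical to its
  brute-force DFT oracle. Ties break toward the lower frequency, because
  harmonics sit above the fundamental. The band argmax must be a *local*
  spectral maximum; otherwise (e.g. a tone below the band whose leakage
  slope peaks at the band edge) the estimate is absent rather than a
  spurious edge value.
* **R-peak detection**: squared first difference, ~120 ms Gaussian
  smoothing, candidate peaks ≥ 250 ms apart above 25 % of the window's
  largest energy peak, refined to the AC maximum with sub-sample parabolic
  interpolation. The detector additionally refuses implausible trains —
  IBI robust dispersion above 15 % of the median (EMG bursts produce
  refractory-spaced spurious peaks) or a gap above 1.8× the median IBI
  (pop-off plateaus) — returning an empty train so the window's estimate
  is invalid. RSA keeps IBI dispersion below ~10 %, so clean windows are
  unaffected. This plausibility check is the package's own addition: with
  only the 40–120 bpm gate, a half-corrupted window can yield an in-range
  but wrong mean-IBI estimate, which would poison the fused output that
  the hierarchy routes through SS-ECG.
* **Gate bounds are inclusive**: "less than 40 and greater than 120"
  excludes only strict violations, so 40.0 and 120.0 are valid.
* **FM extraction** resamples the detrended IBI series at 4 Hz (standard
  HRV practice) with the same monotone interpolant, then smooths with a
  1 s-sd Gaussian kernel; envelope series use a 0.25 s-sd kernel. The BW
  text order is ambiguous about detrending; a linear detrend is applied
  before the PSD to suppress the 0 Hz bin.
* **Absence is a first-class value**: a slot is absent when the modulation
  series' standard deviation falls below 10⁻⁶ of the input scale
  (equivalently 10⁻¹² in relative band power; 10⁻⁴ of the mean IBI for
  FM), when fewer than 8 beats are found, or when no in-band local
  spectral peak exists. Fusion, not the extractors, decides what to do
  with absences.
* **Windows that do not fully fit are dropped** — consistent with the
  11-window count of a trimmed two-minute task; window starts are
  half-open sample slices (`[start, end)`, exactly 1500 samples at 100 Hz)
  on the device clock, with the 130 Hz reference sliced by time.

## Fusion choices

* Both named fusion models are implemented behind `br_fusion()`:
  the **bagged-tree ensemble** (136 bootstrap trees, minimum leaf 4, 13 of
  14 predictors sampled *per split* — the standard random-subspace reading
  of that hyperparameter) is the default for headline metrics and the
  importance analysis; the **robust linear** model is an in-package IRLS
  with Huber weights (k = 1.345), MAD-rescaled residuals each iteration,
  convergence tolerance 10⁻⁶ on the coefficient change, at most 50
  iterations (non-convergence returns the last iterate with a warning).
  On outlier-free data IRLS coincides with OLS to 10⁻⁶.
* Absent slots are imputed with the *training-set* median of the slot
  (stored in the fit, so prediction imputes identically): trees and IRLS
  both need complete rows, and absence correlates with noise.
* The inner 5-fold cross-validation on each LOSO training pool is a
  diagnostic only; it never alters the fit.
* Importance is **out-of-bag permutation** importance, clipped at zero and
  normalized — comparable across feature scales, unlike impurity-based
  importance; fold importances are averaged across LOSO fits.
* HR ground truth per window is the mean-IBI estimate from the chest
  reference over the same time span (the chest strap's role in practice).

## Problem sizes and determinism

The test suite and the acceptance script run on desk-scale cohorts chosen
to exercise every code path while staying quick: single subjects of 40–360 s
for unit tests; ten seeds for the corruption trade-off; a 16-subject
heterogeneous-noise cohort (paced task) for the LOSO evaluation; a
10-subject cohort where only BioZ carries baseline wander for the
importance analysis. All randomness is seeded; identical configs produce
bit-identical recordings, fits and reports.

## Known limitations

* The melanin slopes, noise amplitudes and modulation depths are package
  constants, not measured values; conclusions about *absolute* accuracy on
  real devices cannot be drawn from the synthetic cohorts.
* The spectral HR path assumes the pulse fundamental dominates its
  harmonics inside 0.67–2 Hz, which the pulse template guarantees by
  construction; unusually narrow real pulses could flip that ordering.
* The R-peak plausibility check intentionally sacrifices robustness (R1)
  for accuracy of the surviving estimates; applications that prefer
  coverage can relax `max_ibi_mad_frac` / `max_gap_factor`.
* With only two paced rates, the BR fusion target is nearly binary; the
  LOSO MAE on synthetic cohorts is therefore optimistic relative to
  free-breathing conditions.
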