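# Modality-specific preprocessing.
#
# Pulsatile channels (PPG, BioZ): linear detrend, zero-phase 5th-order
# Butterworth low-pass at 3 Hz (the AC + DC component), then upper-envelope
# subtraction and inversion (the AC component, systolic peaks as positive
# maxima). ECG channels: linear detrend + zero-phase 5th-order Butterworth
# band-pass (5-25 Hz single-sided, 0.5-30 Hz chest reference). "Fifth-order
# zero-phase" is read as the design order; forward-backward application makes
# the effective magnitude order ten.

#' Upper envelope of a signal
#'
#' Joins local maxima at least `min_peak_separation_s` apart with a
#' shape-preserving monotone cubic (Fritsch-Carlson) interpolant; outside the
#' first/last peak the envelope is held at the nearest peak value. Peak
#' heights are refined by a three-point parabola so that a constant-amplitude
#' oscillation yields an essentially exact constant envelope. With no local
#' maxima the envelope is the constant maximum of the signal.
#'
#' @param x Numeric vector (length >= 3).
#' @param min_peak_separation_s Minimum peak separation, seconds.
#' @param fs Sampling rate, Hz.
#' @return Numeric vector, same length as `x`, with `envelope >= x` at every
#'   detected peak.
#' @export
upper_envelope <- function(x, min_peak_separation_s = 0.33, fs = 100) {
  stopifnot(length(x) >= 3L, min_peak_separation_s > 0)
  pk <- find_peaks(x, min_sep = round(min_peak_separation_s * fs))
  if (length(pk$index) == 0L) return(rep(max(x), length(x)))
  if (length(pk$index) == 1L) return(rep(pk$height, length(x)))
  # knots at the integer peak indices with parabola-refined heights, so the
  # envelope passes through (and never undercuts) every detected peak
  f <- stats::splinefun(pk$index, pk$height, method = "monoH.FC")
  idx <- seq_along(x)
  f(pmin(pmax(idx, pk$index[1]), pk$index[length(pk$index)]))
}

lower_envelope <- function(x, min_peak_separation_s = 0.33, fs = 100) {
  -upper_envelope(-x, min_peak_separation_s, fs)
}

butter_filtfilt <- function(x, fs, type, cutoff_hz, order = 5L) {
  ny <- fs / 2
  w <- cutoff_hz / ny
  if (any(w <= 0) || any(w >= 1)) stop("cutoff outside (0, Nyquist)")
  b <- signal::butter(order, w, type = type)
  as.numeric(signal::filtfilt(b, x))
}

#' Preprocess a pulsatile channel (PPG or BioZ)
#'
#' @param raw Raw channel samples (>= 10 s worth).
#' @param fs Sampling rate, Hz.
#' @param lpf_cutoff_hz Low-pass cutoff, Hz.
#' @param butter_order Butterworth design order.
#' @param envelope_min_sep_s Envelope peak separation, seconds (0.33 s admits
#'   one peak per beat up to ~180 bpm).
#' @param modality Channel label carried through to the result.
#' @return An `cf_acdc` list: `ac` (pulsatile component, systolic peaks as
#'   positive maxima), `ac_dc` (detrended low-passed signal retaining the
#'   quasi-DC respiratory baseline), `fs`, `modality`.
#' @export
preprocess_pulsatile <- function(raw, fs, lpf_cutoff_hz = 3,
                                 butter_order = 5L,
                                 envelope_min_sep_s = 0.33,
                                 modality = "ppg") {
  if (length(raw) < 10 * fs)
    stop("pulsatile channel too short for stable filtering (need >= 10 s)")
  ac_dc <- butter_filtfilt(detrend_linear(raw), fs, "low", lpf_cutoff_hz,
                           butter_order)
  env <- upper_envelope(ac_dc, envelope_min_sep_s, fs)
  ac <- -(ac_dc - env)
  structure(list(ac = ac, ac_dc = ac_dc, fs = fs, modality = modality),
            class = "cf_acdc")
}

#' Preprocess an ECG channel (single-sided or chest reference)
#'
#' @param raw Raw ECG samples.
#' @param fs Sampling rate, Hz (native rate of the channel).
#' @param kind `"ssecg"` (5-25 Hz band) or `"ref"` (0.5-30 Hz band).
#' @param butter_order Butterworth design order.
#' @return An `cf_acdc` list with `ac` (band-passed, zero-mean) and `ac_dc`
#'   unset (`NULL`): ECG breathing features use AM and FM only.
#' @export
preprocess_ecg <- function(raw, fs, kind = c("ssecg", "ref"),
                           butter_order = 5L) {
  kind <- match.arg(kind)
  if (length(raw) < 10 * fs)
    stop("ECG channel too short for stable filtering (need >= 10 s)")
  band <- if (kind == "ssecg") c(5, 25) else c(0.5, 30)
  ac <- butter_filtfilt(detrend_linear(raw), fs, "pass", band, butter_order)
  structure(list(ac = ac, ac_dc = NULL, fs = fs, modality = kind),
            class = "cf_acdc")
}

#' Preprocess every channel of a recording
#'
#' Applies [preprocess_pulsatile()] to the PPG/BioZ channels and
#' [preprocess_ecg()] to SS-ECG and the chest reference.
#'
#' @param rec A `cf_recording`.
#' @return Named list of `cf_acdc` objects (`ppg_green`, `ppg_red`, `ppg_ir`,
#'   `bioz`, `ssecg`, `reference`).
#' @export
preprocess_recording <- function(rec) {
  stopifnot(inherits(rec, "cf_recording"))
  out <- list()
  for (m in PULSATILE_CHANNELS)
    out[[m]] <- preprocess_pulsatile(rec$channels[[m]], rec$device_fs,
                                     modality = m)
  out$ssecg <- preprocess_ecg(rec$channels$ssecg, rec$device_fs, "ssecg")
  out$reference <- preprocess_ecg(rec$ref_ecg, rec$ref_fs, "ref")
  out
}
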