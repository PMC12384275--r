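# Per-window heart-rate estimation and the skin-tone conditioned hierarchical
# fusion. ECG channels use the time domain (R-peak inter-beat intervals);
# pulsatile channels use the frequency domain (periodogram peak in the
# 0.67-2 Hz cardiac band). Estimates outside 40-120 bpm are discarded.

HR_BAND_HZ <- c(0.67, 2)
HR_GATE_BPM <- c(40, 120)

#' Detect R-peaks in a band-passed ECG
#'
#' Derivative-energy detector: the squared first difference is smoothed over
#' ~120 ms, candidate peaks at least 250 ms apart (the refractory period) are
#' kept when their energy exceeds an adaptive fraction of the window's peak
#' energy, and each detection is refined to the local maximum of the AC
#' signal with sub-sample parabolic interpolation.
#'
#' The detector reports a train only when it is physiologically plausible:
#' if the intervals are grossly irregular (robust dispersion above
#' `max_ibi_mad_frac` of the median, as under EMG bursts, where spurious
#' energy peaks recur at the refractory period) or contain a long beat-free
#' gap (above `max_gap_factor` times the median interval, as across an
#' electrode pop-off plateau), it returns an empty train and the window's
#' estimate becomes invalid.
#'
#' @param ac_ecg Band-passed ECG (from [preprocess_ecg()]).
#' @param fs Sampling rate, Hz.
#' @param refractory_s Minimum separation between peaks, seconds.
#' @param threshold_frac Energy threshold as a fraction of the largest
#'   smoothed energy peak in the window.
#' @param max_ibi_mad_frac Reject the train when `mad(ibi) / median(ibi)`
#'   exceeds this (respiratory sinus arrhythmia stays below ~0.1).
#' @param max_gap_factor Reject the train when the largest interval exceeds
#'   this multiple of the median interval.
#' @return Numeric vector of increasing peak times, seconds (possibly empty).
#' @export
detect_r_peaks <- function(ac_ecg, fs, refractory_s = 0.25,
                           threshold_frac = 0.25,
                           max_ibi_mad_frac = 0.15, max_gap_factor = 1.8) {
  n <- length(ac_ecg)
  if (n < 3L) return(numeric(0))
  e <- c(0, diff(ac_ecg))^2
  e <- smooth_gaussian(e, 0.04, fs)
  cand <- find_peaks(e, min_sep = round(refractory_s * fs), refine = FALSE)
  if (!length(cand$index)) return(numeric(0))
  thr <- threshold_frac * max(cand$height)
  keep <- cand$index[cand$height >= thr]
  if (!length(keep)) return(numeric(0))
  # refine to the local maximum of the AC signal near each energy peak
  half <- round(0.1 * fs)
  times <- vapply(keep, function(i) {
    lo <- max(1L, i - half); hi <- min(n, i + half)
    j <- lo + which.max(ac_ecg[lo:hi]) - 1L
    pos <- as.numeric(j)
    if (j > 1L && j < n) {
      a <- ac_ecg[j - 1L]; b <- ac_ecg[j]; c <- ac_ecg[j + 1L]
      den <- a - 2 * b + c
      if (abs(den) > .Machine$double.eps)
        pos <- j + max(min(0.5 * (a - c) / den, 0.5), -0.5)
    }
    (pos - 1) / fs
  }, numeric(1))
  times <- sort(unique(times))
  if (length(times) > 1L)
    times <- times[c(TRUE, diff(times) >= refractory_s / 2)]
  if (length(times) >= 3L) {
    ibi <- diff(times)
    m <- stats::median(ibi)
    if (stats::mad(ibi) > max_ibi_mad_frac * m ||
        max(ibi) > max_gap_factor * m)
      return(numeric(0))
  }
  times
}

#' Heart rate from R-peak times (mean inter-beat interval)
#'
#' @param peak_times Increasing peak times, seconds.
#' @return `60 / mean(diff(peak_times))` in beats/min, or `NA` with fewer
#'   than two peaks.
#' @export
hr_from_rpeaks <- function(peak_times) {
  if (length(peak_times) < 2L) return(NA_real_)
  60 / mean(diff(peak_times))
}

#' Heart rate from the spectral peak of a pulsatile AC component
#'
#' Hann-windowed, zero-padded periodogram (frequency grid finer than
#' 0.1 bpm); the maximum within 0.67-2 Hz is converted to beats/min. Ties
#' break toward the lower frequency, since harmonics sit above the
#' fundamental.
#'
#' @param ac Pulsatile AC component (from [preprocess_pulsatile()]).
#' @param fs Sampling rate, Hz.
#' @param band Cardiac search band, Hz.
#' @return Heart rate in beats/min, or `NA` when the band holds no power
#'   (e.g. constant input).
#' @export
hr_from_spectrum <- function(ac, fs, band = HR_BAND_HZ) {
  p <- psd_band_peak(ac, fs, band, df_max = 0.1 / 60)
  if (is.na(p$peak_hz) || p$band_power <= 0 || !p$is_local_max)
    return(NA_real_)
  60 * p$peak_hz
}

#' Physiological validity gate for HR estimates
#'
#' @param hr_bpm Estimate in beats/min (or `NA`).
#' @param gate Inclusive bounds, beats/min.
#' @return `TRUE` iff the estimate is present and inside `[40, 120]`.
#' @export
gate_hr <- function(hr_bpm, gate = HR_GATE_BPM) {
  !is.na(hr_bpm) & hr_bpm >= gate[1] & hr_bpm <= gate[2]
}

#' Skin-tone category from the Monk Skin Tone value
#'
#' @param mst Integer 1-10.
#' @return `"light"` (MST 1-3), `"medium"` (4-6) or `"dark"` (7-10).
#' @export
mst_to_category <- function(mst) {
  if (!(is.numeric(mst) && length(mst) == 1L && mst %in% 1:10))
    stop("mst must be an integer in 1..10")
  if (mst <= 3) "light" else if (mst <= 6) "medium" else "dark"
}

#' Hierarchical skin-tone conditioned HR fusion for one window
#'
#' SS-ECG wins whenever valid (time-domain IBIs are the most direct cardiac
#' measurement); otherwise the first valid estimate in the skin-tone ordered
#' fallback list is used: dark skin tones prefer PPG-IR, then BioZ, then
#' PPG-green (melanin absorbs green most); light/medium prefer PPG-green,
#' then PPG-IR, then BioZ. PPG-red never enters the hierarchy.
#'
#' @param estimates Named numeric vector of gated per-modality estimates in
#'   beats/min (`NA` where invalid); names among `ssecg`, `ppg_green`,
#'   `ppg_ir`, `ppg_red`, `bioz`.
#' @param category Skin-tone category (`"light"`, `"medium"`, `"dark"`).
#' @return List with `hr_bpm` (`NA` if no modality is valid) and `source`
#'   (modality name or `NA`).
#' @export
hierarchical_hr <- function(estimates, category = c("light", "medium", "dark")) {
  category <- match.arg(category)
  fallback <- if (category == "dark") c("ppg_ir", "bioz", "ppg_green")
              else c("ppg_green", "ppg_ir", "bioz")
  for (m in c("ssecg", fallback)) {
    v <- estimates[[m]]
    if (!is.null(v) && !is.na(v) && gate_hr(v))
      return(list(hr_bpm = v, source = m))
  }
  list(hr_bpm = NA_real_, source = NA_character_)
}

hr_precedence <- function(category) {
  c("ssecg", if (category == "dark") c("ppg_ir", "bioz", "ppg_green")
             else c("ppg_green", "ppg_ir", "bioz"))
}

#' Windowed multimodal HR estimation for a recording
#'
#' Preprocesses every channel, trims each selected task span, slides 15 s /
#' 50%-overlap windows and produces the five per-modality estimates (spectral
#' for PPG/BioZ, IBI for SS-ECG), the reference-channel IBI estimate, the
#' validity gates and the hierarchically fused value per window.
#'
#' @param rec A `cf_recording`.
#' @param tasks Task names to analyse (default: every task span).
#' @param trim_s,win_s,overlap Segmentation parameters.
#' @param prep Optional precomputed [preprocess_recording()] output.
#' @return data.frame of class `cf_hr_estimates`, one row per
#'   (task, window, modality) plus `fused` and `reference` rows; columns
#'   `task`, `window_index`, `start_s`, `modality`, `method`, `hr_bpm`,
#'   `valid`, `fused_source`.
#' @export
estimate_hr <- function(rec, tasks = NULL, trim_s = 15, win_s = 15,
                        overlap = 0.5, prep = NULL) {
  stopifnot(inherits(rec, "cf_recording"))
  if (is.null(prep)) prep <- preprocess_recording(rec)
  spans <- rec$task_spans
  if (!is.null(tasks)) spans <- spans[spans$task %in% tasks, , drop = FALSE]
  category <- rec$meta$category
  rows <- list()
  for (i in seq_len(nrow(spans))) {
    usable <- trim_task(spans$start_s[i], spans$end_s[i], trim_s)
    wins <- hr_windows(usable[1], usable[2], win_s, overlap)
    for (w in seq_len(nrow(wins))) {
      est <- c(ppg_green = NA_real_, ppg_red = NA_real_, ppg_ir = NA_real_,
               bioz = NA_real_, ssecg = NA_real_)
      for (m in PULSATILE_CHANNELS) {
        ac <- slice_window(prep[[m]]$ac, rec$device_fs,
                           wins$start_s[w], wins$end_s[w])
        est[[m]] <- hr_from_spectrum(ac, rec$device_fs)
      }
      ac_ss <- slice_window(prep$ssecg$ac, rec$device_fs,
                            wins$start_s[w], wins$end_s[w])
      est[["ssecg"]] <- hr_from_rpeaks(detect_r_peaks(ac_ss, rec$device_fs))
      ac_ref <- slice_window(prep$reference$ac, rec$ref_fs,
                             wins$start_s[w], wins$end_s[w])
      hr_ref <- hr_from_rpeaks(detect_r_peaks(ac_ref, rec$ref_fs))
      gated <- ifelse(gate_hr(est), est, NA_real_)
      fused <- hierarchical_hr(as.list(gated), category)
      mods <- names(est)
      rows[[length(rows) + 1L]] <- data.frame(
        task = spans$task[i], window_index = wins$index[w],
        start_s = wins$start_s[w],
        modality = c(mods, "reference", "fused"),
        method = c(ifelse(mods == "ssecg", "ibi", "spectral"), "ibi", "fusion"),
        hr_bpm = c(unname(est), hr_ref, fused$hr_bpm),
        valid = c(unname(gate_hr(est)), gate_hr(hr_ref), gate_hr(fused$hr_bpm)),
        fused_source = c(rep(NA_character_, length(mods) + 1L), fused$source))
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  attr(out, "category") <- category
  attr(out, "subject_id") <- rec$meta$subject_id
  class(out) <- c("cf_hr_estimates", "data.frame")
  out
}
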