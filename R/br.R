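# Breathing-rate extraction: fourteen per-window estimates from the three
# respiratory signatures - baseline wander (BW; PPG/BioZ only, none exists on
# the upper-arm ECG), amplitude modulation (AM; all five channels) and
# frequency modulation / respiratory sinus arrhythmia (FM; all five). Each
# extractor reduces its channel to a respiratory modulation series and takes
# the Hann periodogram peak in the 0.05-0.5 Hz (3-30 breaths/min) band.

BR_BAND_HZ <- c(0.05, 0.5)

# A modulation series counts as flat (slot absent) when its post-processing
# sd falls below `tol` times a reference scale; 1e-6 in amplitude equals the
# 1e-12 relative band-power floor. Parabolic peak-height refinement in the
# envelope extractor is what pushes constant-amplitude inputs under this
# floor despite sample-grid quantisation.
br_peak_or_na <- function(m, fs, ref_scale, tol = 1e-6, band = BR_BAND_HZ) {
  if (!is.finite(ref_scale) || ref_scale <= 0) return(NA_real_)
  if (stats::sd(m) <= tol * ref_scale) return(NA_real_)
  p <- psd_band_peak(m, fs, band, df_max = 5e-4)
  if (is.na(p$peak_hz) || !p$is_local_max ||
      p$band_power <= 1e-12 * p$total_power)
    return(NA_real_)
  60 * p$peak_hz
}

#' Breathing rate from baseline wander
#'
#' Averages the upper and lower envelopes of the AC + DC component
#' (pointwise arithmetic mean), smooths with a Gaussian kernel, removes the
#' linear trend, and takes the respiratory-band periodogram peak. Only
#' pulsatile channels carry baseline wander; SS-ECG input is rejected.
#'
#' @param ac_dc AC + DC component from [preprocess_pulsatile()] (a 45 s
#'   window).
#' @param fs Sampling rate, Hz.
#' @param modality Channel label (`"ssecg"` is rejected).
#' @param env_sep_s Envelope peak separation, seconds.
#' @param smooth_sd_s Gaussian smoothing sd, seconds.
#' @return Breathing rate, breaths/min, or `NA` when no respiratory baseline
#'   is present.
#' @export
br_from_bw <- function(ac_dc, fs, modality = "ppg", env_sep_s = 0.33,
                       smooth_sd_s = 0.25) {
  if (identical(modality, "ssecg"))
    stop("baseline wander is not defined for SS-ECG")
  if (is.null(ac_dc)) return(NA_real_)
  up <- upper_envelope(ac_dc, env_sep_s, fs)
  lo <- lower_envelope(ac_dc, env_sep_s, fs)
  m <- smooth_gaussian((up + lo) / 2, smooth_sd_s, fs)
  m <- detrend_linear(m)
  br_peak_or_na(m, fs, ref_scale = stats::sd(ac_dc))
}

#' Breathing rate from amplitude modulation
#'
#' Upper envelope of the AC component, linear detrend, Gaussian smoothing,
#' respiratory-band periodogram peak.
#'
#' @param ac AC component (45 s window).
#' @inheritParams br_from_bw
#' @return Breathing rate, breaths/min, or `NA` for a flat envelope.
#' @export
br_from_am <- function(ac, fs, env_sep_s = 0.33, smooth_sd_s = 0.25) {
  up <- upper_envelope(ac, env_sep_s, fs)
  m <- smooth_gaussian(detrend_linear(up), smooth_sd_s, fs)
  br_peak_or_na(m, fs, ref_scale = stats::sd(ac))
}

# Systolic peak times on a pulsatile AC component: positive maxima at least
# 0.33 s apart, above 30% of the tallest, parabolic sub-sample refinement.
systolic_peak_times <- function(ac, fs, min_sep_s = 0.33,
                                threshold_frac = 0.3) {
  pk <- find_peaks(ac, min_sep = round(min_sep_s * fs))
  if (!length(pk$index)) return(numeric(0))
  keep <- pk$height >= threshold_frac * max(pk$height)
  (pk$pos[keep] - 1) / fs
}

#' Breathing rate from frequency modulation (respiratory sinus arrhythmia)
#'
#' Builds the inter-beat-interval series (R-peaks for ECG channels, systolic
#' peaks for PPG/BioZ), removes the linear trend, resamples it uniformly at
#' 4 Hz with a monotone shape-preserving interpolant (no overshoot-created
#' spectral peaks), smooths with a Gaussian kernel, and takes the
#' respiratory-band periodogram peak.
#'
#' @param ac AC component (45 s window).
#' @param fs Sampling rate, Hz.
#' @param modality Channel label; `"ssecg"`/`"ref"` use the R-peak detector.
#' @param resample_hz Uniform resampling rate of the IBI series, Hz.
#' @param smooth_sd_s Gaussian smoothing sd on the resampled series, seconds.
#' @param min_beats Minimum number of beats required.
#' @return Breathing rate, breaths/min, or `NA` (too few beats or constant
#'   intervals).
#' @export
br_from_fm <- function(ac, fs, modality = "ppg", resample_hz = 4,
                       smooth_sd_s = 1.0, min_beats = 8L) {
  beats <- if (modality %in% c("ssecg", "ref")) detect_r_peaks(ac, fs)
           else systolic_peak_times(ac, fs)
  if (length(beats) < min_beats) return(NA_real_)
  ibi <- diff(beats)
  t_ibi <- beats[-1]
  ib_d <- detrend_linear(ibi)
  f <- stats::splinefun(t_ibi, ib_d, method = "monoH.FC")
  tg <- seq(t_ibi[1], t_ibi[length(t_ibi)], by = 1 / resample_hz)
  if (length(tg) < 8L) return(NA_real_)
  m <- smooth_gaussian(f(tg), smooth_sd_s, resample_hz)
  br_peak_or_na(m, resample_hz, ref_scale = mean(ibi), tol = 1e-4)
}

#' Fourteen-channel breathing-rate feature vector for one window
#'
#' BW from the four pulsatile channels plus AM and FM from all five channels.
#' Missing channels leave their slots `NA` (with a warning); the slot count
#' is always fourteen and SS-ECG never has a BW slot.
#'
#' @param prep Named list of `cf_acdc` windows (elements `ppg_green`,
#'   `ppg_red`, `ppg_ir`, `bioz`, `ssecg`; each already sliced to the
#'   analysis window).
#' @param fs Sampling rate, Hz.
#' @return Named numeric vector with the 14 slots
#'   (`bw_*` x 4, `am_*` x 5, `fm_*` x 5).
#' @export
br_features <- function(prep, fs) {
  out <- stats::setNames(rep(NA_real_, length(BR_SLOTS)), BR_SLOTS)
  for (m in PULSATILE_CHANNELS) {
    ch <- prep[[m]]
    if (is.null(ch)) { warning("missing channel: ", m); next }
    out[[paste0("bw_", m)]] <- br_from_bw(ch$ac_dc, fs, modality = m)
    out[[paste0("am_", m)]] <- br_from_am(ch$ac, fs)
    out[[paste0("fm_", m)]] <- br_from_fm(ch$ac, fs, modality = m)
  }
  if (is.null(prep$ssecg)) {
    warning("missing channel: ssecg")
  } else {
    out[["am_ssecg"]] <- br_from_am(prep$ssecg$ac, fs)
    out[["fm_ssecg"]] <- br_from_fm(prep$ssecg$ac, fs, modality = "ssecg")
  }
  out
}

#' Windowed breathing-rate features for a recording
#'
#' Trims the paced-breathing task span and splits it into two 45 s windows
#' (one per paced rate), then fills the 14-slot feature vector for each.
#'
#' @param rec A `cf_recording`.
#' @param task Name of the paced-breathing task span; defaults to the only
#'   span, or the one named `"paced_breathing"` when several exist.
#' @param trim_s Seconds trimmed from each task end.
#' @param labels Nominal paced rates for the two windows; taken from the
#'   simulation's breathing-rate profile when available.
#' @param prep Optional precomputed [preprocess_recording()] output.
#' @return data.frame of class `cf_br_features`: one row per window with
#'   `window_index`, `start_s`, the 14 slot columns (breaths/min) and
#'   `truth_brpm`.
#' @export
estimate_br <- function(rec, task = NULL, trim_s = 15, labels = NULL,
                        prep = NULL) {
  stopifnot(inherits(rec, "cf_recording"))
  spans <- rec$task_spans
  if (is.null(task) && nrow(spans) > 1L && "paced_breathing" %in% spans$task)
    task <- "paced_breathing"
  if (!is.null(task)) spans <- spans[spans$task == task, , drop = FALSE]
  if (nrow(spans) != 1L) stop("need exactly one paced-breathing task span")
  if (is.null(prep)) prep <- preprocess_recording(rec)
  usable <- trim_task(spans$start_s, spans$end_s, trim_s)
  if (is.null(labels)) {
    prof <- br_profile(rec$config$br_brpm)
    mids <- usable[1] + (usable[2] - usable[1]) * c(0.25, 0.75)
    labels <- prof$brpm[pmax(1L, findInterval(mids, prof$start_s))]
  }
  wins <- br_windows(usable[1], usable[2], labels = labels)
  rows <- lapply(seq_len(nrow(wins)), function(w) {
    sl <- lapply(prep[DEVICE_CHANNELS], function(ch) {
      out <- ch
      out$ac <- slice_window(ch$ac, rec$device_fs, wins$start_s[w],
                             wins$end_s[w])
      if (!is.null(ch$ac_dc))
        out$ac_dc <- slice_window(ch$ac_dc, rec$device_fs, wins$start_s[w],
                                  wins$end_s[w])
      out
    })
    fv <- br_features(sl, rec$device_fs)
    cbind(data.frame(window_index = wins$index[w], start_s = wins$start_s[w]),
          as.data.frame(as.list(fv)),
          data.frame(truth_brpm = wins$br_label[w]))
  })
  out <- do.call(rbind, rows)
  attr(out, "subject_id") <- rec$meta$subject_id
  class(out) <- c("cf_br_features", "data.frame")
  out
}
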