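# Independent oracles used to cross-check the spectral estimators, plus
# small fixture builders. The DFT oracle evaluates the transform by direct
# summation on the same Hann-windowed zero-padded grid as the estimators, so
# agreement checks the whole estimator path against an implementation that
# shares no code with it.

# Direct-summation DFT band argmax (no fft): returns the peak frequency in
# `band` on the grid k * fs / nfft, ties toward the lower frequency.
oracle_dft_band_peak <- function(x, fs, band, df_max = fs / 2^16) {
  n <- length(x)
  x <- x - mean(x)
  w <- 0.5 - 0.5 * cos(2 * pi * seq(0, n - 1) / (n - 1))
  xw <- x * w
  nfft <- 2^ceiling(log2(max(n, ceiling(fs / df_max))))
  ks <- which((0:(nfft %/% 2)) * fs / nfft >= band[1] &
              (0:(nfft %/% 2)) * fs / nfft <= band[2]) - 1L
  t_idx <- seq(0, n - 1)
  power <- vapply(ks, function(k) {
    ang <- -2 * pi * k * t_idx / nfft
    Re(sum(xw * cos(ang)))^2 + Re(sum(xw * sin(ang)))^2
  }, numeric(1))
  if (!length(ks) || max(power) <= 0) return(NA_real_)
  ks[which.max(power)] * fs / nfft
}

# Brute-force periodogram peak of an inter-beat-interval sequence resampled
# at `fs_r` by linear interpolation (independent of the package's monotone
# resampling path).
oracle_ibi_peak_freq <- function(beat_times, fs_r = 4, band = c(0.05, 0.5)) {
  ibi <- diff(beat_times)
  tt <- beat_times[-1]
  tg <- seq(tt[1], tt[length(tt)], by = 1 / fs_r)
  y <- stats::approx(tt, ibi, xout = tg)$y
  oracle_dft_band_peak(y - mean(y), fs_r, band, df_max = 5e-4)
}

# Clean single-task recording fixture (no noise) for detector tests.
clean_recording <- function(hr_bpm = 75, br_brpm = 12, fm = 2, am = 0.15,
                            bw = 0.4, mst = 2, duration_s = 60, seed = 11) {
  cfg <- sim_config(duration_s = duration_s, hr_bpm = hr_bpm,
                    br_brpm = br_brpm, fm_depth_bpm = fm, am_depth = am,
                    bw_depth = bw, mst = mst, seed = seed)
  simulate_recording(cfg)
}

# Paced-breathing-only subject (75 s span -> one trimmed 45 s window) at a
# single breathing rate; returns the preprocessed 45 s channel slices.
paced_window_slices <- function(br_brpm, hr_bpm = 75, fm = 3, am = 0.15,
                                bw = 0.5, noise = noise_config(), seed = 5) {
  cfg <- sim_config(duration_s = 75, hr_bpm = hr_bpm, br_brpm = br_brpm,
                    fm_depth_bpm = fm, am_depth = am, bw_depth = bw, mst = 2,
                    noise = noise, seed = seed)
  rec <- simulate_recording(cfg)
  prep <- preprocess_recording(rec)
  lapply(prep[c("ppg_green", "ppg_red", "ppg_ir", "bioz", "ssecg")],
         function(ch) {
           ch$ac <- ch$ac[(15 * rec$device_fs + 1):(60 * rec$device_fs)]
           if (!is.null(ch$ac_dc))
             ch$ac_dc <- ch$ac_dc[(15 * rec$device_fs + 1):(60 * rec$device_fs)]
           ch
         })
}
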