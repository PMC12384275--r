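# Heart-rate estimation: R-peak detection, IBI and spectral estimators,
# the 40-120 bpm gate and the skin-tone conditioned hierarchical fusion.

test_that("R-peak detection recovers clean simulated beats exactly", {
  rec <- clean_recording(hr_bpm = 75, duration_s = 60, seed = 41)
  p <- preprocess_ecg(rec$channels$ssecg, rec$device_fs, "ssecg")
  pk <- detect_r_peaks(p$ac[1501:4500], rec$device_fs)  # 15-45 s slice
  truth <- rec$beat_times[rec$beat_times >= 15 & rec$beat_times < 45] - 15
  expect_equal(length(pk), length(truth))
  expect_lt(max(abs(pk - truth)), 0.02)
  expect_identical(detect_r_peaks(numeric(1500), 100), numeric(0))
})

test_that("saturated windows yield no valid time-domain estimate", {
  cfg <- sim_config(duration_s = 45, hr_bpm = 75, br_brpm = 12, mst = 2,
                    noise = noise_config(popoff_prob = 1, popoff_block_s = 45),
                    seed = 13)
  rec <- simulate_recording(cfg)
  p <- preprocess_ecg(rec$channels$ssecg, rec$device_fs, "ssecg")
  hr <- hr_from_rpeaks(detect_r_peaks(p$ac[1001:2500], rec$device_fs))
  expect_false(gate_hr(hr))
})

test_that("mean-IBI heart rate follows the arithmetic", {
  expect_equal(hr_from_rpeaks(0:10), 60)
  expect_equal(hr_from_rpeaks(c(0, 0.8, 1.6, 2.4)), 75)
  expect_equal(hr_from_rpeaks(c(0, 0.75, 1.6)), 75)  # IBIs 0.75, 0.85
  expect_true(is.na(hr_from_rpeaks(1.2)))
})

test_that("spectral HR matches single tones and gates out-of-band content", {
  fs <- 100
  t <- seq(0, 15 - 1 / fs, by = 1 / fs)
  expect_equal(hr_from_spectrum(sin(2 * pi * 1.25 * t), fs), 75,
               tolerance = 0.1 / 75)
  # an out-of-band tone has no genuine in-band peak, only a leakage slope
  expect_true(is.na(hr_from_spectrum(sin(2 * pi * 0.5 * t), fs)))
  expect_true(is.na(hr_from_spectrum(rep(1, 1500), fs)))
})

test_that("spectral HR equals the brute-force DFT oracle and prefers the fundamental", {
  fs <- 100
  rec <- clean_recording(hr_bpm = 60, fm = 0, am = 0, bw = 0, duration_s = 60,
                         seed = 51)
  p <- preprocess_pulsatile(rec$channels$ppg_green, fs)
  for (start in c(15, 30)) {
    ac <- p$ac[(start * fs + 1):((start + 15) * fs)]
    est <- hr_from_spectrum(ac, fs)
    expect_equal(est, 60, tolerance = 0.5 / 60)
    oracle <- 60 * oracle_dft_band_peak(ac, fs, c(0.67, 2), df_max = 0.1 / 60)
    expect_equal(est, oracle, tolerance = 1e-12)
  }
  # oracle equivalence on assorted non-cardiac fixtures too
  t <- seq(0, 15 - 1 / fs, by = 1 / fs)
  fixtures <- list(sin(2 * pi * 1.7 * t) + 0.5 * sin(2 * pi * 0.9 * t),
                   pmax(sin(2 * pi * 1.1 * t), 0)^3,
                   sin(2 * pi * 0.8 * t) * (1 + 0.3 * sin(2 * pi * 0.15 * t)))
  for (x in fixtures)
    expect_equal(hr_from_spectrum(x, fs),
                 60 * oracle_dft_band_peak(x, fs, c(0.67, 2), df_max = 0.1 / 60),
                 tolerance = 1e-12)
})

test_that("the validity gate is inclusive at 40 and 120 bpm", {
  expect_false(gate_hr(39.9))
  expect_true(gate_hr(40))
  expect_true(gate_hr(75))
  expect_true(gate_hr(120))
  expect_false(gate_hr(120.1))
  expect_false(gate_hr(NA_real_))
})

test_that("Monk Skin Tone maps to the three categories", {
  expect_equal(mst_to_category(1), "light")
  expect_equal(mst_to_category(3), "light")
  expect_equal(mst_to_category(4), "medium")
  expect_equal(mst_to_category(6), "medium")
  expect_equal(mst_to_category(7), "dark")
  expect_equal(mst_to_category(10), "dark")
  expect_error(mst_to_category(0), "mst")
  expect_error(mst_to_category(11), "mst")
})

test_that("hierarchical fusion follows SS-ECG-first then skin-tone precedence", {
  all_valid <- list(ssecg = 72, ppg_green = 90, ppg_ir = 80, bioz = 85,
                    ppg_red = 70)
  f <- hierarchical_hr(all_valid, "dark")
  expect_equal(f$hr_bpm, 72); expect_equal(f$source, "ssecg")
  no_ss <- list(ssecg = NA, ppg_green = 90, ppg_ir = 80, bioz = 85)
  f <- hierarchical_hr(no_ss, "dark")
  expect_equal(f$hr_bpm, 80); expect_equal(f$source, "ppg_ir")
  f <- hierarchical_hr(list(ssecg = NA, ppg_green = NA, ppg_ir = 77,
                            bioz = 70), "light")
  expect_equal(f$hr_bpm, 77); expect_equal(f$source, "ppg_ir")
  f <- hierarchical_hr(list(ssecg = NA, ppg_green = 90, ppg_ir = 80,
                            bioz = 85), "medium")
  expect_equal(f$source, "ppg_green")
  f <- hierarchical_hr(list(ssecg = NA, ppg_green = NA, ppg_ir = NA,
                            bioz = NA), "light")
  expect_true(is.na(f$hr_bpm))
  # out-of-gate entries are never selected; red never enters the hierarchy
  f <- hierarchical_hr(list(ssecg = 130, ppg_green = 39, ppg_ir = NA,
                            bioz = NA, ppg_red = 75), "light")
  expect_true(is.na(f$hr_bpm))
})

test_that("clean simulations validate all modalities and fuse to SS-ECG", {
  rec <- clean_recording(hr_bpm = 68, duration_s = 90, seed = 61)
  hr <- estimate_hr(rec)
  wide <- split(hr, hr$modality)
  for (m in c("ppg_green", "ppg_red", "ppg_ir", "bioz", "ssecg"))
    expect_true(all(wide[[m]]$valid))
  expect_equal(wide$fused$hr_bpm, wide$ssecg$hr_bpm)
  expect_true(all(wide$fused$fused_source == "ssecg"))
  # every fused value respects the gate
  expect_true(all(wide$fused$hr_bpm >= 40 & wide$fused$hr_bpm <= 120))
  # reference channel tracks simulated truth within half a beat per minute
  expect_lt(max(abs(wide$reference$hr_bpm - 68)), 0.5)
})
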