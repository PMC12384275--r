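# Simulator: beat generation, waveform rendering, modulation encoding,
# noise routing, determinism.

test_that("constant-rate beat trains have exact spacing and count", {
  b <- generate_beat_times(60, 0, 12, 10)
  expect_equal(diff(b), rep(1, 10))
  b <- generate_beat_times(75, 0, 12, 60)
  expect_length(diff(b), 75)
  expect_equal(diff(b), rep(0.8, 75), tolerance = 1e-12)
})

test_that("beat counts stay within one of hr * T / 60 without RSA", {
  for (hr in c(41, 55, 75.3, 98, 119)) {
    b <- generate_beat_times(hr, 0, 12, 137)
    expect_lte(abs(length(b) - 1 - hr * 137 / 60), 1)
  }
})

test_that("RSA modulates the inter-beat intervals at the breathing frequency", {
  b <- generate_beat_times(75, 3, 6, 300)
  f <- oracle_ibi_peak_freq(b)
  expect_equal(f, 0.1, tolerance = 0.005)
  # rate conservation still holds approximately under FM
  expect_lte(abs(length(b) - 1 - 75 * 300 / 60), 2)
})

test_that("beat generation rejects out-of-range parameters", {
  expect_error(generate_beat_times(60, 60, 12, 10), "fm_depth")
  expect_error(generate_beat_times(NaN, 0, 12, 10), "hr_bpm")
  expect_error(generate_beat_times(60, 0, 12, -1), "duration_s")
})

test_that("clean pulsatile render is periodic and melanin ordering holds", {
  b <- generate_beat_times(60, 0, 12, 20)
  x <- render_pulsatile(b, "ppg_green", am_depth = 0, bw_depth = 0, fs = 100,
                        duration_s = 20)
  # period 1 s at fs 100: interior samples repeat beat-to-beat
  expect_equal(x[501:600], x[601:700], tolerance = 1e-9)
  amp <- function(mod, mst) {
    y <- render_pulsatile(b, mod, mst = mst, fs = 100, duration_s = 20)
    max(y) - min(y)
  }
  g_ratio <- amp("ppg_green", 9) / amp("ppg_green", 2)
  ir_ratio <- amp("ppg_ir", 9) / amp("ppg_ir", 2)
  expect_lt(g_ratio, 1)
  expect_gt(ir_ratio, g_ratio)  # IR attenuated less than green
  expect_error(render_pulsatile(b, "ppg_uv"), "unknown")
})

test_that("baseline wander is at the breathing frequency with opposite signs in PPG and BioZ", {
  b <- generate_beat_times(72, 0, 6, 60)
  ppg <- render_pulsatile(b, "ppg_ir", bw_depth = 0.5, br_brpm = 6,
                          fs = 100, duration_s = 60)
  bioz <- render_pulsatile(b, "bioz", bw_depth = 0.5, br_brpm = 6,
                           fs = 100, duration_s = 60)
  lp <- function(x) {
    bf <- signal::butter(4, 0.5 / 50, type = "low")
    as.numeric(signal::filtfilt(bf, x - mean(x)))
  }
  bl_p <- lp(ppg); bl_b <- lp(bioz)
  expect_equal(oracle_dft_band_peak(bl_p, 100, c(0.05, 0.5), df_max = 2e-3),
               0.1, tolerance = 0.01)
  expect_lt(stats::cor(bl_p, bl_b), -0.95)  # anti-phase baselines
})

test_that("ECG render centres R-peaks on beats and encodes AM", {
  b <- generate_beat_times(75, 0, 10, 60)
  x <- render_ecg(b, am_depth = 0, fs = 100, kind = "ref", duration_s = 60)
  # all R amplitudes equal without AM
  ramp <- vapply(b[2:50], function(tb) max(x[round(tb * 100) + (-3:3) + 1L]),
                 numeric(1))
  expect_lt(diff(range(ramp)), 1e-6)
  # argmax near each beat within one sample
  for (tb in b[5:10]) {
    idx <- round(tb * 100) + (-10:10) + 1L
    expect_lte(abs((idx[which.max(x[idx])] - 1) / 100 - tb), 1 / 100 + 1e-9)
  }
  xa <- render_ecg(b, am_depth = 0.2, br_brpm = 10, fs = 100, kind = "ref",
                   duration_s = 60)
  ramp <- vapply(b[b > 0.5 & b < 59], function(tb)
    max(xa[round(tb * 100) + (-3:3) + 1L]), numeric(1))
  f <- oracle_dft_band_peak(ramp - mean(ramp), 75 / 60, c(0.05, 0.5),
                            df_max = 2e-3)
  expect_equal(f, 10 / 60, tolerance = 0.01)
  expect_error(render_ecg(b, kind = "chest"), "arg")
})

test_that("simulated recordings are deterministic and clean when noise is off", {
  cfg <- sim_config(duration_s = 40, hr_bpm = 70, br_brpm = 12,
                    fm_depth_bpm = 2, am_depth = 0.1, bw_depth = 0.3,
                    mst = 4, noise = noise_config(white_sd = 0.05,
                                                  emg_rate_hz = 0.2,
                                                  emg_amp = 1,
                                                  popoff_prob = 0.3),
                    seed = 99)
  r1 <- simulate_recording(cfg)
  r2 <- simulate_recording(cfg)
  expect_identical(r1$channels, r2$channels)
  expect_identical(r1$ref_ecg, r2$ref_ecg)

  clean_cfg <- sim_config(duration_s = 40, hr_bpm = 70, br_brpm = 12,
                          fm_depth_bpm = 2, am_depth = 0.1, bw_depth = 0.3,
                          mst = 4, seed = 99)
  rc <- simulate_recording(clean_cfg)
  b <- generate_beat_times(70, 2, 12, 40)
  expect_equal(rc$channels$ppg_green,
               render_pulsatile(b, "ppg_green", 0.1, 0.3, 12, 4, 100, 40))
  expect_equal(rc$channels$ssecg,
               render_ecg(b, 0.1, 12, 100, "ssecg", 40))
})

test_that("EMG and powerline energy is routed away from the PPG channels", {
  base <- list(duration_s = 40, hr_bpm = 70, br_brpm = 12, mst = 2, seed = 7)
  clean <- simulate_recording(do.call(sim_config, base))
  noisy <- simulate_recording(do.call(sim_config, c(base, list(
    noise = noise_config(powerline_amp = 0.3, emg_rate_hz = 0.5,
                         emg_amp = 2)))))
  for (m in c("ppg_green", "ppg_red", "ppg_ir"))
    expect_identical(noisy$channels[[m]], clean$channels[[m]])
  band_power <- function(x) {
    bf <- signal::butter(4, c(20, 45) / 50, type = "pass")
    mean(as.numeric(signal::filtfilt(bf, x))^2)
  }
  expect_gt(band_power(noisy$channels$bioz), 2 * band_power(clean$channels$bioz))
  expect_equal(band_power(noisy$channels$ppg_green),
               band_power(clean$channels$ppg_green), tolerance = 0.01)
})

test_that("electrode pop-off saturates SS-ECG alone inside the affected span", {
  cfg <- sim_config(duration_s = 30, hr_bpm = 70, br_brpm = 12, mst = 2,
                    noise = noise_config(popoff_prob = 1, popoff_block_s = 15),
                    seed = 3)
  rec <- simulate_recording(cfg)
  clean <- simulate_recording(sim_config(duration_s = 30, hr_bpm = 70,
                                         br_brpm = 12, mst = 2, seed = 3))
  inside <- 501:1000
  expect_true(all(rec$channels$ssecg[inside] == rec$config$noise$popoff_rail))
  expect_identical(rec$channels$ppg_green, clean$channels$ppg_green)
})

test_that("invalid task spans are rejected", {
  cfg <- sim_config(duration_s = 60, seed = 1)
  expect_error(simulate_recording(cfg, data.frame(
    task = c("a", "b"), start_s = c(0, 20), end_s = c(30, 60))), "overlap")
  expect_error(simulate_recording(cfg, data.frame(
    task = "a", start_s = 0, end_s = 90)), "duration")
})
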