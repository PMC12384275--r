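# Synthetic multimodal recording simulator.
#
# Renders the five device channels (three PPG wavelengths, BioZ, SS-ECG) plus
# a chest reference ECG from a common ground-truth beat sequence, with the
# three respiratory signatures encoded explicitly:
#   BW - additive baseline at the respiratory frequency, negative-going on
#        inhale for PPG (blood volume shifts away from the periphery) and
#        positive-going for BioZ;
#   AM - per-beat pulse/R amplitude modulation;
#   FM - respiratory sinus arrhythmia, i.e. sinusoidal modulation of the
#        instantaneous heart rate.
# Pulsatile channels are rendered with negative-going pulses (optical
# absorption and tissue impedance both DROP when arterial volume peaks),
# which is what makes the envelope-subtract-and-invert preprocessing yield a
# positive-peaked AC component.

#' Noise configuration for the simulator
#'
#' All amplitudes are in the (arbitrary) units of the rendered signals, whose
#' clean pulse/R amplitudes are of order one. Powerline and EMG energy is
#' routed to BioZ and SS-ECG only (optical channels do not pick up mains or
#' muscle-electrical interference); motion transients touch every device
#' channel; electrode pop-off saturates SS-ECG alone.
#'
#' @param white_sd White-noise standard deviation added to every channel.
#' @param powerline_amp,powerline_hz Mains interference amplitude and
#'   frequency (BioZ and SS-ECG only).
#' @param emg_rate_hz Expected EMG bursts per second (Poisson).
#' @param emg_dur_s,emg_amp Burst duration (s) and amplitude; bursts are
#'   Hann-windowed 20-45 Hz band-limited Gaussian noise on BioZ and SS-ECG.
#' @param emg_tasks Optional character vector of task names; bursts are
#'   confined to those spans (default: anywhere).
#' @param motion_rate_hz,motion_amp Motion transients per second and their
#'   amplitude; each is a smooth ~0.3 s-sd Gaussian bump applied (with a
#'   random per-channel scale) to all device channels.
#' @param popoff_prob Probability that each `popoff_block_s` block of the
#'   SS-ECG trace is replaced by a saturation plateau (electrode pop-off).
#' @param popoff_block_s Block length for pop-off events, seconds.
#' @param popoff_tasks Optional task names to which pop-off is confined.
#' @param popoff_rail Saturation rail value.
#' @return A list of class `cf_noise`.
#' @export
noise_config <- function(white_sd = 0, powerline_amp = 0, powerline_hz = 50,
                         emg_rate_hz = 0, emg_dur_s = 1, emg_amp = 0,
                         emg_tasks = NULL,
                         motion_rate_hz = 0, motion_amp = 0,
                         popoff_prob = 0, popoff_block_s = 15,
                         popoff_tasks = NULL, popoff_rail = 1) {
  check_scalar(white_sd, "white_sd", 0)
  check_scalar(powerline_amp, "powerline_amp", 0)
  check_scalar(emg_rate_hz, "emg_rate_hz", 0)
  check_scalar(motion_rate_hz, "motion_rate_hz", 0)
  check_scalar(popoff_prob, "popoff_prob", 0, 1)
  structure(list(white_sd = white_sd, powerline_amp = powerline_amp,
                 powerline_hz = powerline_hz, emg_rate_hz = emg_rate_hz,
                 emg_dur_s = emg_dur_s, emg_amp = emg_amp,
                 emg_tasks = emg_tasks,
                 motion_rate_hz = motion_rate_hz, motion_amp = motion_amp,
                 popoff_prob = popoff_prob, popoff_block_s = popoff_block_s,
                 popoff_tasks = popoff_tasks, popoff_rail = popoff_rail),
            class = "cf_noise")
}

#' Simulation configuration
#'
#' @param duration_s Recording length, seconds.
#' @param device_fs Device sampling rate, Hz (all five device channels).
#' @param ref_fs Chest reference ECG sampling rate, Hz.
#' @param hr_bpm Mean heart rate, beats/min. In-gate scenarios use 40-120.
#' @param br_brpm Breathing rate, breaths/min: either a single number or a
#'   data.frame with columns `start_s`, `brpm` describing a piecewise-constant
#'   rate profile (e.g. the paced-breathing task switching from 6 to 10 BRpm).
#' @param fm_depth_bpm Peak respiratory-sinus-arrhythmia deviation of the
#'   instantaneous heart rate, beats/min.
#' @param am_depth Fractional pulse-amplitude modulation, in [0, 1).
#' @param bw_depth Baseline-wander amplitude (signal units); a single number
#'   applied to every pulsatile channel, or a named vector over
#'   `ppg_green`, `ppg_red`, `ppg_ir`, `bioz`. The sign convention (PPG down
#'   on inhale, BioZ up) is applied internally; supply magnitudes.
#' @param mst Monk Skin Tone, integer 1-10.
#' @param ibi_jitter_sd Optional beat-to-beat timing jitter sd, seconds.
#' @param noise A [noise_config()].
#' @param subject_id Label for the simulated subject.
#' @param seed RNG seed for [simulate_recording()].
#' @return A list of class `cf_sim_config`.
#' @export
sim_config <- function(duration_s, device_fs = 100, ref_fs = 130,
                       hr_bpm = 75, br_brpm = 12, fm_depth_bpm = 0,
                       am_depth = 0, bw_depth = 0, mst = 1,
                       ibi_jitter_sd = 0, noise = noise_config(),
                       subject_id = "S01", seed = NULL) {
  check_scalar(duration_s, "duration_s", lo = 1e-9)
  check_scalar(device_fs, "device_fs", lo = 50)
  check_scalar(ref_fs, "ref_fs", lo = 50)
  check_scalar(hr_bpm, "hr_bpm", lo = 1)
  check_scalar(fm_depth_bpm, "fm_depth_bpm", 0)
  if (fm_depth_bpm >= hr_bpm) stop("fm_depth_bpm must be < hr_bpm")
  check_scalar(am_depth, "am_depth", 0)
  if (am_depth >= 1) stop("am_depth must be in [0, 1)")
  if (!(is.numeric(mst) && length(mst) == 1L && mst %in% 1:10))
    stop("mst must be an integer in 1..10")
  br_profile(br_brpm)  # validates
  if (is.numeric(bw_depth) && is.null(names(bw_depth)) && length(bw_depth) == 1L) {
    bw_depth <- stats::setNames(rep(bw_depth, 4L), PULSATILE_CHANNELS)
  } else {
    if (!all(names(bw_depth) %in% PULSATILE_CHANNELS))
      stop("named bw_depth entries must be pulsatile channels")
    full <- stats::setNames(rep(0, 4L), PULSATILE_CHANNELS)
    full[names(bw_depth)] <- bw_depth
    bw_depth <- full
  }
  stopifnot(inherits(noise, "cf_noise"))
  structure(list(duration_s = duration_s, device_fs = device_fs,
                 ref_fs = ref_fs, hr_bpm = hr_bpm, br_brpm = br_brpm,
                 fm_depth_bpm = fm_depth_bpm, am_depth = am_depth,
                 bw_depth = bw_depth, mst = as.integer(mst),
                 ibi_jitter_sd = ibi_jitter_sd, noise = noise,
                 subject_id = subject_id, seed = seed),
            class = "cf_sim_config")
}

# Normalise a breathing-rate spec to a data.frame(start_s, brpm) and return
# a vectorised respiratory phase function phi(t) [radians], continuous across
# rate switches, phi(0) = 0.
br_profile <- function(br_brpm) {
  if (is.numeric(br_brpm) && length(br_brpm) == 1L) {
    if (!is.finite(br_brpm) || br_brpm <= 0) stop("br_brpm must be > 0")
    return(data.frame(start_s = 0, brpm = br_brpm))
  }
  if (!is.data.frame(br_brpm) || !all(c("start_s", "brpm") %in% names(br_brpm)))
    stop("br_brpm must be a number or a data.frame(start_s, brpm)")
  p <- br_brpm[order(br_brpm$start_s), c("start_s", "brpm")]
  if (p$start_s[1] != 0) stop("br profile must start at 0 s")
  if (any(p$brpm <= 0) || any(!is.finite(p$brpm))) stop("brpm must be > 0")
  p
}

resp_phase_fun <- function(br_brpm) {
  p <- br_profile(br_brpm)
  f <- p$brpm / 60
  s <- p$start_s
  # cumulative phase (cycles) at each breakpoint
  cyc0 <- c(0, cumsum(f[-length(f)] * diff(s)))
  function(t) {
    i <- findInterval(t, s)
    i[i < 1L] <- 1L
    2 * pi * (cyc0[i] + f[i] * (t - s[i]))
  }
}

#' Ground-truth beat times with respiratory sinus arrhythmia
#'
#' Beats are the integer level-crossings of the integrated instantaneous rate
#' `r(t) = hr_bpm + fm_depth_bpm * sin(phi_resp(t))`, with the respiratory
#' phase from the (possibly piecewise-constant) breathing-rate profile. With
#' `fm_depth_bpm = 0` and no jitter the spacing is exactly `60 / hr_bpm`,
#' starting at t = 0.
#'
#' @param hr_bpm Mean heart rate, beats/min (must exceed `fm_depth_bpm`).
#' @param fm_depth_bpm Peak instantaneous-rate deviation, beats/min.
#' @param br_brpm Breathing rate (number or profile data.frame).
#' @param duration_s Length of the beat train, seconds.
#' @param seed Optional RNG seed (only consumed when `jitter_sd > 0`).
#' @param jitter_sd Additive Gaussian inter-beat-interval jitter sd, seconds.
#' @return Strictly increasing numeric vector of beat instants in
#'   `[0, duration_s]`.
#' @export
generate_beat_times <- function(hr_bpm, fm_depth_bpm = 0, br_brpm = 12,
                                duration_s = 60, seed = NULL, jitter_sd = 0) {
  check_scalar(hr_bpm, "hr_bpm", lo = 1)
  check_scalar(fm_depth_bpm, "fm_depth_bpm", 0)
  check_scalar(duration_s, "duration_s", lo = 1e-9)
  if (fm_depth_bpm >= hr_bpm) stop("fm_depth_bpm must be < hr_bpm")
  if (fm_depth_bpm == 0 && jitter_sd == 0) {
    beats <- seq(0, duration_s, by = 60 / hr_bpm)
  } else {
    phi <- resp_phase_fun(br_brpm)
    dt <- 0.002
    tg <- seq(0, duration_s, by = dt)
    r <- (hr_bpm + fm_depth_bpm * sin(phi(tg))) / 60
    nbeats <- c(0, cumsum((r[-1] + r[-length(r)]) / 2 * dt))
    ks <- seq(0, floor(nbeats[length(nbeats)]))
    beats <- stats::approx(nbeats, tg, xout = ks, ties = "ordered")$y
  }
  if (jitter_sd > 0) {
    if (!is.null(seed)) set.seed(seed)
    ibi <- diff(beats)
    ibi <- pmax(ibi + stats::rnorm(length(ibi), sd = jitter_sd), 0.25)
    beats <- cumsum(c(beats[1], ibi))
    beats <- beats[beats <= duration_s]
  }
  beats
}

# Melanin attenuation of the PPG AC amplitude: multiplicative factor per
# (wavelength, MST). Only the ordering is physiologically established (green
# attenuated most, IR least; darker tones attenuate more); the slopes are
# package constants.
melanin_factor <- function(modality, mst) {
  slope <- c(ppg_green = 0.075, ppg_red = 0.040, ppg_ir = 0.022, bioz = 0)
  1 - slope[[modality]] * (mst - 1)
}

# Asymmetric pulse template (systolic + diastolic Gaussian), peak value 1 at
# tau = 0. Width chosen so that the fundamental dominates the second harmonic
# in the 0.67-2 Hz HR search band.
pulse_template <- function(tau) {
  exp(-tau^2 / (2 * 0.09^2)) + 0.35 * exp(-(tau - 0.28)^2 / (2 * 0.12^2))
}

# Gaussian-sum PQRST template, R peak value 1 at tau = 0. `am` scales the R
# wave only (respiratory rotation of the cardiac electrical axis).
ecg_template <- function(tau, r_scale = 1) {
  0.12 * exp(-(tau + 0.22)^2 / (2 * 0.030^2)) -
    0.12 * exp(-(tau + 0.045)^2 / (2 * 0.012^2)) +
    r_scale * exp(-tau^2 / (2 * 0.018^2)) -
    0.18 * exp(-(tau - 0.045)^2 / (2 * 0.014^2)) +
    0.28 * exp(-(tau - 0.30)^2 / (2 * 0.060^2))
}

add_template <- function(out, fs, center_s, half_lo_s, half_hi_s, f) {
  n <- length(out)
  i0 <- max(1L, as.integer(floor((center_s - half_lo_s) * fs)) + 1L)
  i1 <- min(n, as.integer(ceiling((center_s + half_hi_s) * fs)) + 1L)
  if (i0 > i1) return(out)
  idx <- i0:i1
  tau <- (idx - 1L) / fs - center_s
  out[idx] <- out[idx] + f(tau)
  out
}

#' Render a pulsatile channel (PPG or BioZ) from beat times
#'
#' Each beat contributes a negative-going asymmetric pulse (two-Gaussian
#' systolic/diastolic shape) whose amplitude carries the respiratory AM and,
#' for PPG, the melanin attenuation for the subject's skin tone. A respiratory
#' baseline (BW) is added with the PPG-down / BioZ-up sign convention, inhale
#' being the rising half-cycle of the respiratory phase sinusoid.
#'
#' @param beat_times Increasing beat instants, seconds (non-empty).
#' @param modality One of `"ppg_green"`, `"ppg_red"`, `"ppg_ir"`, `"bioz"`.
#' @param am_depth Fractional amplitude modulation in [0, 1).
#' @param bw_depth Baseline-wander magnitude, signal units.
#' @param br_brpm Breathing rate (number or profile data.frame).
#' @param mst Monk Skin Tone 1-10 (ignored for BioZ).
#' @param fs Sampling rate, Hz (>= 50).
#' @param duration_s Rendered length; defaults to covering the beat train.
#' @return Numeric vector of `round(duration_s * fs)` samples.
#' @export
render_pulsatile <- function(beat_times, modality, am_depth = 0, bw_depth = 0,
                             br_brpm = 12, mst = 1, fs = 100,
                             duration_s = NULL) {
  if (!modality %in% PULSATILE_CHANNELS)
    stop("unknown pulsatile modality: ", modality)
  stopifnot(length(beat_times) > 0, fs >= 50)
  if (is.null(duration_s)) duration_s <- max(beat_times) + 1
  phi <- resp_phase_fun(br_brpm)
  n <- round(duration_s * fs)
  out <- numeric(n)
  mel <- melanin_factor(modality, mst)
  amps <- mel * (1 + am_depth * sin(phi(beat_times)))
  for (k in seq_along(beat_times)) {
    a <- amps[k]
    out <- add_template(out, fs, beat_times[k], 0.45, 0.80,
                        function(tau) -a * pulse_template(tau))
  }
  if (bw_depth != 0) {
    sign_bw <- if (modality == "bioz") 1 else -1
    t <- (seq_len(n) - 1L) / fs
    out <- out + sign_bw * bw_depth * sin(phi(t))
  }
  out
}

#' Render an ECG channel (single-sided or chest reference) from beat times
#'
#' A Gaussian-sum PQRST template is centred at each beat; the R amplitude is
#' scaled by `1 + am_depth * sin(phi_resp(t_beat))`. Neither ECG kind carries
#' baseline wander (none is observed on the upper arm), and the single-sided
#' channel is rendered at a fraction of the chest amplitude.
#'
#' @inheritParams render_pulsatile
#' @param kind `"ssecg"` (upper arm, attenuated) or `"ref"` (chest).
#' @return Numeric vector of `round(duration_s * fs)` samples.
#' @export
render_ecg <- function(beat_times, am_depth = 0, br_brpm = 12, fs = 100,
                       kind = c("ssecg", "ref"), duration_s = NULL) {
  kind <- match.arg(kind)
  stopifnot(length(beat_times) > 0, fs >= 50)
  if (is.null(duration_s)) duration_s <- max(beat_times) + 1
  phi <- resp_phase_fun(br_brpm)
  n <- round(duration_s * fs)
  out <- numeric(n)
  scale <- if (kind == "ssecg") 0.4 else 1.0
  r_scales <- 1 + am_depth * sin(phi(beat_times))
  for (k in seq_along(beat_times)) {
    rs <- r_scales[k]
    out <- add_template(out, fs, beat_times[k], 0.35, 0.55,
                        function(tau) scale * ecg_template(tau, r_scale = rs))
  }
  out
}

validate_task_spans <- function(task_spans, duration_s) {
  stopifnot(is.data.frame(task_spans),
            all(c("task", "start_s", "end_s") %in% names(task_spans)))
  ts <- task_spans[order(task_spans$start_s), ]
  if (any(ts$start_s < 0) || any(ts$end_s > duration_s + 1e-9))
    stop("task_spans exceed the recording duration")
  if (any(ts$end_s <= ts$start_s)) stop("task_spans must have end_s > start_s")
  if (nrow(ts) > 1L && any(ts$start_s[-1] < ts$end_s[-nrow(ts)] - 1e-9))
    stop("task_spans overlap")
  ts
}

span_mask <- function(n, fs, spans) {
  m <- logical(n)
  t <- (seq_len(n) - 1L) / fs
  for (i in seq_len(nrow(spans)))
    m <- m | (t >= spans$start_s[i] & t < spans$end_s[i])
  m
}

restrict_spans <- function(task_spans, tasks) {
  if (is.null(tasks)) return(task_spans)
  out <- task_spans[task_spans$task %in% tasks, , drop = FALSE]
  if (!nrow(out)) task_spans else out
}

band_noise <- function(n, fs, band = c(20, 45)) {
  w <- stats::rnorm(n)
  ny <- fs / 2
  hi <- min(band[2], 0.98 * ny)
  b <- signal::butter(4, c(band[1], hi) / ny, type = "pass")
  as.numeric(signal::filter(b, w))
}

#' Simulate a full multimodal recording
#'
#' Renders all five device channels and the chest reference from one
#' ground-truth beat train, then injects the configured noise: white noise on
#' every channel; powerline and Hann-windowed 20-45 Hz EMG bursts on BioZ and
#' SS-ECG only; smooth motion transients on all device channels; electrode
#' pop-off as saturation plateaus on SS-ECG, drawn per `popoff_block_s` block.
#' Output is deterministic for a fixed `config$seed`.
#'
#' @param config A [sim_config()].
#' @param task_spans Optional data.frame with columns `task`, `start_s`,
#'   `end_s` (non-overlapping, within the recording); a `br_label` column may
#'   carry nominal paced breathing rates. Defaults to one span covering the
#'   whole recording.
#' @return A `cf_recording`: list with `channels` (named list of the five
#'   device channels), `ref_ecg`, `device_fs`, `ref_fs`, `duration_s`,
#'   `beat_times`, `truth` (instantaneous HR/BR at 1 s resolution), `meta`
#'   (subject id, MST, skin-tone category), `task_spans` and `config`.
#' @export
simulate_recording <- function(config, task_spans = NULL) {
  stopifnot(inherits(config, "cf_sim_config"))
  if (is.null(task_spans))
    task_spans <- data.frame(task = "recording", start_s = 0,
                             end_s = config$duration_s)
  task_spans <- validate_task_spans(task_spans, config$duration_s)
  if (!is.null(config$seed)) set.seed(config$seed)
  fs <- config$device_fs
  dur <- config$duration_s
  n <- round(dur * fs)
  beats <- generate_beat_times(config$hr_bpm, config$fm_depth_bpm,
                               config$br_brpm, dur,
                               jitter_sd = config$ibi_jitter_sd)
  channels <- list()
  for (m in PULSATILE_CHANNELS) {
    channels[[m]] <- render_pulsatile(beats, m, config$am_depth,
                                      config$bw_depth[[m]], config$br_brpm,
                                      config$mst, fs, dur)
  }
  channels$ssecg <- render_ecg(beats, config$am_depth, config$br_brpm, fs,
                               "ssecg", dur)
  ref <- render_ecg(beats, config$am_depth, config$br_brpm, config$ref_fs,
                    "ref", dur)
  nz <- config$noise

  if (nz$white_sd > 0) {
    for (m in DEVICE_CHANNELS)
      channels[[m]] <- channels[[m]] + stats::rnorm(n, sd = nz$white_sd)
    ref <- ref + stats::rnorm(length(ref), sd = nz$white_sd)
  }
  if (nz$powerline_amp > 0) {
    t <- (seq_len(n) - 1L) / fs
    for (m in c("bioz", "ssecg")) {
      ph <- stats::runif(1, 0, 2 * pi)
      channels[[m]] <- channels[[m]] +
        nz$powerline_amp * sin(2 * pi * nz$powerline_hz * t + ph)
    }
  }
  if (nz$emg_rate_hz > 0 && nz$emg_amp > 0) {
    spans <- restrict_spans(task_spans, nz$emg_tasks)
    total <- sum(spans$end_s - spans$start_s)
    n_events <- stats::rpois(1, nz$emg_rate_hz * total)
    if (n_events > 0) {
      u <- stats::runif(n_events, 0, total)
      offs <- c(0, cumsum(spans$end_s - spans$start_s))
      seg <- findInterval(u, offs, rightmost.closed = TRUE)
      centers <- spans$start_s[seg] + (u - offs[seg])
      for (m in c("bioz", "ssecg")) {
        bn <- band_noise(n, fs)
        env <- numeric(n)
        for (cth in centers) {
          i0 <- max(1L, round((cth - nz$emg_dur_s / 2) * fs) + 1L)
          i1 <- min(n, round((cth + nz$emg_dur_s / 2) * fs) + 1L)
          if (i1 > i0) {
            h <- 0.5 - 0.5 * cos(2 * pi * seq(0, 1, length.out = i1 - i0 + 1L))
            env[i0:i1] <- pmax(env[i0:i1], h)
          }
        }
        channels[[m]] <- channels[[m]] + nz$emg_amp * env * bn
      }
    }
  }
  if (nz$motion_rate_hz > 0 && nz$motion_amp > 0) {
    n_events <- stats::rpois(1, nz$motion_rate_hz * dur)
    if (n_events > 0) {
      centers <- stats::runif(n_events, 0, dur)
      t <- (seq_len(n) - 1L) / fs
      for (m in DEVICE_CHANNELS) {
        scale <- stats::runif(n_events, 0.5, 1.5) *
          sample(c(-1, 1), n_events, replace = TRUE)
        for (j in seq_len(n_events)) {
          channels[[m]] <- channels[[m]] + nz$motion_amp * scale[j] *
            exp(-(t - centers[j])^2 / (2 * 0.3^2))
        }
      }
    }
  }
  popoff_spans <- NULL
  if (nz$popoff_prob > 0) {
    spans <- restrict_spans(task_spans, nz$popoff_tasks)
    blocks <- list()
    for (i in seq_len(nrow(spans))) {
      b0 <- seq(spans$start_s[i], spans$end_s[i] - 1e-9, by = nz$popoff_block_s)
      for (b in b0)
        blocks[[length(blocks) + 1L]] <-
          c(b, min(b + nz$popoff_block_s, spans$end_s[i]))
    }
    hit <- stats::runif(length(blocks)) < nz$popoff_prob
    for (j in which(hit)) {
      i0 <- round(blocks[[j]][1] * fs) + 1L
      i1 <- min(n, round(blocks[[j]][2] * fs))
      channels$ssecg[i0:i1] <- nz$popoff_rail
    }
    if (any(hit))
      popoff_spans <- do.call(rbind, lapply(blocks[hit], function(b)
        data.frame(start_s = b[1], end_s = b[2])))
  }

  tt <- seq(0, dur, by = 1)
  phi <- resp_phase_fun(config$br_brpm)
  prof <- br_profile(config$br_brpm)
  truth <- data.frame(
    time_s = tt,
    hr_bpm = config$hr_bpm + config$fm_depth_bpm * sin(phi(tt)),
    br_brpm = prof$brpm[pmax(1L, findInterval(tt, prof$start_s))])
  structure(list(
    channels = channels, ref_ecg = ref,
    device_fs = fs, ref_fs = config$ref_fs, duration_s = dur,
    beat_times = beats, truth = truth,
    meta = list(subject_id = config$subject_id, mst = config$mst,
                category = mst_to_category(config$mst)),
    task_spans = task_spans, popoff_spans = popoff_spans,
    config = config), class = "cf_recording")
}

#' @export
print.cf_recording <- function(x, ...) {
  cat(sprintf("<cf_recording> subject %s (MST %d, %s)\n",
              x$meta$subject_id, x$meta$mst, x$meta$category))
  cat(sprintf("  %.0f s @ %g Hz device / %g Hz reference, %d beats\n",
              x$duration_s, x$device_fs, x$ref_fs, length(x$beat_times)))
  cat(sprintf("  tasks: %s\n",
              paste(sprintf("%s [%g, %g)", x$task_spans$task,
                            x$task_spans$start_s, x$task_spans$end_s),
                    collapse = ", ")))
  invisible(x)
}
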