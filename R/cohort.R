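# Study-protocol helpers: the task layout and a synthetic cohort whose
# composition mirrors the study (16 subjects; 8 light / 4 medium / 4 dark
# Monk Skin Tone). Heart-rate tasks last two minutes; the paced-breathing
# task runs one minute at 6 breaths/min followed by one minute at 10.

#' Task spans of the study protocol
#'
#' @param tasks Ordered task names.
#' @param task_s Duration of each task, seconds.
#' @return data.frame with `task`, `start_s`, `end_s` (back-to-back spans).
#' @export
study_task_spans <- function(tasks = c("sedentary", "flexing",
                                       "paced_breathing"),
                             task_s = 120) {
  n <- length(tasks)
  data.frame(task = tasks, start_s = task_s * (seq_len(n) - 1L),
             end_s = task_s * seq_len(n))
}

# Breathing-rate profile matching the task layout: a resting rate outside
# the paced span, 6 then 10 breaths/min inside it.
protocol_br_profile <- function(task_spans, rest_brpm = 12,
                                paced_brpm = c(6, 10)) {
  i <- which(task_spans$task == "paced_breathing")
  if (!length(i)) return(rest_brpm)
  s <- task_spans$start_s[i[1]]; e <- task_spans$end_s[i[1]]
  prof <- data.frame(start_s = 0, brpm = rest_brpm)
  if (s > 0) prof <- rbind(prof, data.frame(start_s = s, brpm = paced_brpm[1]))
  else prof$brpm[1] <- paced_brpm[1]
  prof <- rbind(prof,
                data.frame(start_s = s + (e - s) / 2, brpm = paced_brpm[2]))
  if (e < max(task_spans$end_s))
    prof <- rbind(prof, data.frame(start_s = e, brpm = rest_brpm))
  prof[!duplicated(prof$start_s), ]
}

#' Simulate one subject under the study protocol
#'
#' Wraps [sim_config()] + [simulate_recording()] with the protocol task
#' layout and the paced 6/10 breaths/min profile aligned to the
#' paced-breathing span.
#'
#' @param subject_id Subject label.
#' @param mst Monk Skin Tone 1-10.
#' @param hr_bpm Mean heart rate, beats/min.
#' @param fm_depth_bpm,am_depth,bw_depth Respiratory modulation depths (see
#'   [sim_config()]). Defaults represent a healthy resting adult: ~3 bpm of
#'   respiratory sinus arrhythmia, 15% pulse-amplitude modulation, baseline
#'   wander at 40% of the pulse amplitude.
#' @param noise A [noise_config()].
#' @param task_spans Protocol spans (default [study_task_spans()]).
#' @param rest_brpm Breathing rate outside the paced task, breaths/min.
#' @param seed RNG seed.
#' @return A `cf_recording`.
#' @export
simulate_subject <- function(subject_id = "S01", mst = 2, hr_bpm = 75,
                             fm_depth_bpm = 3, am_depth = 0.15,
                             bw_depth = 0.4, noise = noise_config(),
                             task_spans = study_task_spans(),
                             rest_brpm = 12, seed = NULL) {
  cfg <- sim_config(duration_s = max(task_spans$end_s),
                    hr_bpm = hr_bpm,
                    br_brpm = protocol_br_profile(task_spans, rest_brpm),
                    fm_depth_bpm = fm_depth_bpm, am_depth = am_depth,
                    bw_depth = bw_depth, mst = mst, noise = noise,
                    subject_id = subject_id, seed = seed)
  simulate_recording(cfg, task_spans)
}

#' Simulate a study-sized synthetic cohort
#'
#' Sixteen subjects by default, with the study's skin-tone composition
#' (8 light, 4 medium, 4 dark), subject-specific resting heart rates drawn
#' from 60-95 bpm, and per-subject heterogeneous noise: every subject gets
#' baseline sensor noise, and EMG bursts / electrode pop-off / motion
#' transients are drawn at subject-specific severities so channels fail in
#' different windows for different subjects.
#'
#' @param n_subjects Cohort size.
#' @param seed Cohort-level RNG seed (subject seeds derive from it).
#' @param noisy Logical: draw heterogeneous per-subject noise (`TRUE`) or
#'   render clean signals (`FALSE`).
#' @param task_spans Protocol spans for every subject.
#' @return List of `cf_recording` objects.
#' @export
simulate_cohort <- function(n_subjects = 16, seed = 1, noisy = TRUE,
                            task_spans = study_task_spans()) {
  set.seed(seed)
  msts <- c(sample(1:3, 8, replace = TRUE), sample(4:6, 4, replace = TRUE),
            sample(7:10, 4, replace = TRUE))
  msts <- rep_len(msts[sample.int(16)], n_subjects)
  hrs <- stats::runif(n_subjects, 60, 95)
  fm <- stats::runif(n_subjects, 2, 4)
  am <- stats::runif(n_subjects, 0.10, 0.25)
  bw <- stats::runif(n_subjects, 0.3, 0.6)
  subject_seeds <- sample.int(2^20, n_subjects)
  noise_draws <- lapply(seq_len(n_subjects), function(i) {
    if (!noisy) return(noise_config())
    noise_config(
      white_sd = stats::runif(1, 0.01, 0.08),
      powerline_amp = stats::runif(1, 0, 0.1),
      emg_rate_hz = stats::runif(1, 0, 0.2), emg_amp = stats::runif(1, 0, 1.5),
      motion_rate_hz = stats::runif(1, 0, 0.05),
      motion_amp = stats::runif(1, 0, 0.8),
      popoff_prob = stats::runif(1, 0, 0.3))
  })
  lapply(seq_len(n_subjects), function(i) {
    simulate_subject(subject_id = sprintf("S%02d", i), mst = msts[i],
                     hr_bpm = hrs[i], fm_depth_bpm = fm[i], am_depth = am[i],
                     bw_depth = bw[i], noise = noise_draws[[i]],
                     task_spans = task_spans, seed = subject_seeds[i])
  })
}
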