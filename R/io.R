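# Dataset layout and the end-to-end pipeline driver.
#
# A subject directory holds:
#   recording.csv  - header time_s,ppg_green,ppg_red,ppg_ir,bioz,ssecg
#   reference.csv  - header time_s,ecg (chest reference at its native rate)
#   meta.json      - subject metadata, task spans, simulation provenance and
#                    ground-truth beat times (when simulated)
# Doubles are serialized with 17 significant digits so a write/read
# round-trip reproduces the arrays bit-exactly.

RECORDING_HEADER <- c("time_s", DEVICE_CHANNELS)

fmt17 <- function(x) sprintf("%.17g", x)

write_numeric_csv <- function(df, path) {
  out <- data.table::as.data.table(lapply(df, fmt17))
  data.table::fwrite(out, path, quote = FALSE)
}

#' Write a recording to a subject directory
#'
#' @param rec A `cf_recording`.
#' @param dir Output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
write_recording <- function(rec, dir) {
  stopifnot(inherits(rec, "cf_recording"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  n <- length(rec$channels[[1]])
  dev <- c(list(time_s = (seq_len(n) - 1L) / rec$device_fs), rec$channels)
  write_numeric_csv(as.data.frame(dev), file.path(dir, "recording.csv"))
  nr <- length(rec$ref_ecg)
  write_numeric_csv(data.frame(time_s = (seq_len(nr) - 1L) / rec$ref_fs,
                               ecg = rec$ref_ecg),
                    file.path(dir, "reference.csv"))
  cfg <- rec$config
  meta <- list(
    subject = rec$meta,
    device_fs = rec$device_fs, ref_fs = rec$ref_fs,
    duration_s = rec$duration_s,
    task_spans = rec$task_spans,
    beat_times = rec$beat_times,
    truth = rec$truth,
    sim_config = if (is.null(cfg)) NULL else list(
      hr_bpm = cfg$hr_bpm, br_brpm = cfg$br_brpm,
      fm_depth_bpm = cfg$fm_depth_bpm, am_depth = cfg$am_depth,
      bw_depth = as.list(cfg$bw_depth), mst = cfg$mst,
      ibi_jitter_sd = cfg$ibi_jitter_sd, seed = cfg$seed,
      noise = unclass(cfg$noise)))
  jsonlite::write_json(meta, file.path(dir, "meta.json"), auto_unbox = TRUE,
                       digits = I(17), null = "null")
  invisible(dir)
}

#' Read a recording from a subject directory
#'
#' Validates the CSV headers, the monotone time axis, the sampling rate
#' against the sidecar (within 1 ppm) and the absence of gaps larger than
#' two sample periods.
#'
#' @param dir Subject directory written by [write_recording()].
#' @return A `cf_recording`.
#' @export
read_recording <- function(dir) {
  rec_path <- file.path(dir, "recording.csv")
  ref_path <- file.path(dir, "reference.csv")
  meta_path <- file.path(dir, "meta.json")
  for (p in c(rec_path, ref_path, meta_path))
    if (!file.exists(p)) stop("missing dataset file: ", p)
  meta <- jsonlite::read_json(meta_path, simplifyVector = TRUE)
  dev <- data.table::fread(rec_path, colClasses = "numeric")
  if (!identical(names(dev), RECORDING_HEADER))
    stop("recording.csv header mismatch; missing or misordered columns: ",
         paste(setdiff(RECORDING_HEADER, names(dev)), collapse = ", "))
  ref <- data.table::fread(ref_path, colClasses = "numeric")
  if (!identical(names(ref), c("time_s", "ecg")))
    stop("reference.csv header mismatch")
  check_time_axis(dev$time_s, meta$device_fs, "recording.csv")
  check_time_axis(ref$time_s, meta$ref_fs, "reference.csv")
  cfg <- NULL
  if (!is.null(meta$sim_config)) {
    sc <- meta$sim_config
    br <- if (is.data.frame(sc$br_brpm)) sc$br_brpm else as.numeric(sc$br_brpm)
    cfg <- sim_config(duration_s = meta$duration_s,
                      device_fs = meta$device_fs, ref_fs = meta$ref_fs,
                      hr_bpm = sc$hr_bpm, br_brpm = br,
                      fm_depth_bpm = sc$fm_depth_bpm, am_depth = sc$am_depth,
                      bw_depth = unlist(sc$bw_depth), mst = sc$mst,
                      ibi_jitter_sd = sc$ibi_jitter_sd,
                      noise = do.call(noise_config,
                                      sc$noise[!vapply(sc$noise, is.null,
                                                       logical(1))]),
                      subject_id = meta$subject$subject_id, seed = sc$seed)
  }
  structure(list(
    channels = lapply(stats::setNames(DEVICE_CHANNELS, DEVICE_CHANNELS),
                      function(m) dev[[m]]),
    ref_ecg = ref$ecg,
    device_fs = meta$device_fs, ref_fs = meta$ref_fs,
    duration_s = meta$duration_s,
    beat_times = as.numeric(meta$beat_times),
    truth = meta$truth,
    meta = list(subject_id = meta$subject$subject_id,
                mst = as.integer(meta$subject$mst),
                category = mst_to_category(as.integer(meta$subject$mst))),
    task_spans = as.data.frame(meta$task_spans),
    config = cfg), class = "cf_recording")
}

check_time_axis <- function(t, fs, what) {
  if (is.unsorted(t, strictly = TRUE))
    stop(what, ": time column is not strictly increasing")
  dt <- diff(t)
  if (any(dt > 2 / fs + 1e-12))
    stop(what, ": time column has a gap larger than two sample periods")
  rate <- 1 / stats::median(dt)
  if (abs(rate - fs) / fs > 1e-6)
    stop(sprintf("%s: sampling rate %.6f Hz does not match sidecar %.6f Hz",
                 what, rate, fs))
  invisible(TRUE)
}

#' Write a cohort as a dataset directory
#'
#' @param recordings List of `cf_recording` objects.
#' @param root Dataset root; one subdirectory per subject id.
#' @return `root`, invisibly.
#' @export
write_dataset <- function(recordings, root) {
  for (rec in recordings)
    write_recording(rec, file.path(root, rec$meta$subject_id))
  invisible(root)
}

#' Run the full estimation pipeline over a cohort
#'
#' For every subject: preprocess, window, estimate per-modality HR with the
#' hierarchical fusion (tasks other than paced breathing), and extract the
#' 14-slot BR features from the paced-breathing task. Then pool: HR validity
#' into the R1/R2 robustness measures, fused-versus-reference HR MAE, and a
#' LOSO evaluation of the BR fusion model. A failing subject is skipped and
#' recorded in the report.
#'
#' @param dataset A dataset root directory or a list of `cf_recording`s.
#' @param out_dir Optional output directory for `hr_estimates.csv`,
#'   `br_features.csv` and `report.json`.
#' @param model BR fusion model (`"bagged_trees"` or `"robust_linear"`).
#' @param seed Seed for the fusion bootstrap and inner CV.
#' @param hr_tasks Tasks used for HR (default: every non-paced task).
#' @param quiet Suppress per-subject progress lines.
#' @return List of class `cf_pipeline_report`: `hr` (long estimates table,
#'   per-modality MAE vs reference, `robustness`, fused coverage and MAE),
#'   `br` (feature table and the `cf_eval_report`), `subjects`, `skipped`,
#'   `timings_s`.
#' @export
run_pipeline <- function(dataset, out_dir = NULL, model = "bagged_trees",
                         seed = 1, hr_tasks = NULL, quiet = FALSE) {
  recordings <- if (is.character(dataset)) {
    dirs <- list.dirs(dataset, recursive = FALSE)
    if (!length(dirs)) stop("no subject directories under ", dataset)
    lapply(dirs, read_recording)
  } else dataset
  hr_tabs <- list(); br_tabs <- list()
  skipped <- character(0); processed <- character(0)
  timings <- c(hr = 0, br = 0)
  for (rec in recordings) {
    sid <- rec$meta$subject_id
    res <- tryCatch({
      prep <- preprocess_recording(rec)
      tasks <- hr_tasks
      if (is.null(tasks))
        tasks <- setdiff(rec$task_spans$task, "paced_breathing")
      t0 <- proc.time()[[3]]
      hr_tab <- if (length(tasks)) estimate_hr(rec, tasks = tasks, prep = prep)
                else NULL
      t1 <- proc.time()[[3]]
      br_tab <- if ("paced_breathing" %in% rec$task_spans$task ||
                    nrow(rec$task_spans) == 1L)
        estimate_br(rec, prep = prep) else NULL
      t2 <- proc.time()[[3]]
      list(hr = hr_tab, br = br_tab, dt = c(hr = t1 - t0, br = t2 - t1))
    }, error = function(e) e)
    if (inherits(res, "error")) {
      skipped <- c(skipped, sid)
      if (!quiet) message("skipping subject ", sid, ": ", conditionMessage(res))
      next
    }
    timings <- timings + res$dt
    processed <- c(processed, sid)
    if (!is.null(res$hr)) {
      res$hr$subject_id <- sid
      hr_tabs[[sid]] <- res$hr
    }
    if (!is.null(res$br)) {
      res$br$subject_id <- sid
      br_tabs[[sid]] <- res$br
    }
    if (!quiet)
      message(sprintf("subject %s: %d HR windows, %d BR windows", sid,
                      if (is.null(res$hr)) 0L else
                        length(unique(paste(res$hr$task, res$hr$window_index))),
                      if (is.null(res$br)) 0L else nrow(res$br)))
  }
  if (!length(processed)) stop("no subject could be processed")
  hr_all <- if (length(hr_tabs)) do.call(rbind, hr_tabs) else NULL
  if (!is.null(hr_all)) rownames(hr_all) <- NULL
  hr_summary <- if (is.null(hr_all)) NULL else summarize_hr(hr_all)
  br_all <- if (length(br_tabs)) do.call(rbind, br_tabs) else NULL
  br_eval <- NULL
  if (!is.null(br_all)) {
    if (length(unique(br_all$subject_id)) < 3L)
      stop("LOSO breathing-rate evaluation requires at least 3 subjects; ",
           "got ", length(unique(br_all$subject_id)))
    br_eval <- loso_evaluate(br_all, model = model, seed = seed)
  }
  report <- structure(list(hr = c(list(estimates = hr_all), hr_summary),
                           br = list(features = br_all, eval = br_eval),
                           subjects = processed, skipped = skipped,
                           model = model, timings_s = timings),
                      class = "cf_pipeline_report")
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    if (!is.null(hr_all))
      data.table::fwrite(hr_all, file.path(out_dir, "hr_estimates.csv"))
    if (!is.null(br_all))
      data.table::fwrite(br_all, file.path(out_dir, "br_features.csv"))
    json <- list(
      subjects = report$subjects, skipped = skipped, model = model,
      hr = if (is.null(hr_summary)) NULL else
        list(r1_pct = as.list(hr_summary$robustness$r1_pct),
             r2_pct = as.list(hr_summary$robustness$r2_pct),
             fused_coverage_pct = hr_summary$fused_coverage_pct,
             fused_mae_bpm = hr_summary$fused_mae_bpm,
             modality_mae_bpm = hr_summary$modality_mae),
      br = if (is.null(br_eval)) NULL else list(
        mae_brpm = br_eval$mae_brpm, sd_brpm = br_eval$sd_brpm,
        cv_mae_brpm = br_eval$cv_mae_brpm,
        importance = as.list(br_eval$importance),
        per_subject = br_eval$per_subject,
        single_channel = br_eval$single_channel))
    jsonlite::write_json(json, file.path(out_dir, "report.json"),
                         auto_unbox = TRUE, digits = NA, null = "null",
                         dataframe = "rows")
  }
  report
}

# Pool the long HR table: validity matrix -> R1/R2; per-modality and fused
# MAE against the reference-channel estimate.
summarize_hr <- function(hr_all) {
  # every window contributes one row per modality, in a fixed order, so the
  # per-modality subsets align row-for-row
  wide_valid <- vapply(DEVICE_CHANNELS,
                       function(m) hr_all$valid[hr_all$modality == m],
                       logical(sum(hr_all$modality == DEVICE_CHANNELS[1])))
  if (!is.matrix(wide_valid)) wide_valid <- t(wide_valid)  # single window
  rob <- robustness(wide_valid)
  ref <- hr_all[hr_all$modality == "reference", ]
  ref_key <- paste(ref$subject_id, ref$task, ref$window_index)
  modality_mae <- list()
  for (m in c(DEVICE_CHANNELS, "fused")) {
    sub <- hr_all[hr_all$modality == m, ]
    r <- ref$hr_bpm[match(paste(sub$subject_id, sub$task, sub$window_index),
                          ref_key)]
    ok <- sub$valid & !is.na(r)
    modality_mae[[m]] <- if (any(ok))
      unname(mae_std(sub$hr_bpm[ok], r[ok])[["mae"]]) else NA_real_
  }
  fused <- hr_all[hr_all$modality == "fused", ]
  list(robustness = rob,
       fused_coverage_pct = 100 * mean(fused$valid),
       fused_mae_bpm = modality_mae$fused,
       modality_mae = modality_mae)
}

#' @export
print.cf_pipeline_report <- function(x, ...) {
  cat(sprintf("<cf_pipeline_report> %d subjects (%d skipped)\n",
              length(x$subjects), length(x$skipped)))
  cat("  HR R1 (%):",
      paste(sprintf("%s %.0f", names(x$hr$robustness$r1_pct),
                    x$hr$robustness$r1_pct), collapse = ", "), "\n")
  cat(sprintf("  fused HR: coverage %.1f%%, MAE %.2f bpm vs reference\n",
              x$hr$fused_coverage_pct, x$hr$fused_mae_bpm))
  if (!is.null(x$br$eval))
    cat(sprintf("  fused BR (LOSO, %s): MAE %.2f +/- %.2f breaths/min\n",
                x$model, x$br$eval$mae_brpm, x$br$eval$sd_brpm))
  invisible(x)
}
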