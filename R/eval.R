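# Evaluation: MAE +/- sd of absolute error, the R1/R2 robustness measures,
# and leave-one-subject-out (LOSO) evaluation of the breathing-rate fusion
# with an inner 5-fold cross-validation diagnostic and averaged fold
# importances.

#' Mean absolute error and spread of the absolute error
#'
#' @param predictions,truth Equal-length numeric vectors (>= 1 pair).
#' @return Named numeric `c(mae, sd)`: mean absolute error and the sample
#'   standard deviation of the absolute errors.
#' @export
mae_std <- function(predictions, truth) {
  stopifnot(length(predictions) == length(truth), length(truth) >= 1L)
  ae <- abs(predictions - truth)
  c(mae = mean(ae), sd = if (length(ae) > 1L) stats::sd(ae) else 0)
}

#' R1/R2 robustness measures from a validity matrix
#'
#' R1 is the percentage of analysis windows with a valid HR estimate, per
#' modality; R2 is the distribution of per-window modality coverage, binned
#' at multiples of 20% (five modalities).
#'
#' @param valid Logical matrix, windows x modalities (named columns).
#' @return List with `r1_pct` (named vector, percent per modality),
#'   `r2_pct` (percentage of windows in each coverage bin, named by coverage
#'   percent) and `r2_weighted_mean_pct` (average per-window coverage).
#' @export
robustness <- function(valid) {
  valid <- as.matrix(valid)
  stopifnot(is.logical(valid), nrow(valid) >= 1L)
  r1 <- 100 * colMeans(valid)
  cov_pct <- 100 * rowMeans(valid)
  bins <- round(seq(0, 100, length.out = ncol(valid) + 1L), 6)
  counts <- vapply(bins, function(b) sum(abs(cov_pct - b) < 1e-6), numeric(1))
  r2 <- 100 * counts / nrow(valid)
  names(r2) <- paste0(round(bins), "%")
  list(r1_pct = r1, r2_pct = r2, r2_weighted_mean_pct = mean(cov_pct))
}

#' Per-slot single-channel breathing-rate errors
#'
#' MAE of each individual feature slot against truth, over the windows where
#' that slot produced an estimate.
#'
#' @param features A `cf_br_features`-style data.frame holding the 14 slot
#'   columns and `truth_brpm`.
#' @return data.frame with `slot`, `n_present`, `mae_brpm`, `sd_brpm`.
#' @export
single_channel_mae <- function(features) {
  slots <- intersect(BR_SLOTS, names(features))
  rows <- lapply(slots, function(s) {
    ok <- !is.na(features[[s]])
    if (!any(ok))
      return(data.frame(slot = s, n_present = 0L, mae_brpm = NA_real_,
                        sd_brpm = NA_real_))
    ms <- mae_std(features[[s]][ok], features$truth_brpm[ok])
    data.frame(slot = s, n_present = sum(ok), mae_brpm = ms[["mae"]],
               sd_brpm = ms[["sd"]])
  })
  do.call(rbind, rows)
}

#' Leave-one-subject-out evaluation of the breathing-rate fusion
#'
#' For each subject, fits the fusion model on every other subject's windows
#' and predicts the held-out windows; training and held-out subject-id sets
#' are disjoint in every fold. An inner k-fold cross-validation on each
#' training pool is reported as a diagnostic only. Feature importances
#' (bagged trees) are averaged across the LOSO fits and renormalized.
#'
#' @param features data.frame with `subject_id`, `truth_brpm` and the 14
#'   feature-slot columns (one row per window).
#' @param model,seed,... Passed to [br_fusion()].
#' @param cv_folds Inner cross-validation fold count (diagnostic).
#' @return List of class `cf_eval_report`: `mae_brpm`, `sd_brpm` (pooled over
#'   all held-out predictions), `per_subject` (data.frame), `predictions`
#'   (data.frame with `subject_id`, `truth_brpm`, `pred_brpm`), `cv_mae_brpm`
#'   (mean inner-CV MAE), `importance` (averaged, bagged trees only),
#'   `single_channel` (per-slot MAE table), `model`, `n_subjects`.
#' @export
loso_evaluate <- function(features, model = "bagged_trees", seed = NULL,
                          cv_folds = 5L, ...) {
  stopifnot(is.data.frame(features),
            all(c("subject_id", "truth_brpm") %in% names(features)))
  slots <- intersect(BR_SLOTS, names(features))
  subjects <- unique(features$subject_id)
  usable <- vapply(subjects, function(s)
    sum(features$subject_id == s & !is.na(features$truth_brpm)) > 0,
    logical(1))
  if (any(!usable))
    message("skipping subjects with no usable windows: ",
            paste(subjects[!usable], collapse = ", "))
  subjects <- subjects[usable]
  if (length(subjects) < 3L)
    stop("LOSO evaluation requires at least 3 subjects with usable windows")
  preds <- list()
  cv_maes <- numeric(0)
  imps <- list()
  for (i in seq_along(subjects)) {
    held <- subjects[i]
    tr <- features[features$subject_id != held, , drop = FALSE]
    te <- features[features$subject_id == held, , drop = FALSE]
    fit <- suppressWarnings(
      br_fusion(tr[slots], tr$truth_brpm, model = model,
                seed = if (is.null(seed)) NULL else seed + i, ...))
    p <- predict(fit, te[slots])
    preds[[i]] <- data.frame(subject_id = held, truth_brpm = te$truth_brpm,
                             pred_brpm = p)
    cv_maes <- c(cv_maes, inner_cv_mae(tr, slots, model, cv_folds,
                                       seed = if (is.null(seed)) NULL
                                              else seed + 1000L + i, ...))
    if (model == "bagged_trees") imps[[i]] <- feature_importance(fit)
  }
  predictions <- do.call(rbind, preds)
  pooled <- mae_std(predictions$pred_brpm, predictions$truth_brpm)
  per_subject <- do.call(rbind, lapply(preds, function(d) {
    ms <- mae_std(d$pred_brpm, d$truth_brpm)
    data.frame(subject_id = d$subject_id[1], n_windows = nrow(d),
               mae_brpm = ms[["mae"]], sd_brpm = ms[["sd"]])
  }))
  importance <- NULL
  if (length(imps)) {
    importance <- Reduce(`+`, imps) / length(imps)
    if (sum(importance) > 0) importance <- importance / sum(importance)
  }
  structure(list(mae_brpm = pooled[["mae"]], sd_brpm = pooled[["sd"]],
                 per_subject = per_subject, predictions = predictions,
                 cv_mae_brpm = mean(cv_maes), importance = importance,
                 single_channel = single_channel_mae(features),
                 model = model, n_subjects = length(subjects)),
            class = "cf_eval_report")
}

# Inner k-fold CV MAE on a training pool (diagnostic; does not alter the
# LOSO fit).
inner_cv_mae <- function(tr, slots, model, cv_folds, seed = NULL, ...) {
  n <- nrow(tr)
  if (n < 2L * cv_folds) return(NA_real_)
  if (!is.null(seed)) set.seed(seed)
  fold <- sample(rep(seq_len(cv_folds), length.out = n))
  err <- numeric(0)
  for (k in seq_len(cv_folds)) {
    if (sum(fold != k) < 8L) next
    fit <- suppressWarnings(br_fusion(tr[fold != k, slots, drop = FALSE],
                                      tr$truth_brpm[fold != k],
                                      model = model, seed = seed, ...))
    p <- predict(fit, tr[fold == k, slots, drop = FALSE])
    err <- c(err, abs(p - tr$truth_brpm[fold == k]))
  }
  if (!length(err)) NA_real_ else mean(err)
}

#' @export
print.cf_eval_report <- function(x, ...) {
  cat(sprintf("<cf_eval_report> %s fusion, %d subjects (LOSO)\n",
              x$model, x$n_subjects))
  cat(sprintf("  pooled BR MAE %.2f +/- %.2f breaths/min (inner %s-CV MAE %.2f)\n",
              x$mae_brpm, x$sd_brpm, "5-fold", x$cv_mae_brpm))
  if (!is.null(x$importance)) {
    top <- sort(x$importance, decreasing = TRUE)[1:3]
    cat("  top importances:",
        paste(sprintf("%s %.2f", names(top), top), collapse = ", "), "\n")
  }
  invisible(x)
}
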