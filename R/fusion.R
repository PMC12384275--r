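# Breathing-rate fusion models behind one interface: a bagged decision-tree
# ensemble (136 bootstrap trees, minimum leaf size 4, 13 of the 14 predictors
# sampled at each split) and a robust linear model fitted by iteratively
# reweighted least squares with Huber weights. The ensemble is the default
# used for headline metrics; the robust linear fit is the lighter
# alternative.

#' Fit a breathing-rate fusion model
#'
#' Fuses the fourteen per-channel breathing-rate estimates into one
#' prediction. Columns that are entirely absent are dropped (with a warning);
#' remaining absences are imputed with the training-set median of the slot
#' (absence correlates with channel noise, and both model families need
#' complete rows). Medians are stored so prediction imputes identically.
#'
#' @param x Numeric matrix or data.frame of feature slots (windows x slots);
#'   `NA` marks an absent estimate.
#' @param y Numeric target breathing rates, breaths/min.
#' @param model `"bagged_trees"` (default) or `"robust_linear"`.
#' @param n_learners Number of bootstrap trees.
#' @param min_leaf Minimum terminal-node size.
#' @param predictors_to_sample Predictors sampled at each split (capped at
#'   the number of retained columns).
#' @param seed RNG seed for the bootstrap (fixed seed => identical model).
#' @param huber_k Huber tuning constant for the robust linear model.
#' @param tol IRLS convergence tolerance on the coefficient change.
#' @param max_iter Maximum IRLS iterations; non-convergence returns the last
#'   iterate with a warning.
#' @return An object of class `br_fusion` with methods [predict.br_fusion()],
#'   [coef.br_fusion()], [print.br_fusion()], [summary.br_fusion()] and
#'   [feature_importance()].
#' @export
br_fusion <- function(x, y, model = c("bagged_trees", "robust_linear"),
                      n_learners = 136L, min_leaf = 4L,
                      predictors_to_sample = 13L, seed = NULL,
                      huber_k = 1.345, tol = 1e-6, max_iter = 50L) {
  model <- match.arg(model)
  x <- as.data.frame(x)
  stopifnot(nrow(x) == length(y), nrow(x) >= 8L)
  all_na <- vapply(x, function(col) all(is.na(col)), logical(1))
  if (any(all_na)) {
    warning("dropping all-absent feature columns: ",
            paste(names(x)[all_na], collapse = ", "))
    x <- x[, !all_na, drop = FALSE]
  }
  medians <- vapply(x, function(col) stats::median(col, na.rm = TRUE),
                    numeric(1))
  xi <- impute_medians(x, medians)
  fit <- if (model == "bagged_trees") {
    if (!is.null(seed)) set.seed(seed)
    randomForest::randomForest(
      x = xi, y = y, ntree = n_learners,
      mtry = min(predictors_to_sample, ncol(xi)),
      nodesize = min_leaf, importance = TRUE)
  } else {
    irls_huber(as.matrix(xi), y, k = huber_k, tol = tol, max_iter = max_iter)
  }
  structure(list(model = model, fit = fit, medians = medians,
                 features = names(medians), n = nrow(xi),
                 config = list(n_learners = n_learners, min_leaf = min_leaf,
                               predictors_to_sample = predictors_to_sample,
                               huber_k = huber_k, tol = tol,
                               max_iter = max_iter, seed = seed)),
            class = "br_fusion")
}

impute_medians <- function(x, medians) {
  for (nm in names(medians)) {
    col <- x[[nm]]
    col[is.na(col)] <- medians[[nm]]
    x[[nm]] <- col
  }
  x
}

# Iteratively reweighted least squares with Huber weights. The scale is
# re-estimated each iteration as the MAD of the residuals; weights are 1 for
# |r| <= k*s and k*s/|r| beyond. Converges to OLS on outlier-free data.
irls_huber <- function(X, y, k = 1.345, tol = 1e-6, max_iter = 50L) {
  Xd <- cbind(`(Intercept)` = 1, X)
  beta <- qr.coef(qr(Xd), y)
  beta[is.na(beta)] <- 0
  converged <- FALSE
  iter <- 0L
  for (iter in seq_len(max_iter)) {
    r <- y - drop(Xd %*% beta)
    s <- stats::mad(r, center = 0)
    if (s < 1e-10 * max(1, stats::mad(y))) { converged <- TRUE; break }
    w <- ifelse(abs(r) <= k * s, 1, k * s / abs(r))
    sw <- sqrt(w)
    beta_new <- qr.coef(qr(Xd * sw), y * sw)
    beta_new[is.na(beta_new)] <- 0
    delta <- max(abs(beta_new - beta))
    beta <- beta_new
    if (delta < tol * max(1, max(abs(beta)))) { converged <- TRUE; break }
  }
  if (!converged)
    warning(sprintf("IRLS did not converge in %d iterations; returning last iterate",
                    max_iter))
  r <- y - drop(Xd %*% beta)
  structure(list(coefficients = beta, residuals = r, iterations = iter,
                 converged = converged, k = k), class = "cf_irls")
}

#' @export
predict.br_fusion <- function(object, newdata, ...) {
  newdata <- as.data.frame(newdata)
  missing_cols <- setdiff(object$features, names(newdata))
  for (nm in missing_cols) newdata[[nm]] <- NA_real_
  xi <- impute_medians(newdata[object$features], object$medians)
  if (object$model == "bagged_trees") {
    unname(stats::predict(object$fit, xi))
  } else {
    unname(drop(cbind(1, as.matrix(xi)) %*% object$fit$coefficients))
  }
}

#' @export
coef.br_fusion <- function(object, ...) {
  if (object$model != "robust_linear")
    stop("coefficients are defined for the robust_linear model only")
  object$fit$coefficients
}

#' @export
print.br_fusion <- function(x, ...) {
  cat(sprintf("<br_fusion> %s on %d windows, %d feature slots\n",
              x$model, x$n, length(x$features)))
  if (x$model == "bagged_trees")
    cat(sprintf("  %d trees, min leaf %d, %d predictors per split\n",
                x$config$n_learners, x$config$min_leaf,
                min(x$config$predictors_to_sample, length(x$features))))
  else
    cat(sprintf("  IRLS (Huber k = %.3f), %d iterations, converged: %s\n",
                x$config$huber_k, x$fit$iterations, x$fit$converged))
  invisible(x)
}

#' @export
summary.br_fusion <- function(object, ...) {
  out <- list(model = object$model, n = object$n,
              features = object$features)
  if (object$model == "bagged_trees") {
    out$importance <- feature_importance(object)
  } else {
    out$coefficients <- object$fit$coefficients
    out$iterations <- object$fit$iterations
    out$converged <- object$fit$converged
  }
  structure(out, class = "summary.br_fusion")
}

#' @export
print.summary.br_fusion <- function(x, ...) {
  cat(sprintf("br_fusion %s fit on %d windows\n", x$model, x$n))
  if (!is.null(x$importance)) {
    cat("normalized out-of-bag permutation importance:\n")
    print(round(sort(x$importance, decreasing = TRUE), 3))
  } else {
    cat("coefficients:\n"); print(round(x$coefficients, 4))
  }
  invisible(x)
}

#' Normalized feature importance of the bagged-tree fusion model
#'
#' Out-of-bag permutation importance (mean decrease in accuracy), clipped at
#' zero and normalized to sum to one over the full 14-slot vector (dropped
#' all-absent slots receive weight zero).
#'
#' @param object A fitted `br_fusion` with `model = "bagged_trees"`.
#' @return Named numeric vector over the 14 feature slots, summing to 1.
#' @export
feature_importance <- function(object) {
  stopifnot(inherits(object, "br_fusion"))
  if (object$model != "bagged_trees")
    stop("feature importance is defined for the bagged_trees model")
  imp <- randomForest::importance(object$fit, type = 1, scale = FALSE)[, 1]
  imp <- pmax(imp, 0)
  slots <- if (all(names(imp) %in% BR_SLOTS)) BR_SLOTS else names(imp)
  out <- stats::setNames(rep(0, length(slots)), slots)
  out[names(imp)] <- imp
  if (sum(out) > 0) out <- out / sum(out)
  out
}
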