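# Fusion models: bagged-tree ensemble, IRLS robust linear regression,
# prediction, importance.

make_features <- function(n, seed = 1, informative = "x1") {
  set.seed(seed)
  y <- runif(n, 4, 20)
  x <- as.data.frame(matrix(rnorm(n * 14), n, 14))
  names(x) <- paste0("x", 1:14)
  x[[informative]] <- y
  list(x = x, y = y)
}

test_that("bagged trees fit the identity feature and are deterministic", {
  d <- make_features(200, seed = 2)
  fit <- br_fusion(d$x, d$y, seed = 10)
  expect_s3_class(fit, "br_fusion")
  pred <- predict(fit, d$x)
  expect_lte(mean(abs(pred - d$y)), 0.3)
  fit2 <- br_fusion(d$x, d$y, seed = 10)
  expect_identical(pred, predict(fit2, d$x))
  # constant target -> constant prediction
  fitc <- suppressWarnings(br_fusion(d$x, rep(7, 200), seed = 1))
  expect_equal(unname(predict(fitc, d$x[1:5, ])), rep(7, 5), tolerance = 1e-9)
})

test_that("all-absent feature columns are dropped with a warning and imputation is stored", {
  d <- make_features(100, seed = 3)
  d$x$x14 <- NA_real_
  d$x$x2[1:40] <- NA
  expect_warning(fit <- br_fusion(d$x, d$y, seed = 1), "x14")
  expect_false("x14" %in% fit$features)
  expect_equal(fit$medians[["x2"]],
               stats::median(d$x$x2, na.rm = TRUE))
  # prediction tolerates absent entries and absent columns
  nd <- d$x[1:3, ]
  nd$x2 <- NA_real_
  expect_length(predict(fit, nd), 3)
})

test_that("IRLS reproduces OLS on outlier-free data to 1e-6", {
  set.seed(4)
  x <- matrix(runif(100, 0, 10), ncol = 1)
  colnames(x) <- "x"
  y <- 2 * x[, 1] + 1
  fit <- br_fusion(data.frame(x = x[, 1]), y, model = "robust_linear")
  expect_equal(unname(coef(fit)), c(1, 2), tolerance = 1e-6)
  expect_equal(unname(coef(fit)),
               unname(coef(stats::lm(y ~ x))), tolerance = 1e-6)
  # constant target: slope 0, intercept at the mean
  fitc <- br_fusion(data.frame(x = x[, 1]), rep(3.5, 100),
                    model = "robust_linear")
  expect_equal(unname(coef(fitc)), c(3.5, 0), tolerance = 1e-9)
})

test_that("Huber weighting resists gross outliers better than least squares", {
  set.seed(5)
  n <- 200
  x <- runif(n, 0, 10)
  y <- 2 * x + 1 + rnorm(n, sd = 0.1)
  out <- sample(n, 10)
  y[out] <- y[out] + 40
  fit <- br_fusion(data.frame(x = x), y, model = "robust_linear")
  b_irls <- unname(coef(fit))
  b_ols <- unname(coef(stats::lm(y ~ x)))
  err <- function(b) sum((b - c(1, 2))^2)
  expect_lt(err(b_irls), err(b_ols))
  # cross-check against the reference IRLS implementation
  rf <- MASS::rlm(y ~ x, psi = MASS::psi.huber, k = 1.345, maxit = 50)
  expect_equal(b_irls, unname(coef(rf)), tolerance = 5e-3)
})

test_that("out-of-bag permutation importance is normalized and finds the signal", {
  d <- make_features(200, seed = 6, informative = "x7")
  fit <- br_fusion(d$x, d$y, seed = 2)
  imp <- feature_importance(fit)
  expect_equal(sum(imp), 1)
  expect_true(all(imp >= 0))
  expect_equal(names(which.max(imp)), "x7")
  expect_gt(imp[["x7"]], 0.5)
  expect_error(feature_importance(br_fusion(d$x, d$y, model = "robust_linear")),
               "bagged_trees")
})

test_that("pure-noise features share importance evenly under the permutation null", {
  sums <- NULL
  for (s in 1:20) {
    set.seed(100 + s)
    x <- as.data.frame(matrix(rnorm(60 * 14), 60, 14))
    names(x) <- paste0("x", 1:14)
    y <- runif(60, 4, 20)
    imp <- feature_importance(br_fusion(x, y, seed = s))
    sums <- if (is.null(sums)) imp else sums + imp
  }
  mean_imp <- sums / 20
  expect_lt(max(mean_imp), 3 / 14)
})
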