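# Evaluation metrics and the leave-one-subject-out protocol.

test_that("MAE and absolute-error spread follow the arithmetic", {
  expect_equal(mae_std(c(1, 2, 3), c(1, 2, 3)), c(mae = 0, sd = 0))
  expect_equal(mae_std(c(2, 4), c(1, 2)), c(mae = 1.5, sd = sqrt(0.5)),
               tolerance = 1e-9)
  expect_equal(mae_std(c(5, 6, 7) + 2.5, c(5, 6, 7)),
               c(mae = 2.5, sd = 0))
  expect_error(mae_std(numeric(0), numeric(0)))
})

test_that("R1 and R2 robustness measures summarize the validity matrix", {
  v <- matrix(TRUE, 11, 5,
              dimnames = list(NULL, c("g", "r", "i", "b", "s")))
  rob <- robustness(v)
  expect_equal(unname(rob$r1_pct), rep(100, 5))
  expect_equal(unname(rob$r2_pct[["100%"]]), 100)
  v[, "s"] <- c(rep(TRUE, 4), rep(FALSE, 7))
  rob <- robustness(v)
  expect_equal(rob$r1_pct[["s"]], 100 * 4 / 11, tolerance = 1e-9)
  expect_equal(rob$r2_pct[["80%"]], 100 * 7 / 11, tolerance = 1e-9)
  # a single window with 4 of 5 valid lands in the 80% bin
  rob1 <- robustness(matrix(c(TRUE, TRUE, TRUE, TRUE, FALSE), 1, 5))
  expect_equal(unname(rob1$r2_pct[["80%"]]), 100)
})

fake_features <- function(n_subjects, windows = 4, seed = 1,
                          informative = TRUE) {
  set.seed(seed)
  rows <- lapply(seq_len(n_subjects), function(i) {
    truth <- rep(c(6, 10), length.out = windows)
    x <- if (isTRUE(informative) || i %in% informative)
      truth + rnorm(windows, sd = 0.01) else rnorm(windows, 8, 2)
    d <- as.data.frame(matrix(rnorm(windows * 13), windows, 13))
    names(d) <- setdiff(cardiofuse:::BR_SLOTS, "bw_bioz")
    cbind(data.frame(subject_id = sprintf("S%02d", i), truth_brpm = truth,
                     bw_bioz = x), d)
  })
  do.call(rbind, rows)
}

test_that("LOSO pools held-out predictions and reports near-zero error on perfect features", {
  f <- fake_features(5)
  rep <- loso_evaluate(f, model = "robust_linear")
  expect_s3_class(rep, "cf_eval_report")
  expect_equal(rep$n_subjects, 5)
  expect_lt(rep$mae_brpm, 0.1)
  expect_equal(nrow(rep$per_subject), 5)
  expect_setequal(unique(rep$predictions$subject_id), unique(f$subject_id))
})

test_that("a held-out subject's own mapping never leaks into its fold", {
  # only subject 4 has an informative feature; every training pool that
  # could teach the model to use it excludes subject 4, so its held-out
  # predictions cannot track its truth
  f <- fake_features(4, windows = 8, informative = 4)
  rep <- loso_evaluate(f, model = "bagged_trees", seed = 2)
  ps <- rep$per_subject
  expect_gt(ps$mae_brpm[ps$subject_id == "S04"], 1)
  # and the pooled predictions cover exactly the held-out subjects
  expect_setequal(unique(rep$predictions$subject_id), unique(f$subject_id))
})

test_that("LOSO refuses cohorts below three usable subjects", {
  expect_error(loso_evaluate(fake_features(2)), "3 subjects")
  f <- fake_features(3)
  f$truth_brpm[f$subject_id == "S03"] <- NA
  expect_error(suppressMessages(loso_evaluate(f)), "3 subjects")
})

test_that("single-channel errors are computed per slot over present estimates", {
  f <- fake_features(3)
  f$bw_bioz[1] <- NA
  sc <- single_channel_mae(f)
  expect_equal(nrow(sc), 14)
  expect_equal(sc$n_present[sc$slot == "bw_bioz"], nrow(f) - 1L)
  expect_lt(sc$mae_brpm[sc$slot == "bw_bioz"], 0.1)
  expect_gt(min(sc$mae_brpm[sc$slot != "bw_bioz"]), 1)
})

test_that("white noise does not improve fused heart-rate accuracy", {
  mae_at <- function(sd_noise) {
    maes <- vapply(1:10, function(s) {
      nz <- noise_config(white_sd = sd_noise)
      rec <- simulate_subject("S", mst = 2, hr_bpm = 72, noise = nz,
                              task_spans = study_task_spans("sedentary"),
                              seed = 300 + s)
      h <- estimate_hr(rec)
      f <- h[h$modality == "fused", ]
      mean(abs(f$hr_bpm[f$valid] - 72))
    }, numeric(1))
    mean(maes)
  }
  expect_lte(mae_at(0.02), mae_at(0.8) + 1e-6)
})
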