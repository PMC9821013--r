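test_that("accuracy is the fraction of correct predictions", {
  expect_equal(accuracy(confusion_counts(c(1, 1, 0, 0, 0),
                                         c(1, 1, 0, 0, 0))), 1)
  expect_equal(accuracy(confusion_counts(c(1, 0), c(0, 1))), 0)
  counts <- structure(list(TP = 42, TN = 43, FP = 8, FN = 7),
                      class = "confusion_counts")
  expect_equal(accuracy(counts), 0.85)
  expect_error(accuracy(confusion_counts(integer(0), integer(0))),
               "zero evaluated")
  # label encodings agree
  expect_equal(confusion_counts(c("active", "inactive"), c(1, 0)),
               confusion_counts(c(1, 0), c("active", "inactive")))
})

test_that("ROC AUC agrees with pair counting and an external reference", {
  expect_equal(roc_auc(c(0.9, 0.8, 0.3, 0.2), c(1, 0, 1, 0)), 0.75)
  expect_equal(roc_auc(c(3, 4, 1, 2), c(1, 1, 0, 0)), 1) # separated
  expect_equal(roc_auc(rep(0.5, 6), c(1, 0, 1, 0, 1, 0)), 0.5) # all tied
  expect_error(roc_auc(c(0.1, 0.2), c(1, 1)), "both classes")

  set.seed(19)
  for (i in 1:10) {
    n <- 40
    labels <- rbinom(n, 1, 0.4)
    scores <- round(runif(n), 1) # heavy ties
    auc <- roc_auc(scores, labels)
    # trapezoidal sweep equals the rank formulation exactly
    expect_equal(auc, qsarboost:::rank_auc(scores, labels),
                 tolerance = 1e-12)
    if (requireNamespace("pROC", quietly = TRUE)) {
      ref <- as.numeric(pROC::auc(pROC::roc(labels, scores, quiet = TRUE,
                                            direction = "<")))
      expect_equal(auc, ref, tolerance = 1e-12)
    }
  }
})

test_that("regression metrics match their defining formulas", {
  expect_equal(mae(c(7.52, 8.30), c(6.95, 8.02)), 0.425)
  expect_equal(round(mae(c(7.52, 8.30), c(6.95, 8.02)), 2), 0.43)
  expect_equal(mae(7.52, 6.95), 0.57)
  expect_equal(mae(c(1, 2, 3), c(1, 2, 3)), 0)
  expect_error(mae(numeric(0), numeric(0)), "empty")

  y <- c(5.1, 6.4, 7.2, 8.0, 6.6)
  expect_equal(r2_score(y, y), 1)
  expect_equal(r2_score(y, rep(mean(y), 5)), 0)
  # anti-correlated predictions fall below the mean predictor
  flipped <- mean(y) - (y - mean(y))
  expect_lt(r2_score(y, flipped), 0)
  expect_error(r2_score(rep(2, 4), 1:4), "constant")

  # two-pass reference computation
  set.seed(20)
  yy <- rnorm(50); pp <- yy + rnorm(50, sd = 0.3)
  expect_equal(mae(yy, pp), sum(abs(yy - pp)) / 50, tolerance = 1e-12)
  expect_equal(r2_score(yy, pp),
               1 - sum((yy - pp)^2) / sum((yy - mean(yy))^2),
               tolerance = 1e-12)
})

test_that("cross-validation folds partition the data evenly", {
  folds <- make_folds(10, k = 5, seed = 3)
  expect_equal(unname(table(folds)), rep(2L, 5), ignore_attr = TRUE)
  folds <- make_folds(23, k = 5, seed = 3)
  expect_true(all(abs(table(folds) - 23 / 5) <= 1))
  expect_equal(sort(unique(folds)), 1:5)
  expect_identical(make_folds(23, 5, seed = 3), folds)
  expect_error(make_folds(10, k = 1), "at least 2")
  expect_error(make_folds(3, k = 5), "at least k rows")
})

test_that("k-fold CV estimates generalization near the external estimate", {
  ds <- generate_dataset(small_spec(seed = 31, n = 420, noise_sd = 0.4))
  x <- ds$features$values
  tr <- seq_len(280)
  ext <- setdiff(seq_len(420), tr)
  params <- boost_params(n_estimators = 60, loss = "squared", alpha = 0.1)
  cv <- kfold_cv(x[tr, ], ds$pic50[tr], params, k = 5, seed = 7)
  expect_equal(nrow(cv$folds), 10) # 5 folds x 2 metrics
  expect_equal(sort(unique(cv$fold_id)), 1:5)
  fit <- qsar_boost(x[tr, ], ds$pic50[tr], params)
  q2_ext <- r2_score(ds$pic50[ext], predict(fit, x[ext, ]))
  q2_cv <- cv$summary$mean[cv$summary$metric == "q2"]
  expect_gt(q2_cv, 0.4)
  expect_lt(abs(q2_cv - q2_ext), 0.2) # within sampling noise

  # classification CV reports accuracy and AUC
  yc <- as.integer(ds$records$activity == "active")
  cvc <- kfold_cv(x[tr, ], yc[tr],
                  boost_params(n_estimators = 40, loss = "logistic"),
                  k = 3, seed = 7)
  expect_setequal(cvc$summary$metric, c("accuracy", "auc"))
  expect_true(all(cvc$summary$mean > 0.5))
})

test_that("Y-randomization destroys the structure-activity signal", {
  ds <- generate_dataset(small_spec(seed = 37, n = 260))
  x <- ds$features$values
  tr <- seq_len(180); ext <- 181:260
  params <- boost_params(n_estimators = 40, loss = "squared", alpha = 0.1)
  rep0 <- y_randomization(x[tr, ], ds$pic50[tr], x[ext, ], ds$pic50[ext],
                          params, n_shuffles = 0, seed = 5)
  expect_equal(rep0$n_shuffles, 0)
  expect_gt(rep0$original_q2, 0.5)
  expect_true(is.na(rep0$q2_mean))

  rep5 <- y_randomization(x[tr, ], ds$pic50[tr], x[ext, ], ds$pic50[ext],
                          params, n_shuffles = 5, seed = 5)
  expect_equal(length(rep5$q2), 5)
  # scrambled models predict the true activities worse than their mean
  expect_lt(rep5$q2_mean, 0)
  expect_lt(rep5$r2_mean, 0)
  expect_equal(rep5$original_q2, rep0$original_q2)
  # determinism under the master seed
  rep5b <- y_randomization(x[tr, ], ds$pic50[tr], x[ext, ], ds$pic50[ext],
                           params, n_shuffles = 5, seed = 5)
  expect_identical(rep5$q2, rep5b$q2)
})

test_that("standardized residuals standardize exactly and flag outliers", {
  # five residuals with one extreme point: frozen hand evaluation of the
  # standardization (mean 20, sample SD sqrt(2000))
  ad <- standardized_residuals(c(0, 0, 0, 0, 100), rep(0, 5))
  expect_equal(ad$table$z, c(rep(-20 / sqrt(2000), 4), 80 / sqrt(2000)),
               tolerance = 1e-12)
  # with n = 5 the largest attainable |z| is (n-1)/sqrt(n) < 3: no outlier
  expect_equal(length(ad$outlier_ids), 0)

  # a long run of zeros plus one extreme point exceeds |z| = 3
  y <- c(rep(0, 20), 100)
  ad <- standardized_residuals(y, rep(0, 21),
                               ids = c(sprintf("c%02d", 1:20), "extreme"))
  r <- y
  z_ref <- (r - mean(r)) / sd(r) # independent two-pass computation
  expect_equal(ad$table$z, z_ref, tolerance = 1e-12)
  expect_gt(z_ref[21], 3)
  expect_equal(ad$outlier_ids, "extreme")

  # standardization identity on any non-degenerate input
  set.seed(23)
  ad <- standardized_residuals(rnorm(50, 6.5), rnorm(50, 6.5))
  expect_lt(abs(mean(ad$table$z)), 1e-9)
  expect_equal(sd(ad$table$z), 1, tolerance = 1e-12)

  # all residuals equal: zero variance handled with a warning
  expect_warning(ad0 <- standardized_residuals(c(1, 1, 1), c(0, 0, 0)),
                 "zero residual variance")
  expect_equal(ad0$table$z, c(0, 0, 0))
  expect_equal(length(ad0$outlier_ids), 0)
  expect_error(standardized_residuals(1:2, 1:2), "three")
})

test_that("validation tables flatten heterogeneous reports", {
  yr <- structure(list(n_shuffles = 2, original_r2 = 0.9, original_q2 = 0.7,
                       r2 = c(-1, -0.8), q2 = c(-0.9, -0.7),
                       r2_mean = -0.9, r2_sd = 0.14, q2_mean = -0.8,
                       q2_sd = 0.14), class = "yrand_report")
  tab <- validation_table(external = c(q2 = 0.7, mae = 0.4),
                          y_randomization = yr)
  expect_equal(nrow(tab), 6)
  expect_setequal(unique(tab$context), c("external", "y_randomization"))
  expect_equal(tab$value[tab$metric == "randomized_q2"], -0.8)
})
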