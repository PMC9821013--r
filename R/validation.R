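#' Confusion counts for a binary classification
#'
#' @param truth Observed classes (`"active"`/`"inactive"`, logical, or 0/1).
#' @param predicted Predicted classes in the same encoding.
#' @return A `confusion_counts` list with `TP`, `TN`, `FP`, `FN`.
#' @export
confusion_counts <- function(truth, predicted) {
  truth <- as_binary_label(truth)
  predicted <- as_binary_label(predicted)
  if (length(truth) != length(predicted)) {
    stop("truth and predicted must have the same length")
  }
  structure(list(TP = sum(truth == 1 & predicted == 1),
                 TN = sum(truth == 0 & predicted == 0),
                 FP = sum(truth == 0 & predicted == 1),
                 FN = sum(truth == 1 & predicted == 0)),
            class = "confusion_counts")
}

as_binary_label <- function(x) {
  if (is.character(x) || is.factor(x)) {
    x <- as.character(x)
    bad <- setdiff(unique(x), c("active", "inactive"))
    if (length(bad) > 0) stop("unknown class labels: ",
                              paste(bad, collapse = ", "))
    as.integer(x == "active")
  } else {
    x <- as.integer(x)
    if (!all(x %in% c(0L, 1L))) stop("labels must be 0/1")
    x
  }
}

#' Classification accuracy
#'
#' `(TP + TN) / (TP + TN + FP + FN)`.
#'
#' @param counts A [confusion_counts()] object.
#' @return Fraction of correct predictions.
#' @export
#' @examples
#' accuracy(confusion_counts(c(1, 1, 0, 0), c(1, 1, 0, 1)))  # 0.75
accuracy <- function(counts) {
  stopifnot(inherits(counts, "confusion_counts"))
  total <- counts$TP + counts$TN + counts$FP + counts$FN
  if (total == 0) stop("cannot compute accuracy of zero evaluated pairs")
  (counts$TP + counts$TN) / total
}

#' Area under the ROC curve
#'
#' Sweeps the unique scores as thresholds in descending order, tracing the
#' curve of true-positive rate against false-positive rate, and integrates
#' by trapezoids. With tied scores this equals the rank (pair-counting)
#' formulation: the probability that a random positive outscores a random
#' negative, with ties counted one half.
#'
#' @param scores Numeric classifier scores (higher = more likely active).
#' @param labels Class labels (both classes must be present).
#' @return The AUC in `[0, 1]`.
#' @export
#' @examples
#' roc_auc(c(0.9, 0.8, 0.3, 0.2), c(1, 0, 1, 0))  # 0.75
roc_auc <- function(scores, labels) {
  labels <- as_binary_label(labels)
  if (length(scores) != length(labels)) {
    stop("scores and labels must have the same length")
  }
  n_pos <- sum(labels == 1)
  n_neg <- sum(labels == 0)
  if (n_pos == 0 || n_neg == 0) {
    stop("both classes must be present to compute an AUC")
  }
  # threshold sweep: group rows by descending unique score
  ord <- order(-scores)
  s <- scores[ord]
  l <- labels[ord]
  group <- cumsum(!duplicated(s))
  tp <- cumsum(l)
  fp <- cumsum(1 - l)
  last <- !duplicated(group, fromLast = TRUE) # last row of each tie group
  tpr <- c(0, tp[last] / n_pos)
  fpr <- c(0, fp[last] / n_neg)
  sum(diff(fpr) * (utils::head(tpr, -1) + utils::tail(tpr, -1)) / 2)
}

# rank formulation used as an internal cross-check of roc_auc
rank_auc <- function(scores, labels) {
  labels <- as_binary_label(labels)
  r <- rank(scores, ties.method = "average")
  n_pos <- sum(labels == 1)
  n_neg <- sum(labels == 0)
  (sum(r[labels == 1]) - n_pos * (n_pos + 1) / 2) / (n_pos * n_neg)
}

#' Mean absolute error
#'
#' @param y Experimental values (pIC50 units).
#' @param y_hat Predicted values.
#' @return `mean(|y - y_hat|)`.
#' @export
#' @examples
#' mae(c(7.52, 8.30), c(6.95, 8.02))  # 0.425, i.e. 0.43 at two decimals
mae <- function(y, y_hat) {
  if (length(y) == 0) stop("cannot compute the MAE of an empty set")
  if (length(y) != length(y_hat)) stop("y and y_hat must have equal length")
  mean(abs(y - y_hat))
}

#' Coefficient of determination (R2 on training data, Q2 on held-out data)
#'
#' `1 - sum((y - y_hat)^2) / sum((y - mean(y))^2)`. Unbounded below:
#' predictions worse than the mean of `y` give a negative value, the regime
#' expected of Y-randomized models.
#'
#' @param y Experimental values; must not be constant.
#' @param y_hat Predicted values.
#' @return The coefficient of determination.
#' @export
r2_score <- function(y, y_hat) {
  if (length(y) < 2) stop("at least two pairs are required")
  if (length(y) != length(y_hat)) stop("y and y_hat must have equal length")
  sst <- sum((y - mean(y))^2)
  if (sst == 0) stop("y is constant; the coefficient of determination is undefined")
  1 - sum((y - y_hat)^2) / sst
}

#' Partition indices into k folds
#'
#' Random fold assignment with sizes differing by at most one,
#' deterministic for a fixed seed.
#'
#' @param n Number of rows.
#' @param k Number of folds.
#' @param seed Integer seed.
#' @return Integer vector of fold ids in `1..k`.
#' @export
make_folds <- function(n, k = 5, seed = 1) {
  if (k < 2) stop("k must be at least 2")
  if (n < k) stop("need at least k rows for k folds")
  old <- local_seed(seed)
  on.exit(restore_seed(old), add = TRUE)
  sample(rep_len(seq_len(k), n))
}

# Seed handling: scope RNG use so callers' RNG streams are not disturbed.
local_seed <- function(seed) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  set.seed(seed)
  old
}
restore_seed <- function(old) {
  if (is.null(old)) {
    rm(".Random.seed", envir = globalenv())
  } else {
    assign(".Random.seed", old, envir = globalenv())
  }
}

#' k-fold cross-validation of the boosted learner
#'
#' Partitions the data into `k` folds, trains on each complement, and
#' evaluates on the held-out fold. Regression models report Q2 and MAE per
#' fold; classification models report accuracy and AUC. Aggregates are
#' given as mean and sample standard deviation across folds.
#'
#' @param x,y Features and labels.
#' @param params A [boost_params()] object.
#' @param k Number of folds.
#' @param seed Seed for the fold assignment.
#' @param backend Learner backend passed to [qsar_boost()].
#' @return A `cv_report`: `folds` (per-fold metric data frame), `summary`
#'   (metric, mean, sd), and the fold assignment.
#' @export
kfold_cv <- function(x, y, params, k = 5, seed = 1, backend = "exact") {
  x <- as_feature_values(x)
  fold_id <- make_folds(nrow(x), k = k, seed = seed)
  per_fold <- lapply(seq_len(k), function(f) {
    tr <- fold_id != f
    fit <- qsar_boost(x[tr, , drop = FALSE], y[tr], params, backend = backend)
    pred <- predict(fit, x[!tr, , drop = FALSE])
    if (params$loss == "squared") {
      data.frame(fold = f, metric = c("q2", "mae"),
                 value = c(r2_score(y[!tr], pred), mae(y[!tr], pred)))
    } else {
      cls <- ifelse(pred >= 0.5, 1L, 0L)
      data.frame(fold = f, metric = c("accuracy", "auc"),
                 value = c(accuracy(confusion_counts(y[!tr], cls)),
                           roc_auc(pred, y[!tr])))
    }
  })
  folds <- do.call(rbind, per_fold)
  summary <- do.call(rbind, lapply(split(folds, folds$metric), function(d) {
    data.frame(metric = d$metric[1], mean = mean(d$value),
               sd = stats::sd(d$value))
  }))
  rownames(summary) <- NULL
  structure(list(folds = folds, summary = summary, fold_id = fold_id,
                 k = k, seed = seed),
            class = "cv_report")
}

#' @export
print.cv_report <- function(x, ...) {
  cat(sprintf("%d-fold cross-validation\n", x$k))
  for (i in seq_len(nrow(x$summary))) {
    cat(sprintf("  %-9s %.3f ± %.3f\n", x$summary$metric[i],
                x$summary$mean[i], x$summary$sd[i]))
  }
  invisible(x)
}

#' Y-randomization (Y-scrambling) robustness test
#'
#' Refits the regressor `n_shuffles` times on training data whose labels
#' have been randomly permuted (features untouched, label multiset
#' preserved), with hyperparameters identical to the original model. Every
#' scrambled model is scored against the true experimental activities: R2
#' on the training compounds and Q2 on the untouched external set. Because
#' the scrambled models fit noise, both scores collapse to negative values
#' for a model capturing a real structure-activity relationship, while the
#' original R2/Q2 stay high.
#'
#' @param x_train,y_train Training features and labels (the pairs that get
#'   scrambled).
#' @param x_ext,y_ext External test set, never scrambled.
#' @param params Hyperparameters shared by the original and scrambled fits.
#' @param n_shuffles Number of permutations (0 returns only the original
#'   metrics).
#' @param seed Master seed; each shuffle derives its own sub-seed.
#' @param backend Learner backend passed to [qsar_boost()].
#' @return A `yrand_report` with the original R2/Q2, per-shuffle values, and
#'   their mean and sample SD.
#' @export
y_randomization <- function(x_train, y_train, x_ext, y_ext, params,
                            n_shuffles = 100, seed = 1, backend = "exact") {
  x_train <- as_feature_values(x_train)
  x_ext <- as_feature_values(x_ext)
  fit <- qsar_boost(x_train, y_train, params, backend = backend)
  original_r2 <- r2_score(y_train, predict(fit, x_train))
  original_q2 <- r2_score(y_ext, predict(fit, x_ext))
  r2 <- q2 <- numeric(n_shuffles)
  if (n_shuffles > 0) {
    old <- local_seed(seed)
    on.exit(restore_seed(old), add = TRUE)
    for (s in seq_len(n_shuffles)) {
      y_perm <- sample(y_train)
      fit_s <- qsar_boost(x_train, y_perm, params, backend = backend)
      # scored against the true activities, not the permuted ones
      r2[s] <- r2_score(y_train, predict(fit_s, x_train))
      q2[s] <- r2_score(y_ext, predict(fit_s, x_ext))
    }
  }
  structure(list(n_shuffles = n_shuffles,
                 original_r2 = original_r2, original_q2 = original_q2,
                 r2 = r2, q2 = q2,
                 r2_mean = if (n_shuffles) mean(r2) else NA_real_,
                 r2_sd = if (n_shuffles > 1) stats::sd(r2) else NA_real_,
                 q2_mean = if (n_shuffles) mean(q2) else NA_real_,
                 q2_sd = if (n_shuffles > 1) stats::sd(q2) else NA_real_),
            class = "yrand_report")
}

#' @export
print.yrand_report <- function(x, ...) {
  cat(sprintf("Y-randomization (n = %d shuffles)\n", x$n_shuffles))
  cat(sprintf("  original:   R2 = %.2f, Q2 = %.2f\n",
              x$original_r2, x$original_q2))
  if (x$n_shuffles > 0) {
    cat(sprintf("  randomized: R2 = %.2f ± %.2f, Q2 = %.2f ± %.2f\n",
                x$r2_mean, x$r2_sd, x$q2_mean, x$q2_sd))
  }
  invisible(x)
}

#' Applicability domain by standardized prediction residuals
#'
#' Standardizes the residuals `r_i = y_i - y_hat_i` to
#' `z_i = (r_i - mean(r)) / sd(r)` (sample SD) and flags compounds with
#' `|z| > 3` as outside the applicability domain, i.e. unreliable
#' predictions.
#'
#' @param y Experimental pIC50 values.
#' @param y_hat Predicted pIC50 values.
#' @param ids Optional compound identifiers (defaults to row numbers).
#' @param z_cutoff Outlier threshold on `|z|`.
#' @return An `ad_report` with the residual table (`id`, `residual`, `z`,
#'   `outlier`) and the flagged ids.
#' @export
standardized_residuals <- function(y, y_hat, ids = NULL, z_cutoff = 3) {
  if (length(y) < 3) stop("at least three compounds are required")
  if (length(y) != length(y_hat)) stop("y and y_hat must have equal length")
  if (is.null(ids)) ids <- as.character(seq_along(y))
  r <- y - y_hat
  s <- stats::sd(r)
  if (s == 0) {
    warning("zero residual variance; all standardized residuals set to 0")
    z <- rep(0, length(r))
  } else {
    z <- (r - mean(r)) / s
  }
  outlier <- abs(z) > z_cutoff
  table <- data.frame(id = as.character(ids), residual = r, z = z,
                      outlier = outlier, stringsAsFactors = FALSE)
  structure(list(table = table, outlier_ids = table$id[outlier],
                 z_cutoff = z_cutoff),
            class = "ad_report")
}

#' @export
print.ad_report <- function(x, ...) {
  cat(sprintf("Applicability domain (|z| > %g): %d of %d compounds flagged\n",
              x$z_cutoff, length(x$outlier_ids), nrow(x$table)))
  if (length(x$outlier_ids) > 0) {
    cat("  outliers:", paste(x$outlier_ids, collapse = ", "), "\n")
  }
  invisible(x)
}

#' Write an applicability-domain report as CSV
#'
#' @param report An `ad_report` from [standardized_residuals()].
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_ad_report <- function(report, path) {
  stopifnot(inherits(report, "ad_report"))
  utils::write.csv(report$table, path, row.names = FALSE)
  invisible(path)
}

#' Flatten evaluation metrics into a tidy table
#'
#' Collects metrics from heterogeneous report objects (named numeric
#' vectors, `cv_report`, `yrand_report`) into one data frame with columns
#' `context`, `metric`, `value`, `sd`, the on-disk exchange format of the
#' validation stage.
#'
#' @param ... Named report objects; names become the `context` column.
#' @return A data frame.
#' @export
validation_table <- function(...) {
  reports <- list(...)
  stopifnot(length(names(reports)) == length(reports))
  rows <- lapply(names(reports), function(ctx) {
    r <- reports[[ctx]]
    if (inherits(r, "cv_report")) {
      data.frame(context = ctx, metric = r$summary$metric,
                 value = r$summary$mean, sd = r$summary$sd)
    } else if (inherits(r, "yrand_report")) {
      data.frame(context = ctx,
                 metric = c("original_r2", "original_q2",
                            "randomized_r2", "randomized_q2"),
                 value = c(r$original_r2, r$original_q2, r$r2_mean, r$q2_mean),
                 sd = c(NA, NA, r$r2_sd, r$q2_sd))
    } else {
      data.frame(context = ctx, metric = names(r), value = as.numeric(r),
                 sd = NA_real_)
    }
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
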