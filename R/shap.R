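#' Shapley-value attribution of ensemble predictions
#'
#' Attributes each prediction (raw margin: log-odds for the classifier,
#' pIC50 for the regressor) to the individual fingerprints. The value
#' function of a feature subset is the conditional expectation obtained by
#' tree traversal: at a split on an in-subset feature the observed branch is
#' followed, at a split on an out-of-subset feature the children are
#' averaged with their training-cover weights. For the package's own
#' (`"exact"` backend) models the Shapley values are computed exhaustively
#' over all feature subsets, which is limited to 15 features; wider models
#' must be trained with the `"xgboost"` backend, whose tree-explainer
#' (TreeSHAP) satisfies the same local-accuracy contract at any width.
#'
#' Local accuracy holds row by row: `base_value` plus the row sum of the
#' contributions equals the model's raw margin.
#'
#' @param model A `qsar_booster`.
#' @param x Rows to explain (matrix matching the training schema).
#' @param max_exhaustive Safety cap on the exhaustive path.
#' @return A `shap_matrix`: `contributions` (n x p), `base_value`, and
#'   `units` (`"margin"`).
#' @export
shap_values <- function(model, x, max_exhaustive = 15) {
  stopifnot(inherits(model, "qsar_booster"))
  x <- as_feature_values(x)
  x <- check_schema(model, x)
  p <- ncol(x)
  if (model$backend == "xgboost") {
    contrib <- predict(model$xgb, xgboost::xgb.DMatrix(x, nthread = 1),
                       predcontrib = TRUE)
    base <- contrib[, ncol(contrib)]
    contributions <- contrib[, -ncol(contrib), drop = FALSE]
  } else {
    if (p > max_exhaustive) {
      stop("exhaustive Shapley attribution enumerates all 2^p feature ",
           "subsets and is limited to ", max_exhaustive, " features (got ",
           p, "); train with backend = 'xgboost' for wide fingerprint blocks")
    }
    res <- exhaustive_shap(model, x)
    contributions <- res$contributions
    base <- rep(res$base_value, nrow(x))
  }
  colnames(contributions) <- model$feature_names
  structure(list(contributions = contributions,
                 base_value = unname(base),
                 units = "margin"),
            class = "shap_matrix")
}

# Exhaustive Shapley values for an exact-backend ensemble.
exhaustive_shap <- function(model, x) {
  p <- length(model$feature_names)
  n <- nrow(x)
  lr <- model$params$learning_rate
  n_subsets <- bitwShiftL(1L, p)
  # Shapley kernel weights by subset size: |S|! (p - |S| - 1)! / p!
  wt <- exp(lfactorial(0:(p - 1)) + lfactorial(p - 1 - 0:(p - 1)) -
              lfactorial(p))
  subset_size <- vapply(0:(n_subsets - 1), bit_count, integer(1))
  contributions <- matrix(0, n, p)
  v <- numeric(n_subsets)
  for (row in seq_len(n)) {
    xi <- x[row, ]
    for (mask in 0:(n_subsets - 1)) {
      total <- 0
      for (tree in model$trees) {
        total <- total + tree_cond_expect(tree, xi, mask)
      }
      v[mask + 1] <- lr * total
    }
    for (j in seq_len(p)) {
      bit <- bitwShiftL(1L, j - 1L)
      without <- which(bitwAnd(0:(n_subsets - 1), bit) == 0L)
      phi <- sum(wt[subset_size[without] + 1] *
                   (v[without + bit] - v[without]))
      contributions[row, j] <- phi
    }
  }
  list(contributions = contributions,
       base_value = model$base_margin + v[1])
}

bit_count <- function(mask) {
  n <- 0L
  while (mask > 0L) {
    n <- n + bitwAnd(mask, 1L)
    mask <- bitwShiftR(mask, 1L)
  }
  n
}

# Conditional expectation of a single tree output given the features in the
# bitmask; out-of-subset splits average children by training cover.
tree_cond_expect <- function(tree, xi, mask) {
  recurse <- function(id) {
    j <- tree$feature[id + 1]
    if (j < 0) return(tree$value[id + 1])
    if (bitwAnd(mask, bitwShiftL(1L, j)) != 0L) {
      child <- if (xi[j + 1] < tree$threshold[id + 1]) tree$yes[id + 1]
               else tree$no[id + 1]
      recurse(child)
    } else {
      yes <- tree$yes[id + 1]
      no <- tree$no[id + 1]
      w_yes <- tree$cover[yes + 1]
      w_no <- tree$cover[no + 1]
      (w_yes * recurse(yes) + w_no * recurse(no)) / (w_yes + w_no)
    }
  }
  recurse(0L)
}

#' @export
print.shap_matrix <- function(x, ...) {
  cat(sprintf("Shapley attribution: %d rows x %d features (%s units), mean base value %.4f\n",
              nrow(x$contributions), ncol(x$contributions), x$units,
              mean(x$base_value)))
  invisible(x)
}

#' Rank fingerprints by global Shapley importance
#'
#' Orders features by the mean absolute Shapley contribution over the
#' explained rows (descending; ties broken by column order) and reports a
#' sign tendency. When the explained feature rows are supplied, the
#' tendency is the sign of the correlation between the feature value and
#' its contribution (positive: higher fingerprint values push the
#' prediction up); without them it falls back to the sign of the mean
#' signed contribution, which is close to zero for well-balanced features.
#' Features with zero contribution everywhere are omitted, so a constant
#' model yields an empty ranking.
#'
#' @param shap A `shap_matrix` from [shap_values()].
#' @param top_k Number of features to keep (capped at the number of
#'   contributing features).
#' @param x Optional feature matrix of the explained rows (same order).
#' @return A data frame with `rank`, `feature`, `mean_abs_shap`,
#'   `direction`.
#' @export
rank_importance <- function(shap, top_k = 20, x = NULL) {
  stopifnot(inherits(shap, "shap_matrix"))
  contrib <- shap$contributions
  mean_abs <- colMeans(abs(contrib))
  keep <- which(mean_abs > 0)
  ord <- keep[order(-mean_abs[keep], keep)]
  ord <- utils::head(ord, top_k)
  tendency <- vapply(ord, function(j) {
    if (!is.null(x)) {
      xj <- feature_values(x)[, j]
      if (stats::sd(xj) == 0 || stats::sd(contrib[, j]) == 0) return(0)
      sign(stats::cor(xj, contrib[, j]))
    } else {
      sign(mean(contrib[, j]))
    }
  }, numeric(1))
  data.frame(rank = seq_along(ord),
             feature = colnames(contrib)[ord],
             mean_abs_shap = unname(mean_abs[ord]),
             direction = c("negative", "none", "positive")[tendency + 2],
             stringsAsFactors = FALSE)
}

#' Write a Shapley importance ranking as CSV
#'
#' @param ranking Data frame from [rank_importance()].
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_importance <- function(ranking, path) {
  utils::write.csv(ranking, path, row.names = FALSE)
  invisible(path)
}
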