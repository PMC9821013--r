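#' Hyperparameters for the boosted-tree learner
#'
#' Collects the hyperparameters of the second-order gradient-boosted
#' regression-tree learner. The defaults are the settings used for the
#' KRAS G12C classification head; the regression head differs only in
#' `loss = "squared"` and `alpha = 0.1`.
#'
#' @param n_estimators Number of boosting rounds (trees), `K >= 1`.
#' @param max_depth Maximum tree depth (root at depth 0 counts as one split
#'   level), `>= 1`.
#' @param gamma Per-leaf complexity penalty; a split must reduce the
#'   regularized objective by more than `gamma` to be kept.
#' @param lambda L2 penalty on leaf weights.
#' @param alpha L1 penalty on leaf weights (soft-thresholds the gradient sum).
#' @param learning_rate Shrinkage applied to every tree's output, in (0, 1].
#' @param base_score Initial prediction. For squared loss this is the starting
#'   prediction itself; for logistic loss it is a probability whose logit is
#'   the starting margin (0.5 gives margin 0).
#' @param loss `"squared"` for pIC50 regression, `"logistic"` for the
#'   active/inactive classifier.
#' @param min_child_weight Minimum hessian mass required in each child of a
#'   split (for squared loss the hessian is 1 per row, so this is a row count).
#'
#' @return An object of class `boost_params`.
#' @export
#' @examples
#' boost_params(loss = "logistic")               # classification head
#' boost_params(loss = "squared", alpha = 0.1)   # regression head
boost_params <- function(n_estimators = 100L, max_depth = 4L, gamma = 0,
                         lambda = 0.5, alpha = 0, learning_rate = 0.3,
                         base_score = 0.5, loss = c("logistic", "squared"),
                         min_child_weight = 1) {
  loss <- match.arg(loss)
  n_estimators <- as.integer(n_estimators)
  max_depth <- as.integer(max_depth)
  stopifnot(n_estimators >= 0L, max_depth >= 1L, gamma >= 0, lambda >= 0,
            alpha >= 0, learning_rate > 0, learning_rate <= 1,
            min_child_weight >= 0)
  if (loss == "logistic" && (base_score <= 0 || base_score >= 1)) {
    stop("base_score must be a probability in (0, 1) for logistic loss")
  }
  structure(list(n_estimators = n_estimators, max_depth = max_depth,
                 gamma = gamma, lambda = lambda, alpha = alpha,
                 learning_rate = learning_rate, base_score = base_score,
                 loss = loss, min_child_weight = min_child_weight),
            class = "boost_params")
}

#' @export
print.boost_params <- function(x, ...) {
  cat("Boosting hyperparameters (", x$loss, " loss):\n", sep = "")
  cat(sprintf("  K = %d trees, max_depth = %d, learning_rate = %g\n",
              x$n_estimators, x$max_depth, x$learning_rate))
  cat(sprintf("  gamma = %g, lambda = %g, alpha = %g, base_score = %g\n",
              x$gamma, x$lambda, x$alpha, x$base_score))
  invisible(x)
}

base_margin_of <- function(params) {
  if (params$loss == "logistic") {
    stats::qlogis(params$base_score)
  } else {
    params$base_score
  }
}

#' First and second derivatives of the loss
#'
#' Per-row gradient and hessian of the loss with respect to the current
#' margin. For squared loss `l = (margin - y)^2 / 2` these are
#' `g = margin - y`, `h = 1`; for logistic loss on labels in `{0, 1}`,
#' `p = sigmoid(margin)` gives `g = p - y`, `h = p (1 - p)`.
#'
#' @param loss `"squared"` or `"logistic"`.
#' @param y Observed values (pIC50, or 0/1 class labels).
#' @param margin Current raw model output (pre-sigmoid for logistic).
#' @return A list with numeric vectors `g` and `h`.
#' @export
#' @examples
#' grad_hess("squared", y = 1, margin = 0)   # g = -1, h = 1
#' grad_hess("logistic", y = 1, margin = 0)  # g = -0.5, h = 0.25
grad_hess <- function(loss, y, margin) {
  if (length(y) != length(margin)) {
    stop("y and margin must have the same length")
  }
  if (identical(loss, "squared")) {
    list(g = margin - y, h = rep(1, length(y)))
  } else if (identical(loss, "logistic")) {
    if (!all(y %in% c(0, 1))) stop("logistic loss requires labels in {0, 1}")
    p <- stats::plogis(margin)
    list(g = p - y, h = p * (1 - p))
  } else {
    stop("unknown loss kind: ", loss)
  }
}

#' Closed-form optimal leaf weight
#'
#' Minimizes the per-leaf second-order objective
#' `G w + (H + lambda) w^2 / 2 + alpha |w|` giving
#' `w* = -soft(G, alpha) / (H + lambda)` where `soft` shrinks `G` toward zero
#' by `alpha` and clips to zero inside the L1 dead zone.
#'
#' @param G Sum of gradients over the leaf's instance set.
#' @param H Sum of hessians over the leaf's instance set.
#' @param lambda L2 penalty.
#' @param alpha L1 penalty.
#' @return The optimal leaf weight.
#' @export
#' @examples
#' leaf_weight(G = -4, H = 2, lambda = 0)  # 2
leaf_weight <- function(G, H, lambda, alpha = 0) {
  if (any(H + lambda <= 0)) stop("H + lambda must be positive")
  soft <- sign(G) * pmax(abs(G) - alpha, 0)
  -soft / (H + lambda)
}

#' Objective reduction of a candidate split
#'
#' The decrease in the regularized second-order objective obtained by
#' replacing one leaf with two, each at its optimal weight:
#' `gain = [score(L) + score(R) - score(L+R)] / 2 - gamma` with
#' `score(G, H) = soft(G, alpha)^2 / (H + lambda)`.
#'
#' @param G_L,H_L Gradient/hessian sums of the left child.
#' @param G_R,H_R Gradient/hessian sums of the right child.
#' @param gamma Per-leaf penalty charged for the extra leaf.
#' @param lambda L2 penalty.
#' @param alpha L1 penalty.
#' @return The gain; a split is worth making only when the gain is positive.
#' @export
#' @examples
#' split_gain(G_L = -2, H_L = 1, G_R = 2, H_R = 1, gamma = 0, lambda = 0)  # 4
split_gain <- function(G_L, H_L, G_R, H_R, gamma = 0, lambda = 0, alpha = 0) {
  score <- function(G, H) {
    s <- pmax(abs(G) - alpha, 0)
    s * s / (H + lambda)
  }
  0.5 * (score(G_L, H_L) + score(G_R, H_R) -
           score(G_L + G_R, H_L + H_R)) - gamma
}

#' Fit a single regression tree to gradient statistics
#'
#' Exact greedy construction: every feature and every midpoint between
#' consecutive distinct feature values inside a node is scored with
#' [split_gain()]; the best strictly positive gain wins (ties go to the
#' lowest feature index, then the lowest threshold). Leaves carry the
#' [leaf_weight()] of their instance set.
#'
#' @param x Numeric feature matrix (rows = compounds).
#' @param g,h Gradient and hessian vectors from [grad_hess()].
#' @param params A [boost_params()] object.
#' @return A `qsar_tree`: a list of parallel node vectors (`feature` is the
#'   0-based split column or -1 for a leaf, `threshold`, `yes`/`no` child ids,
#'   `value` leaf weight, `cover` training rows, `sum_hess`).
#' @export
fit_tree <- function(x, g, h, params = boost_params(loss = "squared")) {
  x <- as_feature_values(x)
  if (nrow(x) < 1) stop("at least one row is required")
  tree <- .cpp_fit_tree(x, as.numeric(g), as.numeric(h),
                        params$max_depth, params$gamma, params$lambda,
                        params$alpha, params$min_child_weight)
  structure(tree, class = "qsar_tree")
}

#' @export
print.qsar_tree <- function(x, ...) {
  n_leaf <- sum(x$feature < 0)
  cat(sprintf("Regression tree: %d nodes (%d leaves)\n",
              length(x$feature), n_leaf))
  invisible(x)
}

as_feature_values <- function(x) {
  if (is.data.frame(x)) x <- as.matrix(x)
  if (!is.matrix(x)) x <- matrix(x, ncol = 1)
  storage.mode(x) <- "double"
  if (anyNA(x)) stop("feature matrix contains missing values")
  x
}

#' Fit a gradient-boosted tree ensemble
#'
#' Trains `K` regression trees sequentially: each round computes the
#' gradient/hessian of the loss at the current margin, fits an exact greedy
#' tree to them, and advances the margin by `learning_rate` times the tree
#' output. Two backends satisfy the same contract: `"exact"` is the package's
#' own learner (deterministic, fully enumerated splits) and `"xgboost"`
#' delegates to the xgboost library with single-threaded exact split finding.
#'
#' @param x Feature matrix with column names (the feature schema).
#' @param y pIC50 values (squared loss) or 0/1 labels (logistic loss).
#' @param params A [boost_params()] object.
#' @param backend `"exact"` or `"xgboost"`.
#' @return A `qsar_booster` model object.
#' @export
#' @examples
#' x <- matrix(c(0, 0, 1, 1), ncol = 1, dimnames = list(NULL, "bit1"))
#' fit <- qsar_boost(x, c(1, 1, 3, 3),
#'                   boost_params(n_estimators = 1, learning_rate = 1,
#'                                lambda = 0, base_score = 0,
#'                                loss = "squared"))
#' predict(fit, x)  # 1 1 3 3
qsar_boost <- function(x, y, params = boost_params(),
                       backend = c("exact", "xgboost")) {
  backend <- match.arg(backend)
  x <- as_feature_values(x)
  y <- as.numeric(y)
  if (nrow(x) < 2) stop("at least two rows are required")
  if (length(y) != nrow(x)) stop("label length must match the number of rows")
  if (!all(is.finite(y))) stop("labels must be finite")
  if (params$loss == "logistic" && !all(y %in% c(0, 1))) {
    stop("logistic loss requires labels in {0, 1}")
  }
  feature_names <- colnames(x)
  if (is.null(feature_names)) {
    feature_names <- paste0("f", seq_len(ncol(x)))
    colnames(x) <- feature_names
  }
  model <- list(params = params, feature_names = feature_names,
                base_margin = base_margin_of(params), backend = backend)
  if (backend == "exact") {
    trees <- .cpp_fit_ensemble(x, y, params$loss, params$n_estimators,
                               params$max_depth, params$gamma, params$lambda,
                               params$alpha, params$learning_rate,
                               model$base_margin, params$min_child_weight)
    model$trees <- lapply(trees, function(t) structure(t, class = "qsar_tree"))
  } else {
    model$xgb <- fit_xgboost_backend(x, y, params)
  }
  structure(model, class = "qsar_booster")
}

fit_xgboost_backend <- function(x, y, params) {
  objective <- if (params$loss == "logistic") "binary:logistic"
               else "reg:squarederror"
  dtrain <- xgboost::xgb.DMatrix(x, label = y, nthread = 1)
  xgb_params <- list(objective = objective, max_depth = params$max_depth,
                     eta = params$learning_rate, gamma = params$gamma,
                     lambda = params$lambda, alpha = params$alpha,
                     base_score = params$base_score,
                     min_child_weight = params$min_child_weight,
                     tree_method = "exact", nthread = 1)
  xgboost::xgb.train(xgb_params, dtrain, nrounds = params$n_estimators,
                     verbose = 0)
}

#' @export
print.qsar_booster <- function(x, ...) {
  cat(sprintf("Boosted ensemble (%s loss, %s backend): %d trees, %d features\n",
              x$params$loss, x$backend, x$params$n_estimators,
              length(x$feature_names)))
  invisible(x)
}

check_schema <- function(model, x) {
  if (is.null(colnames(x))) {
    if (ncol(x) != length(model$feature_names)) {
      stop("feature matrix has ", ncol(x), " columns but the model expects ",
           length(model$feature_names))
    }
    colnames(x) <- model$feature_names
    return(x)
  }
  missing <- setdiff(model$feature_names, colnames(x))
  if (length(missing) > 0) {
    stop("feature schema mismatch; missing columns: ",
         paste(utils::head(missing, 5), collapse = ", "),
         if (length(missing) > 5) ", ..." else "")
  }
  x[, model$feature_names, drop = FALSE]
}

#' Predict from a boosted ensemble
#'
#' The raw margin is the base margin plus `learning_rate` times the sum of
#' tree outputs. For logistic loss, `type = "response"` applies the sigmoid
#' and `type = "class"` thresholds the probability at 0.5; for squared loss
#' the margin is the prediction.
#'
#' @param object A `qsar_booster`.
#' @param newdata Feature matrix matching the training schema.
#' @param type `"response"` (default), `"margin"`, or `"class"`.
#' @param ... Unused.
#' @return Numeric predictions, or a character vector of
#'   `"active"`/`"inactive"` for `type = "class"`.
#' @export
predict.qsar_booster <- function(object, newdata,
                                 type = c("response", "margin", "class"),
                                 ...) {
  type <- match.arg(type)
  x <- as_feature_values(newdata)
  x <- check_schema(object, x)
  if (object$backend == "exact") {
    margin <- .cpp_predict_margin(object$trees, x,
                                  object$params$learning_rate,
                                  object$base_margin)
  } else {
    margin <- predict(object$xgb, xgboost::xgb.DMatrix(x, nthread = 1),
                      outputmargin = TRUE)
  }
  if (type == "margin") return(margin)
  response <- if (object$params$loss == "logistic") stats::plogis(margin)
              else margin
  if (type == "response") return(response)
  if (object$params$loss != "logistic") {
    stop("type = 'class' requires a logistic-loss model")
  }
  ifelse(response >= 0.5, "active", "inactive")
}

#' Serialize a boosted ensemble to JSON
#'
#' Writes the hyperparameters, feature schema, and every tree's node table to
#' a JSON document that [load_model_json()] restores bit-identically
#' (predictions before and after a round trip are equal). Only the `"exact"`
#' backend is serialized this way; xgboost-backend models are saved with the
#' library's own serializer next to the JSON header.
#'
#' @param model A `qsar_booster`.
#' @param path Output file path (`.json`).
#' @return `path`, invisibly.
#' @export
save_model_json <- function(model, path) {
  stopifnot(inherits(model, "qsar_booster"))
  doc <- list(format = "qsarboost-model", version = 1L,
              params = unclass(model$params),
              feature_names = model$feature_names,
              base_margin = model$base_margin,
              backend = model$backend)
  if (model$backend == "exact") {
    doc$trees <- lapply(model$trees, unclass)
  } else {
    raw_path <- paste0(path, ".ubj")
    xgboost::xgb.save(model$xgb, raw_path)
    doc$xgb_file <- basename(raw_path)
  }
  # 17 significant digits round-trip IEEE doubles exactly
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = I(17),
                       pretty = FALSE)
  invisible(path)
}

#' Restore a boosted ensemble saved by [save_model_json()]
#'
#' @param path Path to the JSON document.
#' @return A `qsar_booster`.
#' @export
load_model_json <- function(path) {
  doc <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (!identical(doc$format, "qsarboost-model")) {
    stop("not a qsarboost model file: ", path)
  }
  p <- doc$params
  params <- boost_params(n_estimators = p$n_estimators,
                         max_depth = p$max_depth, gamma = p$gamma,
                         lambda = p$lambda, alpha = p$alpha,
                         learning_rate = p$learning_rate,
                         base_score = p$base_score, loss = p$loss,
                         min_child_weight = p$min_child_weight)
  model <- list(params = params, feature_names = doc$feature_names,
                base_margin = doc$base_margin, backend = doc$backend)
  if (identical(doc$backend, "exact")) {
    model$trees <- lapply(seq_len(nrow_of_trees(doc$trees)), function(i) {
      structure(tree_row(doc$trees, i), class = "qsar_tree")
    })
  } else {
    model$xgb <- xgboost::xgb.load(file.path(dirname(path), doc$xgb_file))
  }
  structure(model, class = "qsar_booster")
}

# jsonlite simplifies a homogeneous list of trees to a data.frame of
# list-columns; normalize both shapes back to a plain list of node tables.
nrow_of_trees <- function(trees) {
  if (is.data.frame(trees)) nrow(trees) else length(trees)
}
tree_row <- function(trees, i) {
  t <- if (is.data.frame(trees)) lapply(trees, `[[`, i) else trees[[i]]
  list(feature = as.integer(t$feature), threshold = as.numeric(t$threshold),
       yes = as.integer(t$yes), no = as.integer(t$no),
       value = as.numeric(t$value), cover = as.numeric(t$cover),
       sum_hess = as.numeric(t$sum_hess))
}

#' Grid-search hyperparameter selection by k-fold cross-validation
#'
#' Evaluates every row of a user-supplied hyperparameter grid with
#' [kfold_cv()] and returns the grid annotated with the CV score
#' (mean Q2 for squared loss, mean accuracy for logistic), ordered best
#' first.
#'
#' @param x,y Training features and labels.
#' @param grid A data frame whose columns are [boost_params()] argument names.
#' @param loss Loss kind shared by all grid points.
#' @param k Number of folds.
#' @param seed Seed controlling the fold assignment (shared across the grid).
#' @param backend Learner backend passed to [qsar_boost()].
#' @return The grid with a `cv_score` column, sorted decreasing.
#' @export
grid_search_cv <- function(x, y, grid, loss = "squared", k = 5, seed = 1,
                           backend = "exact") {
  stopifnot(is.data.frame(grid), nrow(grid) > 0)
  scores <- vapply(seq_len(nrow(grid)), function(i) {
    args <- as.list(grid[i, , drop = FALSE])
    args$loss <- loss
    params <- do.call(boost_params, args)
    cv <- kfold_cv(x, y, params, k = k, seed = seed, backend = backend)
    if (loss == "squared") cv$summary$mean[cv$summary$metric == "q2"]
    else cv$summary$mean[cv$summary$metric == "accuracy"]
  }, numeric(1))
  grid$cv_score <- scores
  grid[order(-grid$cv_score), , drop = FALSE]
}
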