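test_that("gradient and hessian follow the loss derivatives", {
  gh <- grad_hess("squared", y = 1, margin = 0)
  expect_equal(gh$g, -1)
  expect_equal(gh$h, 1)

  gh <- grad_hess("logistic", y = 1, margin = 0)
  expect_equal(gh$g, -0.5)
  expect_equal(gh$h, 0.25)

  # saturation: a confidently correct prediction contributes nothing
  gh <- grad_hess("logistic", y = 1, margin = 30)
  expect_lt(abs(gh$g), 1e-12)
  expect_lt(abs(gh$h), 1e-12)

  # hessian bounds
  set.seed(1)
  m <- rnorm(100, sd = 3)
  gh <- grad_hess("logistic", rbinom(100, 1, 0.5), m)
  expect_true(all(gh$h >= 0 & gh$h <= 0.25))

  expect_error(grad_hess("huber", 1, 0), "unknown loss")
  expect_error(grad_hess("logistic", 2, 0), "labels in \\{0, 1\\}")
})

test_that("leaf weight is the closed-form minimizer with L1 soft-threshold", {
  expect_equal(leaf_weight(G = -4, H = 2, lambda = 0), 2)
  # shrinkage limit
  expect_lt(abs(leaf_weight(G = -4, H = 2, lambda = 1e9)), 1e-8)
  # L1 dead zone
  expect_identical(leaf_weight(G = 0.05, H = 1, lambda = 0, alpha = 0.1), 0)

  # the closed form agrees with direct numeric minimization
  set.seed(3)
  for (i in 1:25) {
    G <- rnorm(1, sd = 5); H <- runif(1, 0.1, 10)
    lambda <- runif(1, 0, 3); alpha <- runif(1, 0, 1)
    w <- leaf_weight(G, H, lambda, alpha)
    obj <- function(w) G * w + 0.5 * (H + lambda) * w^2 + alpha * abs(w)
    expect_lt(abs(obj(w) - leaf_objective_min(G, H, lambda, alpha)), 1e-9)
  }

  # monotone shrinkage: larger lambda never increases |w|
  lambdas <- seq(0, 5, by = 0.5)
  w <- abs(leaf_weight(rep(-3, length(lambdas)), 2, lambdas))
  expect_true(all(diff(w) <= 0))

  expect_error(leaf_weight(1, 0, 0), "positive")
})

test_that("split gain equals the brute-force objective reduction", {
  expect_equal(split_gain(-2, 1, 2, 1, gamma = 0, lambda = 0), 4)
  expect_equal(split_gain(-2, 1, 2, 1, gamma = 10, lambda = 0), -6)

  set.seed(11)
  for (i in 1:40) {
    GL <- rnorm(1, sd = 4); GR <- rnorm(1, sd = 4)
    HL <- runif(1, 0.5, 8); HR <- runif(1, 0.5, 8)
    gamma <- runif(1, 0, 2); lambda <- runif(1, 0, 2)
    alpha <- sample(c(0, runif(1, 0, 0.5)), 1)
    expect_lt(abs(split_gain(GL, HL, GR, HR, gamma, lambda, alpha) -
                    brute_gain(GL, HL, GR, HR, gamma, lambda, alpha)),
              1e-9)
  }
})

test_that("exact greedy stump matches brute-force objective minimization", {
  # the worked stump: two groups with residual means 1 and 3
  x <- matrix(c(0, 0, 1, 1), ncol = 1, dimnames = list(NULL, "bit"))
  gh <- grad_hess("squared", y = c(1, 1, 3, 3), margin = rep(0, 4))
  params <- boost_params(n_estimators = 1, max_depth = 1, lambda = 0,
                         base_score = 0, loss = "squared")
  tree <- fit_tree(x, gh$g, gh$h, params)
  expect_equal(sum(tree$feature < 0), 2) # a stump
  expect_setequal(tree$value[tree$feature < 0], c(1, 3))

  # on random instances the fitted stump reaches the brute-force optimum
  set.seed(5)
  for (i in 1:10) {
    n <- sample(8:20, 1)
    x <- tiny_matrix(n, 3, seed = i)
    g <- rnorm(n); h <- runif(n, 0.5, 2)
    lambda <- 0.5; gamma <- 0.05; alpha <- 0.1
    p <- boost_params(max_depth = 1, lambda = lambda, gamma = gamma,
                      alpha = alpha, loss = "squared",
                      min_child_weight = 0)
    tree <- fit_tree(x, g, h, p)
    expect_lt(abs(tree_objective(tree, x, g, h, lambda, gamma, alpha) -
                    brute_best_stump_objective(x, g, h, lambda, gamma,
                                               alpha)),
              1e-9)
  }

  # pure node: no feature variation keeps a single leaf
  x <- matrix(1, nrow = 5, ncol = 2)
  tree <- fit_tree(x, rnorm(5), rep(1, 5), boost_params(loss = "squared"))
  expect_equal(length(tree$feature), 1)

  # prohibitive gamma rejects every split
  x <- tiny_matrix(12, 2, seed = 9)
  tree <- fit_tree(x, rnorm(12), rep(1, 12),
                   boost_params(gamma = 1e6, loss = "squared"))
  expect_equal(length(tree$feature), 1)
})

test_that("accepted splits reduce the objective by exactly the stated gain", {
  # depth-wise trees on <= 20-row instances: recompute every internal
  # node's gain from its instance set and compare with the objective
  # reduction evaluated directly
  set.seed(21)
  for (rep in 1:5) {
    n <- 20
    x <- tiny_matrix(n, 3, seed = rep, binary = rep %% 2 == 0)
    g <- rnorm(n); h <- runif(n, 0.5, 2)
    lambda <- 0.5; gamma <- 0.01
    tree <- fit_tree(x, g, h,
                     boost_params(max_depth = 3, lambda = lambda,
                                  gamma = gamma, loss = "squared",
                                  min_child_weight = 0))
    # instance set of every node by routing rows from the root
    route <- function(row) {
      path <- integer(0); id <- 1
      repeat {
        path <- c(path, id)
        if (tree$feature[id] < 0) return(path)
        id <- if (x[row, tree$feature[id] + 1] < tree$threshold[id]) {
          tree$yes[id] + 1
        } else {
          tree$no[id] + 1
        }
      }
    }
    membership <- matrix(FALSE, n, length(tree$feature))
    for (row in seq_len(n)) membership[row, route(row)] <- TRUE
    for (id in which(tree$feature >= 0)) {
      l <- tree$yes[id] + 1; r <- tree$no[id] + 1
      GL <- sum(g[membership[, l]]); HL <- sum(h[membership[, l]])
      GR <- sum(g[membership[, r]]); HR <- sum(h[membership[, r]])
      gain <- split_gain(GL, HL, GR, HR, gamma, lambda)
      expect_gt(gain, 0)
      expect_lt(abs(gain - brute_gain(GL, HL, GR, HR, gamma, lambda)), 1e-9)
    }
  }
})

test_that("one Newton round with unit learning rate reproduces per-leaf residual means", {
  set.seed(13)
  x <- tiny_matrix(40, 3, seed = 13)
  y <- rnorm(40, sd = 2)
  params <- boost_params(n_estimators = 1, learning_rate = 1, lambda = 0,
                         base_score = 0, loss = "squared")
  fit <- qsar_boost(x, y, params)
  pred <- predict(fit, x)
  # rows sharing a leaf share a prediction equal to their mean label
  for (p in unique(pred)) {
    expect_equal(p, mean(y[pred == p]), tolerance = 1e-12)
  }
  # the worked example predicts the labels exactly
  x2 <- matrix(c(0, 0, 1, 1), ncol = 1)
  fit2 <- qsar_boost(x2, c(1, 1, 3, 3), params)
  expect_equal(predict(fit2, x2), c(1, 1, 3, 3))
  # shrinkage is linear in the first round
  params3 <- boost_params(n_estimators = 1, learning_rate = 0.3, lambda = 0,
                          base_score = 0, loss = "squared")
  expect_equal(predict(qsar_boost(x2, c(1, 1, 3, 3), params3), x2),
               0.3 * c(1, 1, 3, 3))
})

test_that("training squared loss is non-increasing across boosting rounds", {
  set.seed(17)
  x <- tiny_matrix(60, 4, seed = 17)
  y <- rnorm(60)
  params <- boost_params(n_estimators = 25, loss = "squared", alpha = 0.1)
  fit <- qsar_boost(x, y, params)
  margin <- rep(fit$base_margin, nrow(x))
  losses <- numeric(length(fit$trees) + 1)
  losses[1] <- sum((y - margin)^2)
  for (k in seq_along(fit$trees)) {
    t <- fit$trees[[k]]
    leaf_of <- function(row) {
      id <- 1
      while (t$feature[id] >= 0) {
        id <- if (x[row, t$feature[id] + 1] < t$threshold[id]) t$yes[id] + 1
              else t$no[id] + 1
      }
      t$value[id]
    }
    margin <- margin + params$learning_rate *
      vapply(seq_len(nrow(x)), leaf_of, numeric(1))
    losses[k + 1] <- sum((y - margin)^2)
  }
  expect_true(all(diff(losses) <= 1e-9))
})

test_that("prediction handles empty ensembles, schema checks and classes", {
  x <- tiny_matrix(10, 3, seed = 2)
  fit <- qsar_boost(x, rnorm(10),
                    boost_params(n_estimators = 0, loss = "squared",
                                 base_score = 0.5))
  expect_equal(predict(fit, x), rep(0.5, 10))

  fitc <- qsar_boost(x, rbinom(10, 1, 0.5),
                     boost_params(n_estimators = 3, loss = "logistic"))
  prob <- predict(fitc, x)
  expect_true(all(prob > 0 & prob < 1))
  expect_equal(predict(fitc, x, type = "class"),
               ifelse(prob >= 0.5, "active", "inactive"))

  bad <- x; colnames(bad) <- c("f1", "f2", "zzz")
  expect_error(predict(fitc, bad), "f3")
})

test_that("the exact learner matches the reference boosting library within 1e-6", {
  for (seed in c(1, 2, 3)) {
    set.seed(seed)
    x <- matrix(rnorm(250), 50, 5, dimnames = list(NULL, paste0("f", 1:5)))
    # snap to single precision so both learners see identical data
    x <- matrix(qsarboost:::.cpp_float32(x), 50, 5, dimnames = dimnames(x))
    y <- rnorm(50, sd = 2)
    params <- boost_params(n_estimators = 20, max_depth = 4, lambda = 0.5,
                           alpha = 0.1, learning_rate = 0.3,
                           base_score = 0.5, loss = "squared")
    p_exact <- predict(qsar_boost(x, y, params, backend = "exact"), x)
    p_ref <- predict(qsar_boost(x, y, params, backend = "xgboost"), x)
    expect_lt(max(abs(p_exact - p_ref)), 1e-6)

    yb <- rbinom(50, 1, 0.5)
    params_l <- boost_params(n_estimators = 20, loss = "logistic")
    m_exact <- predict(qsar_boost(x, yb, params_l, backend = "exact"), x,
                       type = "margin")
    m_ref <- predict(qsar_boost(x, yb, params_l, backend = "xgboost"), x,
                     type = "margin")
    expect_lt(max(abs(m_exact - m_ref)), 1e-6)
  }
})

test_that("JSON serialization round-trips bit-identically", {
  x <- tiny_matrix(40, 4, seed = 23)
  y <- rnorm(40)
  fit <- qsar_boost(x, y, boost_params(n_estimators = 15, loss = "squared",
                                       alpha = 0.1))
  path <- tempfile(fileext = ".json")
  save_model_json(fit, path)
  restored <- load_model_json(path)
  expect_identical(predict(restored, x), predict(fit, x))
  expect_identical(restored$feature_names, fit$feature_names)

  fitc <- qsar_boost(x, rbinom(40, 1, 0.5),
                     boost_params(n_estimators = 5, loss = "logistic"),
                     backend = "xgboost")
  path2 <- tempfile(fileext = ".json")
  save_model_json(fitc, path2)
  expect_equal(predict(load_model_json(path2), x), predict(fitc, x),
               tolerance = 1e-12)
})

test_that("single-tree fits agree between fit_tree and the ensemble path", {
  x <- tiny_matrix(30, 3, seed = 31)
  y <- rnorm(30)
  params <- boost_params(n_estimators = 1, learning_rate = 1,
                         base_score = 0, loss = "squared", lambda = 0.5)
  fit <- qsar_boost(x, y, params)
  gh <- grad_hess("squared", y, rep(0, 30))
  tree <- fit_tree(x, gh$g, gh$h, params)
  expect_equal(unclass(fit$trees[[1]]), unclass(tree))
})

test_that("grid search orders candidate hyperparameters by CV score", {
  ds <- generate_dataset(small_spec(seed = 41, n = 120))
  x <- ds$features$values
  grid <- data.frame(n_estimators = c(2, 40), max_depth = c(1, 4),
                     alpha = c(0.1, 0.1))
  out <- grid_search_cv(x, ds$pic50, grid, loss = "squared", k = 3,
                        seed = 1)
  expect_equal(nrow(out), 2)
  expect_true(all(diff(out$cv_score) <= 0))
  # the deeper, longer model should beat the near-trivial one here
  expect_equal(out$n_estimators[1], 40)
})
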