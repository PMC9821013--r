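# Independent oracles used to freeze expected values.

# Per-leaf regularized objective minimized numerically (independent of the
# closed-form leaf weight in the implementation).
leaf_objective_min <- function(G, H, lambda, alpha) {
  stats::optimize(function(w) G * w + 0.5 * (H + lambda) * w^2 +
                    alpha * abs(w),
                  interval = c(-100, 100), tol = 1e-12)$objective
}

# Objective reduction of a split evaluated directly from the regularized
# objective (two leaves vs one, each at its numerically optimal weight).
brute_gain <- function(G_L, H_L, G_R, H_R, gamma, lambda, alpha = 0) {
  no_split <- leaf_objective_min(G_L + G_R, H_L + H_R, lambda, alpha) + gamma
  split <- leaf_objective_min(G_L, H_L, lambda, alpha) +
    leaf_objective_min(G_R, H_R, lambda, alpha) + 2 * gamma
  no_split - split
}

# Brute-force best single split (stump) by total objective over all
# feature/threshold candidates; returns the minimal achievable objective.
brute_best_stump_objective <- function(x, g, h, lambda, gamma, alpha = 0) {
  n <- nrow(x)
  best <- leaf_objective_min(sum(g), sum(h), lambda, alpha) + gamma
  for (j in seq_len(ncol(x))) {
    v <- sort(unique(x[, j]))
    if (length(v) < 2) next
    thr <- (utils::head(v, -1) + utils::tail(v, -1)) / 2
    for (t in thr) {
      left <- x[, j] < t
      obj <- leaf_objective_min(sum(g[left]), sum(h[left]), lambda, alpha) +
        leaf_objective_min(sum(g[!left]), sum(h[!left]), lambda, alpha) +
        2 * gamma
      best <- min(best, obj)
    }
  }
  best
}

# Total objective achieved by a fitted tree (leaves at their stored weights).
tree_objective <- function(tree, x, g, h, lambda, gamma, alpha = 0) {
  leaf_of <- function(row) {
    id <- 1
    while (tree$feature[id] >= 0) {
      id <- if (x[row, tree$feature[id] + 1] < tree$threshold[id]) {
        tree$yes[id] + 1
      } else {
        tree$no[id] + 1
      }
    }
    id
  }
  leaves <- vapply(seq_len(nrow(x)), leaf_of, numeric(1))
  obj <- 0
  for (id in unique(leaves)) {
    w <- tree$value[id]
    rows <- leaves == id
    obj <- obj + sum(g[rows]) * w + 0.5 * (sum(h[rows]) + lambda) * w^2 +
      alpha * abs(w)
  }
  obj + gamma * sum(tree$feature < 0)
}

# Deterministic tiny feature matrices for unit tests.
tiny_matrix <- function(n = 30, p = 4, seed = 7, binary = FALSE) {
  set.seed(seed)
  x <- if (binary) matrix(rbinom(n * p, 1, 0.4), n, p)
       else matrix(rnorm(n * p), n, p)
  colnames(x) <- paste0("f", seq_len(p))
  x
}

# Hand-built two-tree symmetric model: tree 1 splits feature a, tree 2
# splits feature b, with identical thresholds, weights, and covers.
symmetric_two_tree_model <- function() {
  mk_tree <- function(feature0) {
    structure(list(feature = c(feature0, -1L, -1L),
                   threshold = c(0.5, NA, NA),
                   yes = c(1L, -1L, -1L), no = c(2L, -1L, -1L),
                   value = c(0, -1, 1), cover = c(4, 2, 2),
                   sum_hess = c(4, 2, 2)),
              class = "qsar_tree")
  }
  params <- boost_params(n_estimators = 2, learning_rate = 1,
                         base_score = 0, loss = "squared")
  structure(list(params = params, feature_names = c("a", "b"),
                 base_margin = 0, backend = "exact",
                 trees = list(mk_tree(0L), mk_tree(1L))),
            class = "qsar_booster")
}

# Reduced-width generator used where the full 1188-column block would be
# needlessly slow for a unit test.
small_spec <- function(seed = 11, n = 300, ...) {
  generator_spec(n_compounds = n, n_binary = 80, n_counts = 20,
                 planted_features = 1:8,
                 planted_weights = c(1.1, 0.9, -0.9, 0.8, 0.8, -0.7,
                                     0.7, 0.6),
                 seed = seed, ...)
}
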