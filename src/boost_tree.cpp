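// Exact greedy second-order gradient boosting.
//
// Trees are grown level-wise.  At every level each feature is scanned once in
// globally presorted order while per-node accumulators track the left-hand
// gradient/hessian sums, so the cost per level is O(n * p) after an O(p n log n)
// presort done once per ensemble fit.  Split candidates are the midpoints
// between consecutive distinct feature values observed inside a node; a split
// is kept only when its gain (objective reduction after the gamma-per-leaf
// penalty) is strictly positive and both children carry at least
// min_child_weight of hessian mass.
//
// Leaf weights use the L1-soft-thresholded closed form
//   w* = -sign(G) max(|G| - alpha, 0) / (H + lambda)
// and are stored unscaled; the learning rate is applied at prediction time.

#include <Rcpp.h>
#include <algorithm>
#include <cmath>
#include <vector>

using namespace Rcpp;

namespace {

inline double thresh_l1(double g, double alpha) {
  if (g > alpha) return g - alpha;
  if (g < -alpha) return g + alpha;
  return 0.0;
}

inline double node_score(double G, double H, double lambda, double alpha) {
  double t = thresh_l1(G, alpha);
  return t * t / (H + lambda);
}

inline double calc_weight(double G, double H, double lambda, double alpha) {
  return -thresh_l1(G, alpha) / (H + lambda);
}

// flat tree representation: one row per node
struct FlatTree {
  std::vector<int> feature;      // -1 for leaf
  std::vector<double> threshold; // x < threshold goes left
  std::vector<int> yes, no;      // child indices, -1 for leaf
  std::vector<double> value;     // leaf weight (unscaled), 0 for internal
  std::vector<double> cover;     // number of training rows reaching the node
  std::vector<double> sum_hess;  // hessian mass at the node

  int add_node() {
    feature.push_back(-1);
    threshold.push_back(NA_REAL);
    yes.push_back(-1);
    no.push_back(-1);
    value.push_back(0.0);
    cover.push_back(0.0);
    sum_hess.push_back(0.0);
    return static_cast<int>(feature.size()) - 1;
  }
  int size() const { return static_cast<int>(feature.size()); }
};

struct NodeStat {
  double G = 0.0, H = 0.0;
  int n = 0;
};

struct BestSplit {
  double gain = 0.0;
  int feature = -1;
  double threshold = 0.0;
  double GL = 0.0, HL = 0.0;
  int nL = 0;
  bool valid() const { return feature >= 0; }
};

FlatTree fit_tree_impl(const NumericMatrix& X,
                       const std::vector<std::vector<int>>& order,
                       const NumericVector& g, const NumericVector& h,
                       int max_depth, double gamma, double lambda,
                       double alpha, double min_child_weight) {
  const int n = X.nrow();
  const int p = X.ncol();
  FlatTree tree;

  std::vector<int> pos(n, 0); // node id of each row; -1 once parked in a leaf
  int root = tree.add_node();
  NodeStat root_stat;
  for (int i = 0; i < n; ++i) {
    root_stat.G += g[i];
    root_stat.H += h[i];
    root_stat.n += 1;
  }
  tree.cover[root] = root_stat.n;
  tree.sum_hess[root] = root_stat.H;

  std::vector<int> frontier{root};
  std::vector<NodeStat> stats{root_stat};
  // stats are indexed by node id (grown lazily)
  auto stat_at = [&stats](int id) -> NodeStat& {
    if (id >= static_cast<int>(stats.size())) stats.resize(id + 1);
    return stats[static_cast<size_t>(id)];
  };

  for (int depth = 0; depth < max_depth && !frontier.empty(); ++depth) {
    const int n_nodes = tree.size();
    std::vector<BestSplit> best(n_nodes);
    std::vector<char> active(n_nodes, 0);
    for (int id : frontier) active[id] = 1;

    // scan accumulators per node, reset for every feature
    std::vector<double> GL(n_nodes), HL(n_nodes), lastv(n_nodes);
    std::vector<int> nL(n_nodes);
    std::vector<char> seen(n_nodes);

    for (int j = 0; j < p; ++j) {
      std::fill(GL.begin(), GL.end(), 0.0);
      std::fill(HL.begin(), HL.end(), 0.0);
      std::fill(nL.begin(), nL.end(), 0);
      std::fill(seen.begin(), seen.end(), 0);
      const std::vector<int>& ord = order[j];
      for (int k = 0; k < n; ++k) {
        const int i = ord[k];
        const int id = pos[i];
        if (id < 0 || !active[id]) continue;
        const double v = X(i, j);
        if (seen[id] && v > lastv[id]) {
          // candidate split between lastv and v
          const NodeStat& st = stats[id];
          const double HR = st.H - HL[id];
          if (HL[id] >= min_child_weight && HR >= min_child_weight) {
            const double GR = st.G - GL[id];
            double gain = 0.5 * (node_score(GL[id], HL[id], lambda, alpha) +
                                 node_score(GR, HR, lambda, alpha) -
                                 node_score(st.G, st.H, lambda, alpha)) -
                          gamma;
            // ties keep the first candidate seen, i.e. the lowest feature
            // index and then the lowest threshold
            BestSplit& b = best[id];
            if (gain > 0.0 && gain > b.gain) {
              b.gain = gain;
              b.feature = j;
              b.threshold = 0.5 * (lastv[id] + v);
              b.GL = GL[id];
              b.HL = HL[id];
              b.nL = nL[id];
            }
          }
        }
        GL[id] += g[i];
        HL[id] += h[i];
        nL[id] += 1;
        lastv[id] = v;
        seen[id] = 1;
      }
    }

    // apply the winning splits, finalize the rest as leaves
    std::vector<int> next_frontier;
    std::vector<int> left_of(n_nodes, -1), right_of(n_nodes, -1);
    for (int id : frontier) {
      const NodeStat st = stats[id];
      if (best[id].valid()) {
        int l = tree.add_node();
        int r = tree.add_node();
        tree.feature[id] = best[id].feature;
        tree.threshold[id] = best[id].threshold;
        tree.yes[id] = l;
        tree.no[id] = r;
        left_of[id] = l;
        right_of[id] = r;
        NodeStat ls, rs;
        ls.G = best[id].GL;
        ls.H = best[id].HL;
        ls.n = best[id].nL;
        rs.G = st.G - ls.G;
        rs.H = st.H - ls.H;
        rs.n = st.n - ls.n;
        stat_at(l) = ls;
        stat_at(r) = rs;
        tree.cover[l] = ls.n;
        tree.cover[r] = rs.n;
        tree.sum_hess[l] = ls.H;
        tree.sum_hess[r] = rs.H;
        next_frontier.push_back(l);
        next_frontier.push_back(r);
      } else {
        tree.value[id] = calc_weight(st.G, st.H, lambda, alpha);
      }
    }
    // route rows to children (or park them in finalized leaves)
    for (int i = 0; i < n; ++i) {
      const int id = pos[i];
      if (id < 0 || !active[id]) continue;
      if (left_of[id] >= 0) {
        pos[i] = X(i, tree.feature[id]) < tree.threshold[id] ? left_of[id]
                                                             : right_of[id];
      } else {
        pos[i] = -1;
      }
    }
    frontier = next_frontier;
  }

  // depth budget exhausted: remaining frontier nodes become leaves
  for (int id : frontier) {
    const NodeStat st = stats[id];
    tree.value[id] = calc_weight(st.G, st.H, lambda, alpha);
  }
  return tree;
}

List flat_tree_to_list(const FlatTree& t) {
  return List::create(
      _["feature"] = IntegerVector(t.feature.begin(), t.feature.end()),
      _["threshold"] = NumericVector(t.threshold.begin(), t.threshold.end()),
      _["yes"] = IntegerVector(t.yes.begin(), t.yes.end()),
      _["no"] = IntegerVector(t.no.begin(), t.no.end()),
      _["value"] = NumericVector(t.value.begin(), t.value.end()),
      _["cover"] = NumericVector(t.cover.begin(), t.cover.end()),
      _["sum_hess"] = NumericVector(t.sum_hess.begin(), t.sum_hess.end()));
}

std::vector<std::vector<int>> presort(const NumericMatrix& X) {
  const int n = X.nrow(), p = X.ncol();
  std::vector<std::vector<int>> order(p);
  for (int j = 0; j < p; ++j) {
    std::vector<int>& ord = order[j];
    ord.resize(n);
    for (int i = 0; i < n; ++i) ord[i] = i;
    std::stable_sort(ord.begin(), ord.end(),
                     [&X, j](int a, int b) { return X(a, j) < X(b, j); });
  }
  return order;
}

void accumulate_tree_margin(const List& tree, const NumericMatrix& X,
                            double scale, std::vector<double>& margin) {
  IntegerVector feature = tree["feature"];
  NumericVector threshold = tree["threshold"];
  IntegerVector yes = tree["yes"];
  IntegerVector no = tree["no"];
  NumericVector value = tree["value"];
  const int n = X.nrow();
  for (int i = 0; i < n; ++i) {
    int id = 0;
    while (feature[id] >= 0) {
      id = X(i, feature[id]) < threshold[id] ? yes[id] : no[id];
    }
    margin[i] += scale * value[id];
  }
}

} // namespace

// [[Rcpp::export(name = ".cpp_fit_tree")]]
List cpp_fit_tree(NumericMatrix X, NumericVector g, NumericVector h,
                  int max_depth, double gamma, double lambda, double alpha,
                  double min_child_weight) {
  if (X.nrow() != g.size() || X.nrow() != h.size())
    stop("gradient/hessian length must match the number of rows");
  std::vector<std::vector<int>> order = presort(X);
  FlatTree t = fit_tree_impl(X, order, g, h, max_depth, gamma, lambda, alpha,
                             min_child_weight);
  return flat_tree_to_list(t);
}

// [[Rcpp::export(name = ".cpp_fit_ensemble")]]
List cpp_fit_ensemble(NumericMatrix X, NumericVector y, std::string loss,
                      int n_estimators, int max_depth, double gamma,
                      double lambda, double alpha, double learning_rate,
                      double base_margin, double min_child_weight) {
  const int n = X.nrow();
  if (y.size() != n) stop("label length must match the number of rows");
  const bool logistic = loss == "logistic";
  if (!logistic && loss != "squared") stop("unknown loss kind: " + loss);

  std::vector<std::vector<int>> order = presort(X);
  std::vector<double> margin(n, base_margin);
  NumericVector g(n), h(n);
  List trees(n_estimators);
  for (int k = 0; k < n_estimators; ++k) {
    for (int i = 0; i < n; ++i) {
      if (logistic) {
        double pr = 1.0 / (1.0 + std::exp(-margin[i]));
        g[i] = pr - y[i];
        h[i] = pr * (1.0 - pr);
      } else {
        g[i] = margin[i] - y[i];
        h[i] = 1.0;
      }
    }
    FlatTree t = fit_tree_impl(X, order, g, h, max_depth, gamma, lambda, alpha,
                               min_child_weight);
    List tl = flat_tree_to_list(t);
    accumulate_tree_margin(tl, X, learning_rate, margin);
    trees[k] = tl;
  }
  return trees;
}

// [[Rcpp::export(name = ".cpp_predict_margin")]]
NumericVector cpp_predict_margin(List trees, NumericMatrix X,
                                 double learning_rate, double base_margin) {
  const int n = X.nrow();
  std::vector<double> margin(n, base_margin);
  for (int k = 0; k < trees.size(); ++k) {
    accumulate_tree_margin(trees[k], X, learning_rate, margin);
  }
  return NumericVector(margin.begin(), margin.end());
}

// [[Rcpp::export(name = ".cpp_float32")]]
NumericVector cpp_float32(NumericVector x) {
  NumericVector out(x.size());
  for (int i = 0; i < x.size(); ++i)
    out[i] = static_cast<double>(static_cast<float>(x[i]));
  return out;
}
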