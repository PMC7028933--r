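#include <Rcpp.h>
#include <algorithm>
#include <vector>
#include <cmath>
using namespace Rcpp;

// Stage-wise gradient boosting on the binomial deviance with depth-limited
// regression trees as weak learners. F0 is the prevalence log-odds; each
// stage fits a tree to the current residual y - p by exhaustive variance-
// reduction split search and takes a Newton leaf step sum(r)/sum(p(1-p)).
// No row/column subsampling, so the fit is fully deterministic.

namespace {

struct Node {
  int var = -1;        // split feature (0-based), -1 for leaf
  double thr = 0.0;    // go left if x <= thr
  int left = -1, right = -1;
  double value = 0.0;  // leaf value (Newton step)
};

struct Tree {
  std::vector<Node> nodes;
};

struct SplitResult {
  int var = -1;
  double thr = 0.0;
  double gain = 0.0;
};

// presorted split search: `order` holds, per feature, all row indices in
// ascending feature order; membership in the current node is tested with a
// flag array, so each node costs O(n * p) regardless of node size.
SplitResult best_split(const NumericMatrix &X, const std::vector<double> &r,
                       const std::vector<int> &rows,
                       const std::vector<int> &order,
                       std::vector<char> &in_node, int min_node) {
  SplitResult best;
  const int m = (int)rows.size();
  const int n = X.nrow();
  const int p = X.ncol();
  double tot = 0.0;
  for (int i : rows) { tot += r[i]; in_node[i] = 1; }
  const double base = tot * tot / m;
  for (int j = 0; j < p; ++j) {
    const int *ord = &order[(size_t)j * n];
    const double *xj = &X(0, j);
    double sl = 0.0;
    int nl = 0;
    double prev_x = 0.0;
    bool have_prev = false;
    for (int k = 0; k < n; ++k) {
      const int i = ord[k];
      if (!in_node[i]) continue;
      const double x = xj[i];
      if (have_prev && x != prev_x && nl >= min_node && (m - nl) >= min_node) {
        const double sr = tot - sl;
        const double gain = sl * sl / nl + sr * sr / (m - nl) - base;
        if (gain > best.gain + 1e-12) {
          best.gain = gain;
          best.var = j;
          best.thr = 0.5 * (prev_x + x);
        }
      }
      sl += r[i];
      ++nl;
      prev_x = x;
      have_prev = true;
    }
  }
  for (int i : rows) in_node[i] = 0;
  return best;
}

double leaf_value(const std::vector<double> &r, const std::vector<double> &h,
                  const std::vector<int> &rows) {
  double sr = 0.0, sh = 0.0;
  for (int i : rows) { sr += r[i]; sh += h[i]; }
  double v = sr / (sh + 1e-12);
  if (v > 4.0) v = 4.0;
  if (v < -4.0) v = -4.0;
  return v;
}

int build(Tree &tree, const NumericMatrix &X, const std::vector<double> &r,
          const std::vector<double> &h, std::vector<int> rows, int depth,
          int max_depth, int min_node, std::vector<double> &imp,
          const std::vector<int> &order, std::vector<char> &in_node) {
  const int id = (int)tree.nodes.size();
  tree.nodes.emplace_back();
  if (depth >= max_depth || (int)rows.size() < 2 * min_node) {
    tree.nodes[id].value = leaf_value(r, h, rows);
    return id;
  }
  SplitResult s = best_split(X, r, rows, order, in_node, min_node);
  if (s.var < 0) {
    tree.nodes[id].value = leaf_value(r, h, rows);
    return id;
  }
  imp[s.var] += s.gain;
  std::vector<int> lrows, rrows;
  for (int i : rows) {
    if (X(i, s.var) <= s.thr) lrows.push_back(i); else rrows.push_back(i);
  }
  rows.clear(); rows.shrink_to_fit();
  tree.nodes[id].var = s.var;
  tree.nodes[id].thr = s.thr;
  const int l = build(tree, X, r, h, std::move(lrows), depth + 1, max_depth,
                      min_node, imp, order, in_node);
  const int rr = build(tree, X, r, h, std::move(rrows), depth + 1, max_depth,
                       min_node, imp, order, in_node);
  tree.nodes[id].left = l;
  tree.nodes[id].right = rr;
  return id;
}

double tree_predict(const Tree &t, const NumericMatrix &X, int i) {
  int id = 0;
  while (t.nodes[id].var >= 0) {
    id = (X(i, t.nodes[id].var) <= t.nodes[id].thr) ? t.nodes[id].left
                                                    : t.nodes[id].right;
  }
  return t.nodes[id].value;
}

List tree_to_list(const Tree &t) {
  const int n = (int)t.nodes.size();
  IntegerVector var(n), left(n), right(n);
  NumericVector thr(n), value(n);
  for (int i = 0; i < n; ++i) {
    var[i] = t.nodes[i].var;
    thr[i] = t.nodes[i].thr;
    left[i] = t.nodes[i].left;
    right[i] = t.nodes[i].right;
    value[i] = t.nodes[i].value;
  }
  return List::create(_["var"] = var, _["thr"] = thr, _["left"] = left,
                      _["right"] = right, _["value"] = value);
}

} // namespace

// [[Rcpp::export(name = ".gbm_fit_cpp")]]
List gbm_fit_cpp(NumericMatrix X, NumericVector y, int n_trees, int max_depth,
                 double shrinkage, int min_node) {
  const int n = X.nrow(), p = X.ncol();
  double ybar = 0.0;
  for (int i = 0; i < n; ++i) ybar += y[i];
  ybar /= n;
  ybar = std::min(std::max(ybar, 1e-12), 1.0 - 1e-12);
  const double f0 = std::log(ybar / (1.0 - ybar));

  std::vector<double> F(n, f0), prob(n), r(n), h(n);
  std::vector<double> imp(p, 0.0);
  NumericVector logloss(n_trees);
  List trees(n_trees);
  std::vector<int> all(n);
  for (int i = 0; i < n; ++i) all[i] = i;

  // presort every feature column once
  std::vector<int> order((size_t)n * p);
  for (int j = 0; j < p; ++j) {
    int *ord = &order[(size_t)j * n];
    for (int i = 0; i < n; ++i) ord[i] = i;
    const double *xj = &X(0, j);
    std::sort(ord, ord + n,
              [xj](int a, int b) { return xj[a] < xj[b]; });
  }
  std::vector<char> in_node(n, 0);

  for (int t = 0; t < n_trees; ++t) {
    for (int i = 0; i < n; ++i) {
      prob[i] = 1.0 / (1.0 + std::exp(-F[i]));
      r[i] = y[i] - prob[i];
      h[i] = std::max(prob[i] * (1.0 - prob[i]), 1e-12);
    }
    Tree tree;
    build(tree, X, r, h, all, 0, max_depth, min_node, imp, order, in_node);
    double ll = 0.0;
    for (int i = 0; i < n; ++i) {
      F[i] += shrinkage * tree_predict(tree, X, i);
      const double pi = 1.0 / (1.0 + std::exp(-F[i]));
      const double pc = std::min(std::max(pi, 1e-12), 1.0 - 1e-12);
      ll -= y[i] * std::log(pc) + (1.0 - y[i]) * std::log(1.0 - pc);
    }
    logloss[t] = ll / n;
    trees[t] = tree_to_list(tree);
  }
  return List::create(_["f0"] = f0, _["trees"] = trees,
                      _["importance"] = NumericVector(imp.begin(), imp.end()),
                      _["train_logloss"] = logloss);
}

// [[Rcpp::export(name = ".gbm_predict_cpp")]]
NumericVector gbm_predict_cpp(List model, NumericMatrix X, int n_trees) {
  const int n = X.nrow();
  const double f0 = as<double>(model["f0"]);
  List trees = model["trees"];
  const double shrinkage = as<double>(model["shrinkage"]);
  const int nt = (n_trees < 0 || n_trees > trees.size()) ? trees.size()
                                                         : n_trees;
  NumericVector out(n, f0);
  for (int t = 0; t < nt; ++t) {
    List tl = trees[t];
    IntegerVector var = tl["var"], left = tl["left"], right = tl["right"];
    NumericVector thr = tl["thr"], value = tl["value"];
    for (int i = 0; i < n; ++i) {
      int id = 0;
      while (var[id] >= 0)
        id = (X(i, var[id]) <= thr[id]) ? left[id] : right[id];
      out[i] += shrinkage * value[id];
    }
  }
  for (int i = 0; i < n; ++i) out[i] = 1.0 / (1.0 + std::exp(-out[i]));
  return out;
}
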