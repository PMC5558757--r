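// Greedy entropy-split binary classification tree and a bagged random forest
// built on it. These back two of the node-classifier families of the
// omnivariate tree; plain R recursion is too slow inside a GA loop.
#include <Rcpp.h>
#include <random>
#include <algorithm>
#include <vector>
#include <cmath>
using namespace Rcpp;

namespace {

struct TreeNodes {
  std::vector<int> feature;      // -1 for leaf
  std::vector<double> threshold; // go left if x <= threshold
  std::vector<int> left, right;  // child indices, -1 for leaf
  std::vector<int> n, npos;      // routed training count / positives
};

inline double entropy2(double pos, double tot) {
  if (tot <= 0.0) return 0.0;
  double p = pos / tot;
  double e = 0.0;
  if (p > 0.0) e -= p * std::log2(p);
  if (p < 1.0) e -= (1.0 - p) * std::log2(1.0 - p);
  return e;
}

struct Builder {
  const NumericMatrix& X;
  const IntegerVector& y;
  int max_depth, min_split, min_leaf, mtry;
  double min_gain;
  std::mt19937 rng;
  TreeNodes t;

  Builder(const NumericMatrix& X_, const IntegerVector& y_, int max_depth_,
          int min_split_, int min_leaf_, int mtry_, double min_gain_,
          unsigned int seed)
    : X(X_), y(y_), max_depth(max_depth_), min_split(min_split_),
      min_leaf(min_leaf_), mtry(mtry_), min_gain(min_gain_), rng(seed) {}

  int new_node(int n, int npos) {
    t.feature.push_back(-1);
    t.threshold.push_back(0.0);
    t.left.push_back(-1);
    t.right.push_back(-1);
    t.n.push_back(n);
    t.npos.push_back(npos);
    return (int)t.feature.size() - 1;
  }

  // sample mtry distinct feature indices, returned sorted (deterministic
  // tie-breaking: lower feature index wins on equal gain)
  std::vector<int> sample_features() {
    int p = X.ncol();
    std::vector<int> idx(p);
    for (int j = 0; j < p; ++j) idx[j] = j;
    if (mtry >= p) return idx;
    // partial Fisher-Yates
    for (int j = 0; j < mtry; ++j) {
      std::uniform_int_distribution<int> d(j, p - 1);
      std::swap(idx[j], idx[d(rng)]);
    }
    idx.resize(mtry);
    std::sort(idx.begin(), idx.end());
    return idx;
  }

  int build(std::vector<int>& rows, int depth) {
    int n = (int)rows.size();
    int npos = 0;
    for (int r : rows) npos += y[r];
    int id = new_node(n, npos);
    if (depth >= max_depth || n < min_split || npos == 0 || npos == n)
      return id;

    double h_parent = entropy2((double)npos, (double)n);
    std::vector<int> feats = sample_features();
    int best_f = -1;
    double best_gain = min_gain, best_thr = 0.0;
    std::vector<int> ord(rows);
    std::vector<double> vals(n);
    for (int f : feats) {
      for (int i = 0; i < n; ++i) vals[i] = X(rows[i], f);
      std::vector<int> o(n);
      for (int i = 0; i < n; ++i) o[i] = i;
      std::stable_sort(o.begin(), o.end(),
                       [&](int a, int b) { return vals[a] < vals[b]; });
      int pos_left = 0;
      for (int i = 0; i < n - 1; ++i) {
        pos_left += y[rows[o[i]]];
        int nl = i + 1, nr = n - nl;
        if (vals[o[i]] == vals[o[i + 1]]) continue; // not a cut point
        if (nl < min_leaf || nr < min_leaf) continue;
        double h = (nl * entropy2((double)pos_left, (double)nl) +
                    nr * entropy2((double)(npos - pos_left), (double)nr)) / n;
        double gain = h_parent - h;
        if (gain > best_gain + 1e-12) {
          best_gain = gain;
          best_f = f;
          best_thr = 0.5 * (vals[o[i]] + vals[o[i + 1]]);
        }
      }
    }
    if (best_f < 0) return id;

    std::vector<int> lrows, rrows;
    for (int r : rows) {
      if (X(r, best_f) <= best_thr) lrows.push_back(r); else rrows.push_back(r);
    }
    t.feature[id] = best_f;
    t.threshold[id] = best_thr;
    // free parent's row copy before recursing? rows kept by caller; fine.
    int l = build(lrows, depth + 1);
    int r = build(rrows, depth + 1);
    t.left[id] = l;
    t.right[id] = r;
    return id;
  }
};

List tree_to_list(const TreeNodes& t) {
  return List::create(
    _["feature"] = IntegerVector(t.feature.begin(), t.feature.end()),
    _["threshold"] = NumericVector(t.threshold.begin(), t.threshold.end()),
    _["left"] = IntegerVector(t.left.begin(), t.left.end()),
    _["right"] = IntegerVector(t.right.begin(), t.right.end()),
    _["n"] = IntegerVector(t.n.begin(), t.n.end()),
    _["npos"] = IntegerVector(t.npos.begin(), t.npos.end()));
}

NumericVector tree_prob(const List& tree, const NumericMatrix& X) {
  IntegerVector feature = tree["feature"];
  NumericVector threshold = tree["threshold"];
  IntegerVector left = tree["left"], right = tree["right"];
  IntegerVector n = tree["n"], npos = tree["npos"];
  int m = X.nrow();
  NumericVector out(m);
  for (int i = 0; i < m; ++i) {
    int node = 0;
    while (feature[node] >= 0) {
      node = (X(i, feature[node]) <= threshold[node]) ? left[node]
                                                      : right[node];
    }
    out[i] = n[node] > 0 ? (double)npos[node] / n[node] : 0.5;
  }
  return out;
}

} // namespace

// [[Rcpp::export(name = ".cpp_tree_fit")]]
List cpp_tree_fit(NumericMatrix X, IntegerVector y, int max_depth,
                  int min_split, int min_leaf, int mtry, double min_gain,
                  int seed) {
  Builder b(X, y, max_depth, min_split, min_leaf, mtry, min_gain,
            (unsigned int)seed);
  std::vector<int> rows(X.nrow());
  for (int i = 0; i < X.nrow(); ++i) rows[i] = i;
  b.build(rows, 0);
  return tree_to_list(b.t);
}

// [[Rcpp::export(name = ".cpp_tree_prob")]]
NumericVector cpp_tree_prob(List tree, NumericMatrix X) {
  return tree_prob(tree, X);
}

// [[Rcpp::export(name = ".cpp_forest_fit")]]
List cpp_forest_fit(NumericMatrix X, IntegerVector y, int n_trees,
                    int max_depth, int min_split, int min_leaf, int mtry,
                    int seed) {
  int n = X.nrow();
  std::mt19937 rng((unsigned int)seed);
  List trees(n_trees);
  std::uniform_int_distribution<int> pick(0, n - 1);
  for (int b = 0; b < n_trees; ++b) {
    // bootstrap by row indices (duplicates allowed); no matrix copy
    std::vector<int> rows(n);
    for (int i = 0; i < n; ++i) rows[i] = pick(rng);
    std::uniform_int_distribution<int> sdist(0, 2147483646);
    Builder bl(X, y, max_depth, min_split, min_leaf, mtry, 0.0,
               (unsigned int)sdist(rng));
    bl.build(rows, 0);
    trees[b] = tree_to_list(bl.t);
  }
  return trees;
}

// [[Rcpp::export(name = ".cpp_forest_prob")]]
NumericVector cpp_forest_prob(List trees, NumericMatrix X) {
  int m = X.nrow(), B = trees.size();
  NumericVector acc(m);
  for (int b = 0; b < B; ++b) {
    NumericVector p = tree_prob(trees[b], X);
    // majority vote per tree: count a tree as voting class 1 when its leaf
    // is majority-positive
    for (int i = 0; i < m; ++i) acc[i] += (p[i] >= 0.5) ? 1.0 : 0.0;
  }
  for (int i = 0; i < m; ++i) acc[i] /= B;
  return acc;
}
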