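// Compact random-forest classifier: CART trees with gini splits, grown on
// weighted bootstrap samples, majority vote across trees. Uses R's RNG so
// set.seed() on the R side makes training deterministic.

#include <Rcpp.h>
#include <algorithm>
#include <vector>
using namespace Rcpp;

namespace {

struct Node {
  int var;        // -1 for leaf
  double thr;
  int left, right;
  int pred;       // leaf: majority class
};

struct TreeBuilder {
  const NumericMatrix& X;
  const IntegerVector& y;
  int nclass;
  int mtry;
  int min_node;
  std::vector<Node> nodes;

  TreeBuilder(const NumericMatrix& X_, const IntegerVector& y_, int nclass_,
              int mtry_, int min_node_)
      : X(X_), y(y_), nclass(nclass_), mtry(mtry_), min_node(min_node_) {}

  static double gini(const std::vector<double>& cnt, double n) {
    if (n <= 0) return 0.0;
    double g = 1.0;
    for (double c : cnt) g -= (c / n) * (c / n);
    return g;
  }

  int build(std::vector<int>& idx, int lo, int hi) {
    int n = hi - lo;
    std::vector<double> cnt(nclass, 0.0);
    for (int i = lo; i < hi; ++i) cnt[y[idx[i]]] += 1.0;
    int best_class = std::max_element(cnt.begin(), cnt.end()) - cnt.begin();
    bool pure = cnt[best_class] == n;

    int me = (int)nodes.size();
    nodes.push_back({-1, 0.0, -1, -1, best_class});
    if (pure || n < 2 * min_node) return me;

    int p = X.ncol();
    double node_gini = gini(cnt, n);
    double best_gain = 1e-12;
    int best_var = -1;
    double best_thr = 0.0;

    // sample mtry distinct features
    std::vector<int> feats(p);
    for (int j = 0; j < p; ++j) feats[j] = j;
    for (int j = 0; j < mtry && j < p; ++j) {
      int k = j + (int)(unif_rand() * (p - j));
      if (k >= p) k = p - 1;
      std::swap(feats[j], feats[k]);
    }

    std::vector<int> ord(idx.begin() + lo, idx.begin() + hi);
    std::vector<double> lcnt(nclass), rcnt(nclass);
    for (int j = 0; j < mtry && j < p; ++j) {
      int v = feats[j];
      std::sort(ord.begin(), ord.end(),
                [&](int a, int b) { return X(a, v) < X(b, v); });
      std::fill(lcnt.begin(), lcnt.end(), 0.0);
      rcnt = cnt;
      for (int i = 0; i + 1 < n; ++i) {
        int c = y[ord[i]];
        lcnt[c] += 1.0;
        rcnt[c] -= 1.0;
        double xv = X(ord[i], v), xn = X(ord[i + 1], v);
        if (xn <= xv) continue;  // not a distinct cut
        double nl = i + 1, nr = n - nl;
        if (nl < min_node || nr < min_node) continue;
        double gain = node_gini -
            (nl / n) * gini(lcnt, nl) - (nr / n) * gini(rcnt, nr);
        if (gain > best_gain) {
          best_gain = gain;
          best_var = v;
          best_thr = 0.5 * (xv + xn);
        }
      }
    }
    if (best_var < 0) return me;

    // partition idx[lo..hi) in place
    int mid = lo;
    for (int i = lo; i < hi; ++i) {
      if (X(idx[i], best_var) <= best_thr) std::swap(idx[i], idx[mid++]);
    }
    if (mid == lo || mid == hi) return me;

    nodes[me].var = best_var;
    nodes[me].thr = best_thr;
    int l = build(idx, lo, mid);
    int r = build(idx, mid, hi);
    nodes[me].left = l;
    nodes[me].right = r;
    return me;
  }
};

int tree_predict(const NumericMatrix& tree, const NumericMatrix& X, int row) {
  int node = 0;
  while (tree(node, 0) >= 0) {
    int v = (int)tree(node, 0);
    node = (X(row, v) <= tree(node, 1)) ? (int)tree(node, 2)
                                        : (int)tree(node, 3);
  }
  return (int)tree(node, 4);
}

}  // namespace

// [[Rcpp::export(name = ".rf_train_cpp")]]
List rf_train_cpp(NumericMatrix X, IntegerVector y, int nclass, int ntree,
                  int mtry, int min_node, NumericVector case_weights) {
  int n = X.nrow();
  std::vector<double> cum(n);
  double tot = 0.0;
  for (int i = 0; i < n; ++i) { tot += case_weights[i]; cum[i] = tot; }

  List trees(ntree);
  RNGScope scope;
  for (int t = 0; t < ntree; ++t) {
    std::vector<int> idx(n);
    for (int i = 0; i < n; ++i) {
      double u = unif_rand() * tot;
      idx[i] = std::lower_bound(cum.begin(), cum.end(), u) - cum.begin();
      if (idx[i] >= n) idx[i] = n - 1;
    }
    TreeBuilder tb(X, y, nclass, mtry, min_node);
    tb.build(idx, 0, n);
    NumericMatrix m(tb.nodes.size(), 5);
    for (size_t i = 0; i < tb.nodes.size(); ++i) {
      m(i, 0) = tb.nodes[i].var;
      m(i, 1) = tb.nodes[i].thr;
      m(i, 2) = tb.nodes[i].left;
      m(i, 3) = tb.nodes[i].right;
      m(i, 4) = tb.nodes[i].pred;
    }
    trees[t] = m;
  }
  return trees;
}

// [[Rcpp::export(name = ".rf_predict_cpp")]]
NumericMatrix rf_predict_cpp(List trees, NumericMatrix X, int nclass) {
  int n = X.nrow(), ntree = trees.size();
  NumericMatrix votes(n, nclass);
  for (int t = 0; t < ntree; ++t) {
    NumericMatrix tree = trees[t];
    for (int i = 0; i < n; ++i) votes(i, tree_predict(tree, X, i)) += 1.0;
  }
  for (int i = 0; i < n; ++i)
    for (int c = 0; c < nclass; ++c) votes(i, c) /= ntree;
  return votes;
}
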