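#include <Rcpp.h>
#include <algorithm>
#include <vector>
using namespace Rcpp;

// Minimal bagged regression forest (CART with random feature subsampling).
// Implemented here because the target environment ships no tree package.
// Uses R's RNG so results are governed by set.seed() on the R side.

namespace {

struct Tree {
  std::vector<int> feat;      // -1 for a leaf
  std::vector<double> thr;
  std::vector<int> left, right;
  std::vector<double> value;  // node mean
};

inline int rand_int(int n) {
  int k = static_cast<int>(unif_rand() * n);
  return k >= n ? n - 1 : k;
}

void grow_node(const NumericMatrix& X, const NumericVector& y,
               std::vector<int>& idx, int lo, int hi, int node,
               int mtry, int min_split, Tree& tree,
               std::vector<int>& feat_pool) {
  const int n = hi - lo;
  double sum = 0;
  for (int i = lo; i < hi; ++i) sum += y[idx[i]];
  const double mean = sum / n;
  tree.value[node] = mean;
  if (n < min_split) return;
  double sse = 0;
  for (int i = lo; i < hi; ++i) {
    const double d = y[idx[i]] - mean;
    sse += d * d;
  }
  if (sse < 1e-12) return;

  // sample mtry features without replacement (partial Fisher-Yates)
  const int p = X.ncol();
  for (int j = 0; j < p; ++j) feat_pool[j] = j;
  const int m = std::min(mtry, p);
  for (int j = 0; j < m; ++j) std::swap(feat_pool[j], feat_pool[j + rand_int(p - j)]);

  int best_f = -1;
  double best_gain = 0, best_thr = 0;
  std::vector<int> ord(idx.begin() + lo, idx.begin() + hi);
  for (int jj = 0; jj < m; ++jj) {
    const int f = feat_pool[jj];
    std::sort(ord.begin(), ord.end(), [&](int a, int b) {
      return X(a, f) < X(b, f);
    });
    double sl = 0;
    for (int k = 0; k < n - 1; ++k) {
      sl += y[ord[k]];
      if (X(ord[k], f) == X(ord[k + 1], f)) continue;  // no gap to split in
      const int nl = k + 1, nr = n - nl;
      const double sr = sum - sl;
      const double gain = sl * sl / nl + sr * sr / nr - sum * sum / n;
      if (gain > best_gain + 1e-12) {
        best_gain = gain;
        best_f = f;
        best_thr = 0.5 * (X(ord[k], f) + X(ord[k + 1], f));
      }
    }
  }
  if (best_f < 0) return;

  // partition idx[lo, hi) in place
  int mid = lo;
  for (int i = lo; i < hi; ++i) {
    if (X(idx[i], best_f) <= best_thr) std::swap(idx[i], idx[mid++]);
  }
  if (mid == lo || mid == hi) return;  // degenerate split guard

  const int l = static_cast<int>(tree.feat.size());
  tree.feat.push_back(-1); tree.thr.push_back(0);
  tree.left.push_back(-1); tree.right.push_back(-1); tree.value.push_back(0);
  const int r = static_cast<int>(tree.feat.size());
  tree.feat.push_back(-1); tree.thr.push_back(0);
  tree.left.push_back(-1); tree.right.push_back(-1); tree.value.push_back(0);
  tree.feat[node] = best_f;
  tree.thr[node] = best_thr;
  tree.left[node] = l;
  tree.right[node] = r;
  grow_node(X, y, idx, lo, mid, l, mtry, min_split, tree, feat_pool);
  grow_node(X, y, idx, mid, hi, r, mtry, min_split, tree, feat_pool);
}

}  // namespace

// [[Rcpp::export]]
List rf_fit_cpp(NumericMatrix X, NumericVector y, int ntree, int mtry,
                int min_split) {
  const int n = X.nrow();
  List trees(ntree);
  std::vector<int> feat_pool(X.ncol());
  for (int t = 0; t < ntree; ++t) {
    std::vector<int> idx(n);
    for (int i = 0; i < n; ++i) idx[i] = rand_int(n);  // bootstrap sample
    Tree tree;
    tree.feat.assign(1, -1); tree.thr.assign(1, 0);
    tree.left.assign(1, -1); tree.right.assign(1, -1); tree.value.assign(1, 0);
    grow_node(X, y, idx, 0, n, 0, mtry, min_split, tree, feat_pool);
    trees[t] = List::create(_["feat"] = wrap(tree.feat),
                            _["thr"] = wrap(tree.thr),
                            _["left"] = wrap(tree.left),
                            _["right"] = wrap(tree.right),
                            _["value"] = wrap(tree.value));
  }
  return trees;
}

// [[Rcpp::export]]
NumericVector rf_predict_cpp(List trees, NumericMatrix X) {
  const int n = X.nrow();
  const int ntree = trees.size();
  NumericVector out(n);
  for (int t = 0; t < ntree; ++t) {
    List tr = trees[t];
    IntegerVector feat = tr["feat"];
    NumericVector thr = tr["thr"];
    IntegerVector left = tr["left"], right = tr["right"];
    NumericVector value = tr["value"];
    for (int i = 0; i < n; ++i) {
      int node = 0;
      while (feat[node] >= 0) {
        node = X(i, feat[node]) <= thr[node] ? left[node] : right[node];
      }
      out[i] += value[node];
    }
  }
  return out / static_cast<double>(ntree);
}
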