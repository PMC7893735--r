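// Compact probability random forest for binary classification.
// Bagged CART with gini splits and per-node feature subsampling; leaf
// prediction is the in-bag positive-class fraction, averaged over trees.
// Uses R's RNG throughout so results are reproducible via set.seed().

#include <Rcpp.h>
#include <algorithm>
#include <vector>
using namespace Rcpp;

namespace {

struct TreeBuf {
  std::vector<int> feat;     // split feature (0-based), -1 for leaf
  std::vector<double> thr;   // split threshold (go left if x <= thr)
  std::vector<int> left, right;
  std::vector<double> pred;  // leaf positive fraction
};

// draw k of n without replacement (partial Fisher-Yates), R RNG
void sample_features(std::vector<int> &pool, int k) {
  int n = pool.size();
  for (int i = 0; i < k; ++i) {
    int j = i + (int)(unif_rand() * (n - i));
    if (j >= n) j = n - 1;
    std::swap(pool[i], pool[j]);
  }
}

int grow_node(const NumericMatrix &X, const IntegerVector &y,
              std::vector<int> &idx, int lo, int hi, int mtry, int min_node,
              int depth, std::vector<int> &fpool, TreeBuf &t) {
  int n = hi - lo;
  int pos = 0;
  for (int i = lo; i < hi; ++i) pos += y[idx[i]];

  int node = (int)t.feat.size();
  t.feat.push_back(-1);
  t.thr.push_back(0.0);
  t.left.push_back(-1);
  t.right.push_back(-1);
  t.pred.push_back((double)pos / n);

  if (pos == 0 || pos == n || n < 2 * min_node || depth >= 30) return node;

  sample_features(fpool, mtry);

  int best_f = -1, best_k = -1;
  double best_score = R_PosInf, best_thr = 0.0;
  std::vector<std::pair<double, int>> v(n);

  for (int m = 0; m < mtry; ++m) {
    int f = fpool[m];
    for (int i = 0; i < n; ++i)
      v[i] = std::make_pair(X(idx[lo + i], f), y[idx[lo + i]]);
    std::sort(v.begin(), v.end());
    int posl = 0;
    for (int k = 1; k < n; ++k) {
      posl += v[k - 1].second;
      if (v[k - 1].first == v[k].first) continue;
      if (k < min_node || n - k < min_node) continue;
      double pl = posl, pr = pos - posl;
      double nl = k, nr = n - k;
      double score = pl * (nl - pl) / nl + pr * (nr - pr) / nr;
      if (score < best_score) {
        best_score = score;
        best_f = f;
        best_k = k;
        best_thr = 0.5 * (v[k - 1].first + v[k].first);
      }
    }
  }
  if (best_f < 0) return node;

  // stable partition of idx[lo, hi) on the chosen split
  std::stable_partition(idx.begin() + lo, idx.begin() + hi,
                        [&](int r) { return X(r, best_f) <= best_thr; });
  int mid = lo;
  while (mid < hi && X(idx[mid], best_f) <= best_thr) ++mid;
  if (mid == lo || mid == hi) return node;  // degenerate (ties)

  t.feat[node] = best_f;
  t.thr[node] = best_thr;
  int l = grow_node(X, y, idx, lo, mid, mtry, min_node, depth + 1, fpool, t);
  t.left[node] = l;
  int r = grow_node(X, y, idx, mid, hi, mtry, min_node, depth + 1, fpool, t);
  t.right[node] = r;
  return node;
}

}  // namespace

// [[Rcpp::export(name = ".rf_build")]]
List rf_build(NumericMatrix X, IntegerVector y, int num_trees, int mtry,
              int min_node) {
  int n = X.nrow(), p = X.ncol();
  if (n < 2) stop("need at least 2 samples");
  if (mtry < 1 || mtry > p) stop("invalid mtry");
  RNGScope scope;
  List forest(num_trees);
  std::vector<int> idx(n), fpool(p);
  for (int b = 0; b < num_trees; ++b) {
    for (int i = 0; i < n; ++i) {
      int j = (int)(unif_rand() * n);
      idx[i] = j >= n ? n - 1 : j;
    }
    for (int f = 0; f < p; ++f) fpool[f] = f;
    TreeBuf t;
    grow_node(X, y, idx, 0, n, mtry, min_node, 0, fpool, t);
    forest[b] = List::create(
        _["feat"] = IntegerVector(t.feat.begin(), t.feat.end()),
        _["thr"] = NumericVector(t.thr.begin(), t.thr.end()),
        _["left"] = IntegerVector(t.left.begin(), t.left.end()),
        _["right"] = IntegerVector(t.right.begin(), t.right.end()),
        _["pred"] = NumericVector(t.pred.begin(), t.pred.end()));
  }
  return forest;
}

// [[Rcpp::export(name = ".rf_predict")]]
NumericVector rf_predict(List forest, NumericMatrix X) {
  int n = X.nrow(), ntree = forest.size();
  NumericVector out(n, 0.0);
  for (int b = 0; b < ntree; ++b) {
    List t = forest[b];
    IntegerVector feat = t["feat"];
    NumericVector thr = t["thr"];
    IntegerVector left = t["left"], right = t["right"];
    NumericVector pred = t["pred"];
    for (int i = 0; i < n; ++i) {
      int node = 0;
      while (feat[node] >= 0)
        node = X(i, feat[node]) <= thr[node] ? left[node] : right[node];
      out[i] += pred[node];
    }
  }
  return out / (double)ntree;
}
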