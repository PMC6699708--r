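#include <Rcpp.h>
#include <vector>
#include <algorithm>
#include <cmath>
using namespace Rcpp;

// Random forest regression: CART trees grown on bootstrap samples with
// `mtry` candidate features per split, terminal nodes of at most `nodesize`
// samples, predictions averaged over trees. All randomness goes through
// R's RNG (RNGScope), so set.seed() in R makes fits bit-reproducible.

namespace {

struct Tree {
  std::vector<int> feat;      // split feature (0-based), -1 for leaf
  std::vector<double> thr;    // split threshold (go left if x <= thr)
  std::vector<int> left, right;
  std::vector<double> pred;   // node mean (used at leaves)
};

inline int runif_int(int n) {
  // uniform integer in 0..n-1 via R's RNG
  int k = (int)std::floor(unif_rand() * n);
  if (k >= n) k = n - 1;
  return k;
}

void grow_node(const NumericMatrix& X, const NumericVector& y,
               std::vector<int>& samples, int lo, int hi, // node rows: samples[lo, hi)
               int node, Tree& tree, int mtry, int nodesize,
               std::vector<int>& featbuf) {
  const int n = hi - lo;
  double s = 0.0, s2 = 0.0;
  for (int i = lo; i < hi; ++i) { double v = y[samples[i]]; s += v; s2 += v * v; }
  tree.pred[node] = s / n;
  if (n <= nodesize) return;
  double sse = s2 - s * s / n;
  if (sse <= 1e-12) return; // pure node

  const int p = X.ncol();
  // partial Fisher-Yates draw of mtry distinct features
  for (int j = 0; j < p; ++j) featbuf[j] = j;
  int best_f = -1, best_pos = -1;
  double best_score = -1.0, best_thr = 0.0;
  std::vector<std::pair<double,double> > xy(n);
  for (int m = 0; m < p && m < mtry; ++m) {
    int pick = m + runif_int(p - m);
    std::swap(featbuf[m], featbuf[pick]);
    int f = featbuf[m];
    for (int i = 0; i < n; ++i) {
      int row = samples[lo + i];
      xy[i] = std::make_pair(X(row, f), y[row]);
    }
    std::sort(xy.begin(), xy.end());
    if (xy[0].first == xy[n - 1].first) continue; // constant in node
    double sl = 0.0;
    for (int i = 1; i < n; ++i) {
      sl += xy[i - 1].second;
      if (xy[i].first <= xy[i - 1].first) continue;
      double sr = s - sl;
      double score = sl * sl / i + sr * sr / (n - i);
      if (score > best_score) {
        best_score = score;
        best_f = f;
        best_thr = 0.5 * (xy[i - 1].first + xy[i].first);
        best_pos = i;
      }
    }
  }
  if (best_f < 0) return; // all candidates constant -> leaf

  // partition samples[lo,hi) in place by the chosen split
  int mid = lo;
  for (int i = lo; i < hi; ++i)
    if (X(samples[i], best_f) <= best_thr) std::swap(samples[mid++], samples[i]);
  if (mid == lo || mid == hi) return; // numerical guard; should not happen
  (void)best_pos;

  int l = (int)tree.feat.size();
  tree.feat.push_back(-1); tree.thr.push_back(0.0);
  tree.left.push_back(-1); tree.right.push_back(-1); tree.pred.push_back(0.0);
  int r = (int)tree.feat.size();
  tree.feat.push_back(-1); tree.thr.push_back(0.0);
  tree.left.push_back(-1); tree.right.push_back(-1); tree.pred.push_back(0.0);
  tree.feat[node] = best_f;
  tree.thr[node] = best_thr;
  tree.left[node] = l;
  tree.right[node] = r;
  grow_node(X, y, samples, lo, mid, l, tree, mtry, nodesize, featbuf);
  grow_node(X, y, samples, mid, hi, r, tree, mtry, nodesize, featbuf);
}

inline double tree_predict(const Tree& t, const NumericMatrix& X, int row) {
  int node = 0;
  while (t.feat[node] >= 0)
    node = (X(row, t.feat[node]) <= t.thr[node]) ? t.left[node] : t.right[node];
  return t.pred[node];
}

Tree list_to_tree(const List& tl) {
  Tree t;
  IntegerVector feat = tl["feat"], left = tl["left"], right = tl["right"];
  NumericVector thr = tl["thr"], pred = tl["pred"];
  t.feat.assign(feat.begin(), feat.end());
  t.thr.assign(thr.begin(), thr.end());
  t.left.assign(left.begin(), left.end());
  t.right.assign(right.begin(), right.end());
  t.pred.assign(pred.begin(), pred.end());
  return t;
}

} // namespace

// [[Rcpp::export(name = "cpp_rf_build")]]
List cpp_rf_build(const NumericMatrix& X, const NumericVector& y,
                  int ntree, int mtry, int nodesize) {
  const int n = X.nrow(), p = X.ncol();
  if (mtry < 1) mtry = 1;
  if (mtry > p) mtry = p;
  RNGScope scope;
  List forest(ntree);
  std::vector<int> featbuf(p);
  for (int t = 0; t < ntree; ++t) {
    std::vector<int> samples(n);
    std::vector<int> inbag(n, 0);
    for (int i = 0; i < n; ++i) {
      int k = runif_int(n);
      samples[i] = k;
      inbag[k]++;
    }
    Tree tree;
    tree.feat.push_back(-1); tree.thr.push_back(0.0);
    tree.left.push_back(-1); tree.right.push_back(-1); tree.pred.push_back(0.0);
    grow_node(X, y, samples, 0, n, 0, tree, mtry, nodesize, featbuf);
    std::vector<int> oob;
    for (int i = 0; i < n; ++i) if (inbag[i] == 0) oob.push_back(i);
    forest[t] = List::create(
      _["feat"] = IntegerVector(tree.feat.begin(), tree.feat.end()),
      _["thr"] = NumericVector(tree.thr.begin(), tree.thr.end()),
      _["left"] = IntegerVector(tree.left.begin(), tree.left.end()),
      _["right"] = IntegerVector(tree.right.begin(), tree.right.end()),
      _["pred"] = NumericVector(tree.pred.begin(), tree.pred.end()),
      _["oob"] = IntegerVector(oob.begin(), oob.end()));
  }
  return forest;
}

// [[Rcpp::export(name = "cpp_rf_predict")]]
NumericVector cpp_rf_predict(const List& forest, const NumericMatrix& X) {
  const int n = X.nrow(), ntree = forest.size();
  NumericVector out(n);
  for (int t = 0; t < ntree; ++t) {
    Tree tr = list_to_tree(forest[t]);
    for (int i = 0; i < n; ++i) out[i] += tree_predict(tr, X, i);
  }
  for (int i = 0; i < n; ++i) out[i] /= ntree;
  return out;
}

// Out-of-bag prediction on the training matrix: each row averaged over the
// trees for which it was out of bag; NA if a row was in-bag everywhere.
// [[Rcpp::export(name = "cpp_rf_oob_predict")]]
NumericVector cpp_rf_oob_predict(const List& forest, const NumericMatrix& X) {
  const int n = X.nrow(), ntree = forest.size();
  std::vector<double> acc(n, 0.0);
  std::vector<int> cnt(n, 0);
  for (int t = 0; t < ntree; ++t) {
    List tl = forest[t];
    Tree tr = list_to_tree(tl);
    IntegerVector oob = tl["oob"];
    for (int k = 0; k < oob.size(); ++k) {
      int i = oob[k];
      acc[i] += tree_predict(tr, X, i);
      cnt[i]++;
    }
  }
  NumericVector out(n);
  for (int i = 0; i < n; ++i)
    out[i] = cnt[i] ? acc[i] / cnt[i] : NA_REAL;
  return out;
}

// Permutation importance under the MSE criterion: per tree, the increase in
// out-of-bag MSE when one feature's OOB values are shuffled, averaged over
// `nrep` shuffles and all trees (the unscaled %IncMSE convention).
// [[Rcpp::export(name = "cpp_rf_importance")]]
NumericVector cpp_rf_importance(const List& forest, const NumericMatrix& X,
                                const NumericVector& y, int nrep) {
  const int p = X.ncol(), ntree = forest.size();
  RNGScope scope;
  NumericVector imp(p);
  NumericMatrix Xp(clone(X));
  for (int t = 0; t < ntree; ++t) {
    List tl = forest[t];
    Tree tr = list_to_tree(tl);
    IntegerVector oob = tl["oob"];
    const int m = oob.size();
    if (m < 2) continue;
    double mse0 = 0.0;
    for (int k = 0; k < m; ++k) {
      double e = tree_predict(tr, X, oob[k]) - y[oob[k]];
      mse0 += e * e;
    }
    mse0 /= m;
    std::vector<double> hold(m);
    std::vector<int> perm(m);
    for (int f = 0; f < p; ++f) {
      for (int k = 0; k < m; ++k) hold[k] = X(oob[k], f);
      double dsum = 0.0;
      for (int r = 0; r < nrep; ++r) {
        for (int k = 0; k < m; ++k) perm[k] = k;
        for (int k = m - 1; k > 0; --k) std::swap(perm[k], perm[runif_int(k + 1)]);
        for (int k = 0; k < m; ++k) Xp(oob[k], f) = hold[perm[k]];
        double mse = 0.0;
        for (int k = 0; k < m; ++k) {
          double e = tree_predict(tr, Xp, oob[k]) - y[oob[k]];
          mse += e * e;
        }
        mse /= m;
        dsum += mse - mse0;
      }
      for (int k = 0; k < m; ++k) Xp(oob[k], f) = hold[k];
      imp[f] += dsum / nrep;
    }
  }
  for (int f = 0; f < p; ++f) imp[f] /= ntree;
  return imp;
}
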