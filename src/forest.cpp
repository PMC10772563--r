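#include <Rcpp.h>
#include <vector>
#include <algorithm>
#include <cmath>
using namespace Rcpp;

// Poisson log-likelihood contribution D * log(D / T), with 0*log0 == 0
static inline double dlogdt(double D, double T) {
  if (D <= 0.0 || T <= 0.0) return 0.0;
  return D * std::log(D / T);
}

struct TreeBuf {
  std::vector<int> feature;     // -1 for leaf
  std::vector<double> threshold;
  std::vector<int> left, right; // -1 for leaf
  std::vector<double> lambda, D, T;
};

// draw `m` distinct ints from 0..p-1 via partial Fisher-Yates on R's RNG
static void sample_features(int p, int m, std::vector<int> &pool,
                            std::vector<int> &out) {
  for (int i = 0; i < p; ++i) pool[i] = i;
  out.clear();
  for (int i = 0; i < m; ++i) {
    int j = i + (int)(unif_rand() * (p - i));
    if (j >= p) j = p - 1;
    std::swap(pool[i], pool[j]);
    out.push_back(pool[i]);
  }
}

static int grow_node(const NumericMatrix &X, const IntegerVector &d,
                     const NumericVector &tau, std::vector<int> &rows,
                     int lo, int hi, int mtry, double min_events,
                     int min_obs, double a, double b, TreeBuf &tree) {
  int n = hi - lo;
  double Dn = 0.0, Tn = 0.0;
  for (int i = lo; i < hi; ++i) { Dn += d[rows[i]]; Tn += tau[rows[i]]; }

  int node = (int)tree.feature.size();
  tree.feature.push_back(-1); tree.threshold.push_back(NA_REAL);
  tree.left.push_back(-1); tree.right.push_back(-1);
  tree.lambda.push_back((Dn + a) / (Tn + b));
  tree.D.push_back(Dn); tree.T.push_back(Tn);

  if (Dn < 2.0 * min_events || n < 2 * min_obs) return node;

  int p = X.ncol();
  int m = std::min(mtry, p);
  std::vector<int> pool(p), feats;
  sample_features(p, m, pool, feats);

  double best_gain = 1e-12, best_thr = 0.0;
  int best_f = -1;
  double base = dlogdt(Dn, Tn);

  std::vector<int> idx(n);
  std::vector<double> v(n);
  for (size_t fi = 0; fi < feats.size(); ++fi) {
    int f = feats[fi];
    for (int i = 0; i < n; ++i) { idx[i] = rows[lo + i]; v[i] = X(idx[i], f); }
    std::vector<int> ord(n);
    for (int i = 0; i < n; ++i) ord[i] = i;
    std::sort(ord.begin(), ord.end(),
              [&](int x, int y) { return v[x] < v[y]; });
    double DL = 0.0, TL = 0.0;
    for (int i = 0; i < n - 1; ++i) {
      int r = idx[ord[i]];
      DL += d[r]; TL += tau[r];
      if (v[ord[i + 1]] <= v[ord[i]]) continue; // ties: no cut here
      int nL = i + 1, nR = n - nL;
      double DR = Dn - DL, TR = Tn - TL;
      if (nL < min_obs || nR < min_obs) continue;
      if (DL < min_events || DR < min_events) continue;
      if (TL <= 0.0 || TR <= 0.0) continue;
      double gain = dlogdt(DL, TL) + dlogdt(DR, TR) - base;
      if (gain > best_gain) {
        best_gain = gain;
        best_f = f;
        best_thr = 0.5 * (v[ord[i]] + v[ord[i + 1]]);
      }
    }
  }
  if (best_f < 0) return node;

  // partition rows[lo:hi] in place by the chosen split
  int mid = lo;
  for (int i = lo; i < hi; ++i)
    if (X(rows[i], best_f) <= best_thr) std::swap(rows[mid++], rows[i]);

  tree.feature[node] = best_f;
  tree.threshold[node] = best_thr;
  int lchild = grow_node(X, d, tau, rows, lo, mid, mtry, min_events,
                         min_obs, a, b, tree);
  int rchild = grow_node(X, d, tau, rows, mid, hi, mtry, min_events,
                         min_obs, a, b, tree);
  tree.left[node] = lchild;
  tree.right[node] = rchild;
  return node;
}

// [[Rcpp::export]]
List grow_tree_cpp(NumericMatrix X, IntegerVector d, NumericVector tau,
                   IntegerVector rows, int mtry, double min_events,
                   int min_obs, double a, double b) {
  TreeBuf tree;
  std::vector<int> r(rows.begin(), rows.end());
  grow_node(X, d, tau, r, 0, (int)r.size(), mtry, min_events, min_obs,
            a, b, tree);
  return List::create(
    _["feature"] = IntegerVector(tree.feature.begin(), tree.feature.end()),
    _["threshold"] = NumericVector(tree.threshold.begin(), tree.threshold.end()),
    _["left"] = IntegerVector(tree.left.begin(), tree.left.end()),
    _["right"] = IntegerVector(tree.right.begin(), tree.right.end()),
    _["lambda"] = NumericVector(tree.lambda.begin(), tree.lambda.end()),
    _["D"] = NumericVector(tree.D.begin(), tree.D.end()),
    _["T"] = NumericVector(tree.T.begin(), tree.T.end()));
}

// [[Rcpp::export]]
NumericVector predict_forest_cpp(List trees, NumericMatrix X) {
  int n = X.nrow(), ntree = trees.size();
  NumericVector out(n, 0.0);
  for (int t = 0; t < ntree; ++t) {
    List tr = trees[t];
    IntegerVector feature = tr["feature"];
    NumericVector threshold = tr["threshold"];
    IntegerVector left = tr["left"], right = tr["right"];
    NumericVector lambda = tr["lambda"];
    for (int i = 0; i < n; ++i) {
      int node = 0;
      while (feature[node] >= 0)
        node = (X(i, feature[node]) <= threshold[node]) ? left[node]
                                                        : right[node];
      out[i] += lambda[node];
    }
  }
  return out / (double)ntree;
}

// classical DTW, absolute local distance, unit steps, two-row DP
// [[Rcpp::export]]
double dtw_distance_cpp(NumericVector a, NumericVector b) {
  int n = a.size(), m = b.size();
  if (n == 0 || m == 0) return NA_REAL;
  std::vector<double> prev(m), cur(m);
  prev[0] = std::fabs(a[0] - b[0]);
  for (int j = 1; j < m; ++j) prev[j] = prev[j - 1] + std::fabs(a[0] - b[j]);
  for (int i = 1; i < n; ++i) {
    cur[0] = prev[0] + std::fabs(a[i] - b[0]);
    for (int j = 1; j < m; ++j) {
      double c = std::fabs(a[i] - b[j]);
      cur[j] = c + std::min(prev[j], std::min(cur[j - 1], prev[j - 1]));
    }
    std::swap(prev, cur);
  }
  return prev[m - 1];
}
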