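#include <Rcpp.h>
#include <vector>
#include <algorithm>
#include <cmath>
using namespace Rcpp;

// Regression random forest: bootstrap-bagged, depth-limited CART trees with
// exact variance-reduction (MSE) split search and mean-decrease-of-impurity
// (Gini) feature importance. Defaults mirror scikit-learn's
// RandomForestRegressor (min_samples_split = 2, min_samples_leaf = 1,
// max_features = all). Uses R's RNG so results are reproducible via
// set.seed().

namespace {

struct Node {
  int feature = -1;          // -1 for leaf
  double threshold = 0.0;
  int left = -1, right = -1;
  double value = 0.0;
};

struct TreeBuilder {
  const NumericMatrix &X;
  const NumericVector &y;
  int max_depth, mtry, min_split;
  int n_total;
  std::vector<Node> nodes;
  std::vector<double> importance; // summed SS decreases / n_total
  std::vector<int> feat_pool;

  TreeBuilder(const NumericMatrix &X_, const NumericVector &y_, int max_depth_,
              int mtry_, int min_split_)
      : X(X_), y(y_), max_depth(max_depth_), mtry(mtry_),
        min_split(min_split_), n_total(0), importance(X_.ncol(), 0.0),
        feat_pool(X_.ncol()) {
    for (int f = 0; f < X_.ncol(); ++f) feat_pool[f] = f;
  }

  int build(std::vector<int> &idx, int depth) {
    int n = idx.size();
    double sum = 0.0, sumsq = 0.0;
    for (int i : idx) {
      sum += y[i];
      sumsq += y[i] * y[i];
    }
    double mean = sum / n;
    double ss = sumsq - sum * sum / n; // n * variance
    int me = nodes.size();
    nodes.push_back(Node{});
    nodes[me].value = mean;
    if (depth >= max_depth || n < min_split || ss <= 1e-12) return me;

    // candidate features (partial Fisher-Yates when mtry < p)
    int p = X.ncol();
    int ncand = std::min(mtry, p);
    if (ncand < p) {
      for (int f = 0; f < ncand; ++f) {
        int j = f + (int)(unif_rand() * (p - f));
        if (j >= p) j = p - 1;
        std::swap(feat_pool[f], feat_pool[j]);
      }
    }

    double best_impr = 0.0, best_thr = 0.0;
    int best_f = -1, best_nl = 0;
    std::vector<int> ord(idx);
    for (int c = 0; c < ncand; ++c) {
      int f = feat_pool[c];
      std::sort(ord.begin(), ord.end(), [&](int a, int b) {
        return X(a, f) < X(b, f);
      });
      double lsum = 0.0, lsq = 0.0;
      for (int s = 0; s < n - 1; ++s) {
        double yv = y[ord[s]];
        lsum += yv;
        lsq += yv * yv;
        double xs = X(ord[s], f), xn = X(ord[s + 1], f);
        if (xn <= xs) continue; // not a boundary between distinct values
        int nl = s + 1, nr = n - nl;
        double rsum = sum - lsum, rsq = sumsq - lsq;
        double ssl = lsq - lsum * lsum / nl;
        double ssr = rsq - rsum * rsum / nr;
        double impr = ss - ssl - ssr;
        if (impr > best_impr + 1e-15) {
          best_impr = impr;
          best_f = f;
          // midpoint can round up to xn for adjacent doubles, which would
          // leave the right child empty; fall back to the left value
          double thr = (xs + xn) / 2.0;
          best_thr = (thr < xn) ? thr : xs;
          best_nl = nl;
        }
      }
    }
    if (best_f < 0) return me;

    importance[best_f] += best_impr / n_total;
    std::vector<int> lidx, ridx;
    lidx.reserve(best_nl);
    ridx.reserve(n - best_nl);
    for (int i : idx) {
      if (X(i, best_f) <= best_thr) lidx.push_back(i);
      else ridx.push_back(i);
    }
    int l = build(lidx, depth + 1);
    int r = build(ridx, depth + 1);
    nodes[me].feature = best_f;
    nodes[me].threshold = best_thr;
    nodes[me].left = l;
    nodes[me].right = r;
    return me;
  }

  double predict(const NumericMatrix &Xt, int row) const {
    int v = 0;
    while (nodes[v].feature >= 0) {
      v = (Xt(row, nodes[v].feature) <= nodes[v].threshold) ? nodes[v].left
                                                            : nodes[v].right;
    }
    return nodes[v].value;
  }
};

} // namespace

// [[Rcpp::export]]
List cpp_rf(NumericMatrix X, NumericVector y, NumericMatrix Xtest,
            int n_trees, int max_depth, int mtry, int min_split) {
  int n = X.nrow(), p = X.ncol(), nt = Xtest.nrow();
  NumericVector pred(nt, 0.0);
  NumericVector imp(p, 0.0);
  int informative_trees = 0;
  for (int t = 0; t < n_trees; ++t) {
    std::vector<int> idx(n);
    for (int i = 0; i < n; ++i) {
      int j = (int)(unif_rand() * n);
      if (j >= n) j = n - 1;
      idx[i] = j;
    }
    TreeBuilder tb(X, y, max_depth, mtry, min_split);
    tb.n_total = n;
    tb.build(idx, 0);
    for (int r = 0; r < nt; ++r) pred[r] += tb.predict(Xtest, r);
    double tot = 0.0;
    for (int f = 0; f < p; ++f) tot += tb.importance[f];
    if (tot > 0) {
      ++informative_trees;
      for (int f = 0; f < p; ++f) imp[f] += tb.importance[f] / tot;
    }
  }
  for (int r = 0; r < nt; ++r) pred[r] /= n_trees;
  if (informative_trees > 0) {
    for (int f = 0; f < p; ++f) imp[f] /= informative_trees;
  }
  return List::create(_["pred"] = pred, _["importance"] = imp);
}
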