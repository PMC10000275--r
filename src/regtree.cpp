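#include <Rcpp.h>
#include <vector>
#include <cmath>
#include <algorithm>
#include <limits>

using namespace Rcpp;

// Weighted CART regression tree (variance-reduction / squared-error
// impurity, exact greedy splits at midpoints between adjacent distinct
// feature values). Impurity-based feature importance is accumulated as the
// weighted impurity decrease of every split, the convention of tree
// ensembles in mainstream ML libraries.

struct TreeBuf {
  std::vector<int> feature;     // -1 for leaf
  std::vector<double> threshold;
  std::vector<int> left, right; // 0-based child ids, -1 for leaf
  std::vector<double> value;    // weighted mean response
};

struct Builder {
  const NumericMatrix &X;
  const NumericVector &y;
  const NumericVector &w;
  int max_depth;            // <= 0 means unbounded
  double W_total;
  TreeBuf buf;
  std::vector<double> importance;

  Builder(const NumericMatrix &X_, const NumericVector &y_,
          const NumericVector &w_, int max_depth_)
      : X(X_), y(y_), w(w_), max_depth(max_depth_), W_total(0.0),
        importance(X_.ncol(), 0.0) {
    for (int i = 0; i < w.size(); ++i) W_total += w[i];
  }

  int new_node() {
    buf.feature.push_back(-1);
    buf.threshold.push_back(NA_REAL);
    buf.left.push_back(-1);
    buf.right.push_back(-1);
    buf.value.push_back(0.0);
    return (int)buf.feature.size() - 1;
  }

  // build on the index set idx; returns node id
  int build(std::vector<int> &idx, int depth) {
    int id = new_node();
    double W = 0.0, S = 0.0, S2 = 0.0;
    for (int i : idx) {
      W += w[i];
      S += w[i] * y[i];
      S2 += w[i] * y[i] * y[i];
    }
    double mean = S / W;
    double imp = S2 / W - mean * mean; // weighted variance
    if (imp < 0) imp = 0;
    buf.value[id] = mean;
    bool can_split = (int)idx.size() >= 2 && imp > 0 &&
                     (max_depth <= 0 || depth < max_depth);
    if (!can_split) return id;

    int p = X.ncol();
    double best_gain = 0.0;
    int best_f = -1;
    double best_thr = 0.0;
    std::vector<int> ordbuf(idx);
    for (int f = 0; f < p; ++f) {
      std::sort(ordbuf.begin(), ordbuf.end(), [&](int a, int b) {
        if (X(a, f) != X(b, f)) return X(a, f) < X(b, f);
        return a < b;
      });
      double Wl = 0.0, Sl = 0.0, S2l = 0.0;
      for (size_t j = 0; j + 1 < ordbuf.size(); ++j) {
        int i = ordbuf[j];
        Wl += w[i];
        Sl += w[i] * y[i];
        S2l += w[i] * y[i] * y[i];
        double xcur = X(i, f), xnext = X(ordbuf[j + 1], f);
        if (xcur == xnext) continue; // can't cut inside a tie
        double Wr = W - Wl, Sr = S - Sl, S2r = S2 - S2l;
        double impl = S2l / Wl - (Sl / Wl) * (Sl / Wl);
        double impr = S2r / Wr - (Sr / Wr) * (Sr / Wr);
        if (impl < 0) impl = 0;
        if (impr < 0) impr = 0;
        double gain = (W / W_total) *
                      (imp - (Wl / W) * impl - (Wr / W) * impr);
        if (gain > best_gain + 1e-15) {
          best_gain = gain;
          best_f = f;
          best_thr = (xcur + xnext) / 2.0;
        }
      }
    }
    if (best_f < 0) return id;
    std::vector<int> lidx, ridx;
    for (int i : idx) {
      if (X(i, best_f) <= best_thr)
        lidx.push_back(i);
      else
        ridx.push_back(i);
    }
    if (lidx.empty() || ridx.empty()) return id;
    importance[best_f] += best_gain;
    buf.feature[id] = best_f;
    buf.threshold[id] = best_thr;
    idx.clear();
    idx.shrink_to_fit();
    buf.left[id] = build(lidx, depth + 1);
    buf.right[id] = build(ridx, depth + 1);
    return id;
  }
};

// [[Rcpp::export]]
List cpp_tree_fit(NumericMatrix X, NumericVector y, NumericVector w,
                  int max_depth) {
  Builder b(X, y, w, max_depth);
  std::vector<int> idx(X.nrow());
  for (int i = 0; i < X.nrow(); ++i) idx[i] = i;
  b.build(idx, 0);
  return List::create(
      _["feature"] = wrap(b.buf.feature), _["threshold"] = wrap(b.buf.threshold),
      _["left"] = wrap(b.buf.left), _["right"] = wrap(b.buf.right),
      _["value"] = wrap(b.buf.value), _["importance"] = wrap(b.importance));
}

// [[Rcpp::export]]
NumericVector cpp_tree_predict(List tree, NumericMatrix X) {
  IntegerVector feature = tree["feature"];
  NumericVector threshold = tree["threshold"];
  IntegerVector left = tree["left"], right = tree["right"];
  NumericVector value = tree["value"];
  int n = X.nrow();
  NumericVector out(n);
  for (int i = 0; i < n; ++i) {
    int node = 0;
    while (feature[node] >= 0) {
      node = (X(i, feature[node]) <= threshold[node]) ? left[node]
                                                      : right[node];
    }
    out[i] = value[node];
  }
  return out;
}
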