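#include <Rcpp.h>
#include <vector>
#include <cmath>
#include <algorithm>
#include <limits>

using namespace Rcpp;

// Maximal-information-coefficient machinery: builds the characteristic
// matrix of normalized maximal mutual information over grid shapes
// (k columns x l rows) with k*l <= B(n) = ceil(n^alpha), k,l >= 2.
// One axis is equipartitioned, the other optimized by a dynamic program
// whose cut points are restricted to "clump" boundaries (runs of points
// sharing an x value or a y row); this restriction is lossless because an
// optimal column boundary never splits such a run. When the number of
// clumps exceeds c*k they are merged into superclumps (the approximation).

// Partition sorted values v into at most y groups of near-equal size,
// never splitting ties. Returns number of groups used; fills 0-based
// group index per point.
static int equipartition_axis(const std::vector<double> &v, int y,
                              std::vector<int> &grp) {
  int n = (int)v.size();
  grp.assign(n, 0);
  int i = 0, currgrp = 0, currsize = 0;
  double desired = (double)n / (double)y;
  while (i < n) {
    int s = 1;
    while (i + s < n && v[i + s] == v[i]) ++s;
    double with_run = std::fabs((double)currsize + (double)s - desired);
    double without = std::fabs((double)currsize - desired);
    if (currsize != 0 && with_run >= without && currgrp < y - 1) {
      ++currgrp;
      currsize = 0;
      desired = (double)(n - i) / (double)(y - currgrp);
    }
    for (int j = 0; j < s; ++j) grp[i + j] = currgrp;
    i += s;
    currsize += s;
  }
  return currgrp + 1;
}

// Clump assignment along the x axis: points are in x-sorted order with row
// labels `row` (from the y-axis equipartition). A clump boundary falls
// wherever the row label changes; x-ties spanning several rows are fused
// into a single clump of their own. Returns number of clumps.
static int get_clumps(const std::vector<double> &xs, const std::vector<int> &row,
                      std::vector<int> &clump) {
  int n = (int)xs.size();
  std::vector<long long> lab(row.begin(), row.end());
  long long fresh = -1;
  int i = 0;
  while (i < n) {
    int s = 1;
    bool mixed = false;
    while (i + s < n && xs[i + s] == xs[i]) {
      if (row[i + s] != row[i]) mixed = true;
      ++s;
    }
    if (s > 1 && mixed) {
      for (int j = 0; j < s; ++j) lab[i + j] = fresh;
      --fresh;
    }
    i += s;
  }
  clump.assign(n, 0);
  int nc = 0;
  for (int j = 1; j < n; ++j) {
    if (lab[j] != lab[j - 1]) ++nc;
    clump[j] = nc;
  }
  return nc + 1;
}

static inline double xlog2x(double p) {
  return (p > 0.0) ? p * std::log2(p) : 0.0;
}

// One orientation: equipartition the y axis into l rows (l = 2..B/2),
// optimize the x partition; fills mi[k][l] with raw maximal MI (bits) for
// 2 <= k <= floor(B/l). mi is (kcap+1) x (lcap+1), index [k][l].
static void half_char_matrix(const std::vector<double> &x,
                             const std::vector<double> &y, double B, int cpar,
                             std::vector<std::vector<double>> &mi) {
  int n = (int)x.size();
  int lcap = (int)(B / 2.0);
  // order points by x (ties by y for determinism)
  std::vector<int> ord(n);
  for (int i = 0; i < n; ++i) ord[i] = i;
  std::sort(ord.begin(), ord.end(), [&](int a, int b) {
    if (x[a] != x[b]) return x[a] < x[b];
    return y[a] < y[b];
  });
  std::vector<double> xs(n), ys_by_x(n);
  for (int i = 0; i < n; ++i) {
    xs[i] = x[ord[i]];
    ys_by_x[i] = y[ord[i]];
  }
  // y values sorted, for the equipartition
  std::vector<double> ys(ys_by_x);
  std::sort(ys.begin(), ys.end());

  for (int l = 2; l <= lcap; ++l) {
    int kmax = (int)(B / (double)l);
    if (kmax < 2) continue;
    // row assignment by y-equipartition, mapped onto x-sorted points
    std::vector<int> grp_sorted;
    int q = equipartition_axis(ys, l, grp_sorted);
    // map each y value to its row: rows are contiguous in sorted y, so a
    // value's row = row of its first occurrence in the sorted vector
    std::vector<int> row(n);
    for (int i = 0; i < n; ++i) {
      int pos = (int)(std::lower_bound(ys.begin(), ys.end(), ys_by_x[i]) -
                      ys.begin());
      row[i] = grp_sorted[pos];
    }
    // clumps, then superclumps if too many
    std::vector<int> clump;
    int nc = get_clumps(xs, row, clump);
    int khat = std::max(cpar * kmax, 1);
    if (nc > khat) {
      std::vector<double> asval(clump.begin(), clump.end());
      std::vector<int> super;
      nc = equipartition_axis(asval, khat, super);
      clump = super;
    }
    // cumulative per-row counts at clump boundaries:
    // cum[t][r] = points of row r among the first t clumps (t = 0..nc)
    std::vector<std::vector<int>> cum(nc + 1, std::vector<int>(q, 0));
    std::vector<int> cnt(nc + 1, 0);
    {
      std::vector<int> acc(q, 0);
      int cur = 0, seen = 0;
      for (int i = 0; i < n; ++i) {
        if (clump[i] != cur) {
          cum[cur + 1] = acc;
          cnt[cur + 1] = seen;
          cur = clump[i];
        }
        ++acc[row[i]];
        ++seen;
      }
      cum[cur + 1] = acc;
      cnt[cur + 1] = seen;
    }
    // H(Q): entropy of the row margin over all n points
    double HQ = 0.0;
    for (int r = 0; r < q; ++r) HQ -= xlog2x((double)cum[nc][r] / n);
    // column contribution g(s, t] with global denominator n
    auto colterm = [&](int s, int t) -> double {
      double np = (double)(cnt[t] - cnt[s]);
      double g = -xlog2x(np / n);
      for (int r = 0; r < q; ++r)
        g += xlog2x((double)(cum[t][r] - cum[s][r]) / n);
      return g;
    };
    int kuse = std::min(kmax, nc);
    // F[l][t]: best sum of column terms partitioning first t clumps into l cols
    const double NEG = -std::numeric_limits<double>::infinity();
    std::vector<std::vector<double>> F(kuse + 1,
                                       std::vector<double>(nc + 1, NEG));
    for (int t = 1; t <= nc; ++t) F[1][t] = colterm(0, t);
    for (int cols = 2; cols <= kuse; ++cols) {
      for (int t = cols; t <= nc; ++t) {
        double best = NEG;
        for (int s = cols - 1; s < t; ++s) {
          double v = F[cols - 1][s] + colterm(s, t);
          if (v > best) best = v;
        }
        F[cols][t] = best;
      }
    }
    // best over <= k columns (refinement can only help, but ties/caps make
    // the explicit running max the safe choice)
    double runmax = NEG;
    for (int k = 2; k <= kmax; ++k) {
      int kk = std::min(k, kuse);
      if (kk >= 1 && F[kk][nc] > runmax) runmax = F[kk][nc];
      double I = HQ + runmax;
      if (I < 0) I = 0;
      if (I > mi[k][l]) mi[k][l] = I;
    }
  }
}

// [[Rcpp::export]]
NumericMatrix cpp_char_matrix(NumericVector x, NumericVector y, double alpha,
                              int cpar, bool both_orientations) {
  int n = x.size();
  double B = std::ceil(std::pow((double)n, alpha));
  if (B < 4) B = 4;
  int cap = (int)(B / 2.0);
  std::vector<double> xv(x.begin(), x.end()), yv(y.begin(), y.end());
  std::vector<std::vector<double>> miA(cap + 1, std::vector<double>(cap + 1, -1.0)),
      miB(cap + 1, std::vector<double>(cap + 1, -1.0));
  for (auto &r : miA) std::fill(r.begin(), r.end(), -1.0);
  for (auto &r : miB) std::fill(r.begin(), r.end(), -1.0);
  // initialise computable cells to 0 so half_char_matrix can take maxima
  for (int l = 2; l <= cap; ++l)
    for (int k = 2; k <= (int)(B / (double)l); ++k) {
      miA[k][l] = 0.0;
      miB[k][l] = 0.0;
    }
  half_char_matrix(xv, yv, B, cpar, miA);
  if (both_orientations) half_char_matrix(yv, xv, B, cpar, miB);

  NumericMatrix out(cap - 1, cap - 1); // rows: k = 2..cap, cols: l = 2..cap
  std::fill(out.begin(), out.end(), NA_REAL);
  for (int k = 2; k <= cap; ++k) {
    for (int l = 2; l <= cap; ++l) {
      if ((double)k * (double)l > B) continue;
      double a = miA[k][l];
      // orientation swap: l columns over y, k rows over x
      double b = both_orientations ? miB[l][k] : a;
      double I = std::max(a, b);
      double m = I / std::log2((double)std::min(k, l));
      if (m < 0) m = 0;
      if (m > 1) m = 1;
      out(k - 2, l - 2) = m;
    }
  }
  return out;
}
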