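// Regression random forest for gradient-forest turnover modelling.
//
// Unlike off-the-shelf forests, every split's (predictor, split value,
// impurity decrease) is recorded and binned along the predictor's range;
// per locus the out-of-bag R^2 weights its normalized split-importance
// profile, and profiles are averaged over positive-R^2 loci.  Trees use
// bootstrap resampling, a random predictor subset per split and the
// variance-reduction split criterion.

#include <Rcpp.h>
#include <random>
#include <algorithm>
#include <vector>
using namespace Rcpp;

namespace {

struct Node {
  int var = -1;          // -1: leaf
  double split = 0.0;
  int left = -1, right = -1;
  double value = 0.0;    // leaf mean
};

struct SplitRec { int var; double split; double decrease; };

struct Builder {
  const NumericMatrix& X;
  const double* y;
  int n, P, mtry, min_node;
  std::mt19937& rng;
  std::vector<Node> nodes;
  std::vector<SplitRec> splits;
  std::vector<int> pidx;  // scratch for predictor subset

  Builder(const NumericMatrix& X_, const double* y_, int mtry_,
          int min_node_, std::mt19937& rng_)
      : X(X_), y(y_), n(X_.nrow()), P(X_.ncol()), mtry(mtry_),
        min_node(min_node_), rng(rng_), pidx(P) {
    for (int j = 0; j < P; ++j) pidx[j] = j;
  }

  // deterministic bounded draw (avoids implementation-defined
  // std::uniform_int_distribution)
  int draw(int k) { return (int)(rng() % (unsigned)k); }

  int build(std::vector<int>& idx) {
    int m = (int)idx.size();
    double sum = 0.0, ss = 0.0;
    for (int i : idx) sum += y[i];
    double mean = sum / m;
    for (int i : idx) ss += (y[i] - mean) * (y[i] - mean);
    int me = (int)nodes.size();
    nodes.push_back(Node());
    nodes[me].value = mean;
    if (m < 2 * min_node || ss <= 1e-12) return me;

    // predictor subset: partial Fisher-Yates
    for (int j = 0; j < mtry; ++j) std::swap(pidx[j], pidx[j + draw(P - j)]);

    double best_dec = 0.0, best_split = 0.0;
    int best_var = -1;
    std::vector<std::pair<double, double>> xv(m);  // (x, y)
    for (int jj = 0; jj < mtry; ++jj) {
      int v = pidx[jj];
      for (int k = 0; k < m; ++k) xv[k] = {X(idx[k], v), y[idx[k]]};
      std::sort(xv.begin(), xv.end());
      double lsum = 0.0, lss = 0.0;  // running left stats (Welford-free)
      double ls2 = 0.0;
      for (int k = 0; k < m - 1; ++k) {
        lsum += xv[k].second;
        ls2 += xv[k].second * xv[k].second;
        if (xv[k + 1].first <= xv[k].first) continue;  // tie, no cut here
        int nl = k + 1, nr = m - nl;
        if (nl < min_node || nr < min_node) continue;
        double rsum = sum - lsum;
        double ss_l = ls2 - lsum * lsum / nl;
        // right SS from totals
        double ts2 = 0.0;  // computed lazily below
        (void)ts2;
        double r2sum = 0.0;
        // total sum of squares of y within node: ss + m*mean^2
        r2sum = ss + m * mean * mean - ls2;
        double ss_r = r2sum - rsum * rsum / nr;
        double dec = ss - ss_l - ss_r;
        if (dec > best_dec + 1e-12) {
          best_dec = dec;
          best_var = v;
          best_split = 0.5 * (xv[k].first + xv[k + 1].first);
        }
      }
      (void)lss;
    }
    if (best_var < 0) return me;

    splits.push_back({best_var, best_split, best_dec});
    std::vector<int> li, ri;
    li.reserve(m); ri.reserve(m);
    for (int i : idx)
      (X(i, best_var) <= best_split ? li : ri).push_back(i);
    nodes[me].var = best_var;
    nodes[me].split = best_split;
    int l = build(li);
    int r = build(ri);
    nodes[me].left = l;
    nodes[me].right = r;
    return me;
  }

  double predict(int node, int i) const {
    while (nodes[node].var >= 0)
      node = (X(i, nodes[node].var) <= nodes[node].split)
                 ? nodes[node].left : nodes[node].right;
    return nodes[node].value;
  }
};

}  // namespace

// Fit forests for every locus (columns of Y) and aggregate binned split
// importance.  xmin/xbw give each predictor's bin origin and width.
// [[Rcpp::export(name = ".gf_fit_cpp")]]
List gf_fit_cpp(NumericMatrix X, NumericMatrix Y, int ntree, int mtry,
                int min_node, NumericVector xmin, NumericVector xbw,
                int n_bins, int seed) {
  int n = X.nrow(), P = X.ncol(), L = Y.ncol();
  NumericMatrix agg(P, n_bins);      // mean over R^2>0 loci of share*R^2
  NumericVector r2(L);
  std::mt19937 rng((unsigned)seed);
  std::vector<double> yloc(n);
  std::vector<double> oob_sum(n), raw(P * n_bins);
  std::vector<int> oob_cnt(n);
  std::vector<char> inbag(n);
  int n_pos = 0;

  for (int l = 0; l < L; ++l) {
    for (int i = 0; i < n; ++i) yloc[i] = Y(i, l);
    double ym = 0.0, yv = 0.0;
    for (int i = 0; i < n; ++i) ym += yloc[i];
    ym /= n;
    for (int i = 0; i < n; ++i) yv += (yloc[i] - ym) * (yloc[i] - ym);
    yv /= n;
    if (yv <= 1e-12) { r2[l] = NA_REAL; continue; }  // constant response

    std::fill(oob_sum.begin(), oob_sum.end(), 0.0);
    std::fill(oob_cnt.begin(), oob_cnt.end(), 0);
    std::fill(raw.begin(), raw.end(), 0.0);

    for (int t = 0; t < ntree; ++t) {
      Builder b(X, yloc.data(), mtry, min_node, rng);
      std::fill(inbag.begin(), inbag.end(), 0);
      std::vector<int> idx(n);
      for (int i = 0; i < n; ++i) {
        idx[i] = b.draw(n);
        inbag[idx[i]] = 1;
      }
      int root = b.build(idx);
      for (const SplitRec& s : b.splits) {
        int bin = (int)std::floor((s.split - xmin[s.var]) / xbw[s.var]);
        if (bin < 0) bin = 0;
        if (bin >= n_bins) bin = n_bins - 1;
        raw[s.var * n_bins + bin] += s.decrease;
      }
      for (int i = 0; i < n; ++i)
        if (!inbag[i]) { oob_sum[i] += b.predict(root, i); ++oob_cnt[i]; }
    }
    double mse = 0.0; int nm = 0;
    for (int i = 0; i < n; ++i)
      if (oob_cnt[i] > 0) {
        double e = yloc[i] - oob_sum[i] / oob_cnt[i];
        mse += e * e; ++nm;
      }
    if (nm == 0) { r2[l] = NA_REAL; continue; }
    mse /= nm;
    double r2l = 1.0 - mse / yv;
    r2[l] = r2l;
    if (r2l <= 0.0) continue;
    double tot = 0.0;
    for (double v : raw) tot += v;
    if (tot <= 0.0) continue;
    ++n_pos;
    for (int v = 0; v < P; ++v)
      for (int bme = 0; bme < n_bins; ++bme)
        agg(v, bme) += raw[v * n_bins + bme] / tot * r2l;
  }
  if (n_pos > 0)
    for (int v = 0; v < P; ++v)
      for (int bme = 0; bme < n_bins; ++bme) agg(v, bme) /= n_pos;
  return List::create(_["importance"] = agg, _["r2"] = r2,
                      _["n_positive"] = n_pos);
}
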