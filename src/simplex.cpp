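#include <Rcpp.h>
#include <cmath>
#include <vector>
#include <algorithm>
using namespace Rcpp;

// One-step simplex-projection forecast skill (Pearson correlation between
// predicted and observed next values) for a single embedding dimension.
// Library and prediction sets are disjoint index ranges of the same series.
// Neighbors: E + 1 nearest library states, exponential weights exp(-d/d_min).

// [[Rcpp::export(name = ".simplex_skill_cpp")]]
double simplex_skill_cpp(NumericVector x, int E, int tau,
                         IntegerVector lib_idx,
                         IntegerVector pred_idx) {
  int n = x.size();
  int lag_span = (E - 1) * tau;
  int k = E + 1;

  // usable library states: indices m (0-based) with lag_span <= m, m + 1 < n
  std::vector<int> lib;
  lib.reserve(lib_idx.size());
  for (int j = 0; j < lib_idx.size(); ++j) {
    int m = lib_idx[j];
    if (m >= lag_span && m + 1 < n) lib.push_back(m);
  }
  if ((int)lib.size() < k + 1) return NA_REAL;

  int np = pred_idx.size();
  std::vector<double> pred, obs;
  pred.reserve(np); obs.reserve(np);

  std::vector<double> d(lib.size());
  std::vector<int> ord(lib.size());

  for (int q = 0; q < np; ++q) {
    int m = pred_idx[q];
    if (m < lag_span || m + 1 >= n) continue;
    // distances to all library states
    for (size_t j = 0; j < lib.size(); ++j) {
      double acc = 0.0;
      int mj = lib[j];
      for (int e = 0; e < E; ++e) {
        double diff = x[m - e * tau] - x[mj - e * tau];
        acc += diff * diff;
      }
      d[j] = acc;
    }
    for (size_t j = 0; j < lib.size(); ++j) ord[j] = j;
    std::partial_sort(ord.begin(), ord.begin() + k, ord.end(),
                      [&](int a, int b) { return d[a] < d[b]; });
    double dmin = std::sqrt(d[ord[0]]);
    double wsum = 0.0, ysum = 0.0;
    for (int j = 0; j < k; ++j) {
      double dist = std::sqrt(d[ord[j]]);
      double w = (dmin > 0.0) ? std::exp(-dist / dmin) : (dist == 0.0 ? 1.0 : 0.0);
      if (dmin == 0.0 && dist > 0.0) continue;
      wsum += w;
      ysum += w * x[lib[ord[j]] + 1];
    }
    if (wsum <= 0.0) continue;
    pred.push_back(ysum / wsum);
    obs.push_back(x[m + 1]);
  }

  size_t np_eff = pred.size();
  if (np_eff < 3) return NA_REAL;
  double mp = 0.0, mo = 0.0;
  for (size_t i = 0; i < np_eff; ++i) { mp += pred[i]; mo += obs[i]; }
  mp /= np_eff; mo /= np_eff;
  double sxy = 0.0, sxx = 0.0, syy = 0.0;
  for (size_t i = 0; i < np_eff; ++i) {
    double a = pred[i] - mp, b = obs[i] - mo;
    sxy += a * b; sxx += a * a; syy += b * b;
  }
  if (sxx <= 0.0 || syy <= 0.0) return NA_REAL;
  return sxy / std::sqrt(sxx * syy);
}
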