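#include <Rcpp.h>
#include <random>
#include <cmath>
#include <vector>
using namespace Rcpp;

// Exhaustive search over circular arcs (i, j], 0 <= i < j <= n (the
// full span excluded), of the standardized mean-difference statistic
// comparing probes inside the arc with those outside:
//   T = |mean_in - mean_out| / (s * sqrt(1/k + 1/(n-k))).
// Both the arc and its complement must hold at least min_w probes.
// Ties are broken toward the shorter arc, then the leftmost start.
static void max_arc(const std::vector<double> &S, int n, double s,
                    int min_w, int &bi, int &bj, double &bT) {
  const double tot = S[n];
  bT = -1.0; bi = 0; bj = 0;
  for (int k = min_w; k <= n - min_w; ++k) {
    const double denom = s * std::sqrt(1.0 / k + 1.0 / (n - k));
    for (int i = 0; i + k <= n; ++i) {
      const double sin_ = S[i + k] - S[i];
      const double T = std::fabs((sin_ / k - (tot - sin_) / (n - k)) / denom);
      if (T > bT * (1.0 + 1e-12) + 1e-15) { bT = T; bi = i; bj = i + k; }
    }
  }
}

// True as soon as any arc reaches `threshold` (early exit).
static bool any_arc_reaches(const std::vector<double> &S, int n,
                            double s, int min_w, double threshold) {
  const double tot = S[n];
  for (int k = min_w; k <= n - min_w; ++k) {
    const double denom = s * std::sqrt(1.0 / k + 1.0 / (n - k));
    const double cut = threshold * denom;   // compare on the raw scale
    for (int i = 0; i + k <= n; ++i) {
      const double sin_ = S[i + k] - S[i];
      if (std::fabs(sin_ / k - (tot - sin_) / (n - k)) >= cut)
        return true;
    }
  }
  return false;
}

static std::vector<double> prefix(const std::vector<double> &x) {
  std::vector<double> S(x.size() + 1, 0.0);
  for (size_t i = 0; i < x.size(); ++i) S[i + 1] = S[i] + x[i];
  return S;
}

// [[Rcpp::export]]
List cbs_max_arc(NumericVector x, double s, int min_w) {
  const int n = x.size();
  std::vector<double> v(x.begin(), x.end());
  std::vector<double> S = prefix(v);
  int bi, bj; double bT;
  max_arc(S, n, s, min_w, bi, bj, bT);
  // number of arcs examined, for the Gaussian tail bound
  double n_arcs = 0.0;
  for (int k = min_w; k <= n - min_w; ++k) n_arcs += (n - k + 1);
  return List::create(_["i"] = bi, _["j"] = bj, _["stat"] = bT,
                      _["n_arcs"] = n_arcs);
}

// Permutation screen: count shuffles whose maximal arc statistic
// reaches the observed one.  Deterministic given `seed` (Mersenne
// twister, Fisher-Yates).  Stops early once the running count already
// forces the permutation p-value above `alpha` (the decision is then
// settled), and stops scanning a shuffle at its first exceedance.
// [[Rcpp::export]]
List cbs_perm_exceed(NumericVector x, double s, int min_w,
                     double threshold, int n_perm, int seed,
                     double alpha) {
  const int n = x.size();
  std::vector<double> v(x.begin(), x.end());
  std::mt19937 rng(static_cast<unsigned int>(seed));
  int n_ge = 0, done = 0;
  for (int b = 0; b < n_perm; ++b) {
    for (int i = n - 1; i > 0; --i) {
      std::uniform_int_distribution<int> u(0, i);
      std::swap(v[i], v[u(rng)]);
    }
    std::vector<double> S = prefix(v);
    if (any_arc_reaches(S, n, s, min_w, threshold)) ++n_ge;
    ++done;
    if ((1.0 + n_ge) / (n_perm + 1.0) > alpha) break;
  }
  return List::create(_["n_ge"] = n_ge, _["n_done"] = done);
}
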