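#include <Rcpp.h>
using namespace Rcpp;

// Circular binary segmentation scan statistic.
//
// For a segment x[0..m-1] consider every arc (i, j], 1 <= j - i <= m/2
// (an arc and its circular complement share the breakpoint pair {i, j}
// and the same statistic, so scanning half the widths is exhaustive).
// The statistic compares the arc mean with the complement mean using a
// fixed segment-wide standard deviation:
//   Z(i,j) = (S_j - S_i - k*mu) / (sigma * sqrt(k * (1 - k/m))),  k = j - i.
//
// Both scans use an exact pruning rule: with centered prefix sums
// C[i] = S[i] - i*mu, every arc numerator satisfies |num| <= max(C) - min(C),
// while the denominator k*(1 - k/m) grows with the width k (k <= m/2), so
// the width loop stops as soon as no remaining width can improve on the
// running maximum (observed scan) or reach the exceedance threshold
// (permutation scan).

static double seg_sd(const std::vector<double>& x) {
  int m = x.size();
  if (m < 2) return 0.0;
  double mu = 0.0;
  for (int i = 0; i < m; ++i) mu += x[i];
  mu /= m;
  double ss = 0.0;
  for (int i = 0; i < m; ++i) ss += (x[i] - mu) * (x[i] - mu);
  return std::sqrt(ss / (m - 1));
}

// centered prefix sums and their range
static double centered_prefix(const std::vector<double>& x,
                              std::vector<double>& C) {
  int m = x.size();
  double tot = 0.0;
  for (int i = 0; i < m; ++i) tot += x[i];
  double mu = tot / m;
  C.resize(m + 1);
  C[0] = 0.0;
  double lo = 0.0, hi = 0.0;
  for (int i = 0; i < m; ++i) {
    C[i + 1] = C[i] + x[i] - mu;
    if (C[i + 1] < lo) lo = C[i + 1];
    if (C[i + 1] > hi) hi = C[i + 1];
  }
  return hi - lo;
}

// [[Rcpp::export]]
List cbs_max_stat(NumericVector x) {
  int m = x.size();
  if (m < 2) return List::create(_["t"] = 0.0, _["i"] = 0, _["j"] = 0);
  std::vector<double> v(x.begin(), x.end());
  double sigma = seg_sd(v);
  if (sigma <= 0.0) return List::create(_["t"] = 0.0, _["i"] = 0, _["j"] = 0);
  std::vector<double> C;
  double rng = centered_prefix(v, C);
  double rng2 = rng * rng;
  int kmax = m / 2;
  double best_q = -1.0;  // max of num^2 / (k*(1-k/m))
  int bi = 0, bj = 0;
  for (int k = 1; k <= kmax; ++k) {
    double den = static_cast<double>(k) * (1.0 - static_cast<double>(k) / m);
    if (best_q > 0.0 && best_q * den >= rng2) break;  // no width >= k can win
    for (int i = 0; i + k <= m; ++i) {
      double num = C[i + k] - C[i];
      double q = num * num / den;
      if (q > best_q) {
        best_q = q;
        bi = i;
        bj = i + k;
      }
    }
  }
  return List::create(_["t"] = std::sqrt(best_q) / sigma,
                      _["i"] = bi, _["j"] = bj);
}

// Permutation p-value for the max arc statistic with sequential early
// stopping: permutations stop as soon as enough exceedances accumulate
// to conclude p >= alpha. Uses R's RNG so set.seed() governs the result.
// [[Rcpp::export]]
double cbs_perm_pvalue(NumericVector x, double tobs, int nperm, double alpha) {
  int m = x.size();
  if (m < 2) return 1.0;
  std::vector<double> v(x.begin(), x.end());
  double sigma = seg_sd(v);
  if (sigma <= 0.0) return 1.0;
  double thresh = tobs * tobs * sigma * sigma;  // on the num^2/den scale
  std::vector<double> C;
  int cutoff = static_cast<int>(std::floor(alpha * nperm)) + 1;
  int exceed = 0;
  int kmax = m / 2;
  for (int p = 1; p <= nperm; ++p) {
    // Fisher-Yates shuffle with R's RNG
    for (int i = m - 1; i > 0; --i) {
      int j = static_cast<int>(unif_rand() * (i + 1));
      if (j > i) j = i;
      std::swap(v[i], v[j]);
    }
    double rng = centered_prefix(v, C);
    double rng2 = rng * rng;
    bool hit = false;
    for (int k = 1; k <= kmax && !hit; ++k) {
      double den = static_cast<double>(k) * (1.0 - static_cast<double>(k) / m);
      double lim = thresh * den;
      if (rng2 < lim) break;  // no remaining width can reach the threshold
      for (int i = 0; i + k <= m; ++i) {
        double num = C[i + k] - C[i];
        if (num * num >= lim) { hit = true; break; }
      }
    }
    if (hit) {
      ++exceed;
      if (exceed >= cutoff) return static_cast<double>(exceed) / p;
    }
  }
  return static_cast<double>(exceed) / nperm;
}
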