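#include <Rcpp.h>
#include <vector>
#include <algorithm>
#include <cstdint>
#include <cmath>

using namespace Rcpp;

// Kendall concordance statistics over the voxel time series of one sliding
// window: mean pairwise tau-b across series and Kendall's W across series.
// These are the only O(T^2)-per-pair quantities in the feature set, so they
// get a compiled kernel; everything else is vectorised R.

namespace {

inline int popcnt64(uint64_t x) {
#if defined(__GNUC__) || defined(__clang__)
  return __builtin_popcountll(x);
#else
  int c = 0;
  while (x) { x &= x - 1; ++c; }
  return c;
#endif
}

// sort indices, fill mid-ranks (average ranks for ties), return tied-pair
// count sum_t t*(t-1)/2 and accumulate sum_t (t^3 - t) into tcorr
double rank_column(const double* x, int n, std::vector<int>& idx,
                   std::vector<double>& r, double& tcorr) {
  for (int i = 0; i < n; ++i) idx[i] = i;
  std::sort(idx.begin(), idx.end(), [&](int a, int b) { return x[a] < x[b]; });
  double tp = 0.0;
  int i = 0;
  while (i < n) {
    int j = i;
    while (j + 1 < n && x[idx[j + 1]] == x[idx[i]]) ++j;
    double avg = 0.5 * (i + j) + 1.0;
    for (int k = i; k <= j; ++k) r[idx[k]] = avg;
    double t = j - i + 1;
    tp += t * (t - 1) / 2.0;
    tcorr += t * t * t - t;
    i = j + 1;
  }
  return tp;
}

// exact O(n^2) tau-b for one pair of columns (fallback when ties are present)
double tau_slow(const double* a, const double* b, int n) {
  double S = 0.0, Ta = 0.0, Tb = 0.0;
  for (int i = 0; i < n - 1; ++i) {
    for (int j = i + 1; j < n; ++j) {
      double da = a[i] - a[j], db = b[i] - b[j];
      int sa = (da > 0) - (da < 0);
      int sb = (db > 0) - (db < 0);
      S += sa * sb;
      if (sa == 0) Ta += 1.0;
      if (sb == 0) Tb += 1.0;
    }
  }
  double n0 = 0.5 * n * (n - 1);
  double den = std::sqrt((n0 - Ta) * (n0 - Tb));
  if (den <= 0) return NA_REAL;
  return S / den;
}

} // namespace

// [[Rcpp::export]]
double cpp_kendall_tau_mean(NumericMatrix X) {
  const int n = X.nrow(), k = X.ncol();
  if (k < 2) stop("need at least 2 series for pairwise Kendall tau");
  if (n < 2) stop("need at least 2 time points");

  const int npair = n * (n - 1) / 2;
  const int nw = (npair + 63) / 64;

  // Bit-packed order indicators per series (bit set <=> x_i > x_j for time
  // pair i < j); the discordant-pair count of a tie-free pair of series is
  // then a popcount of the XOR. Ties fall back to the direct formula.
  std::vector<uint64_t> bits((size_t)k * nw, 0ULL);
  std::vector<bool> hasties(k, false);
  {
    std::vector<int> idx(n);
    std::vector<double> r(n);
    for (int c = 0; c < k; ++c) {
      double dummy = 0.0;
      if (rank_column(&X(0, c), n, idx, r, dummy) > 0) {
        hasties[c] = true;
        continue;
      }
      const double* x = &X(0, c);
      uint64_t* bc = &bits[(size_t)c * nw];
      uint64_t cur = 0;
      int p = 0;
      for (int i = 0; i < n - 1; ++i) {
        const double xi = x[i];
        for (int j = i + 1; j < n; ++j, ++p) {
          cur |= (uint64_t)(xi > x[j]) << (p & 63);
          if ((p & 63) == 63) { bc[p >> 6] = cur; cur = 0; }
        }
      }
      if (p & 63) bc[p >> 6] = cur;
    }
  }

  double acc = 0.0;
  int cnt = 0;
  for (int a = 0; a < k - 1; ++a) {
    for (int b = a + 1; b < k; ++b) {
      double tau;
      if (hasties[a] || hasties[b]) {
        tau = tau_slow(&X(0, a), &X(0, b), n);
      } else {
        const uint64_t* ba = &bits[(size_t)a * nw];
        const uint64_t* bb = &bits[(size_t)b * nw];
        int disc = 0;
        for (int w = 0; w < nw; ++w) disc += popcnt64(ba[w] ^ bb[w]);
        tau = (npair - 2.0 * disc) / npair;
      }
      if (!ISNAN(tau)) { acc += tau; ++cnt; }
    }
  }
  if (cnt == 0) return NA_REAL;
  return acc / cnt;
}

// [[Rcpp::export]]
double cpp_kendall_w(NumericMatrix X) {
  // Judges = series (columns), objects = time points (rows); tie-corrected.
  const int n = X.nrow(), k = X.ncol();
  if (k < 2) stop("need at least 2 series for Kendall W");
  if (n < 2) stop("need at least 2 time points");

  std::vector<double> rsum(n, 0.0), r(n);
  std::vector<int> idx(n);
  double tcorr = 0.0; // sum over judges of sum_t (t^3 - t)
  for (int c = 0; c < k; ++c) {
    rank_column(&X(0, c), n, idx, r, tcorr);
    for (int i = 0; i < n; ++i) rsum[i] += r[i];
  }
  double rbar = 0.0;
  for (int i = 0; i < n; ++i) rbar += rsum[i];
  rbar /= n;
  double S = 0.0;
  for (int i = 0; i < n; ++i) S += (rsum[i] - rbar) * (rsum[i] - rbar);
  double den = (double)k * k * (std::pow((double)n, 3.0) - n) - (double)k * tcorr;
  if (den <= 0) return NA_REAL;
  return 12.0 * S / den;
}
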