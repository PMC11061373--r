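#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// Direct form II transposed IIR filter. b, a are the numerator/denominator
// coefficients (a[0] must be 1 after normalisation, enforced here).
// [[Rcpp::export]]
NumericVector cpp_iir_filter(NumericVector b, NumericVector a, NumericVector x) {
  int nb = b.size(), na = a.size(), n = x.size();
  if (na < 1 || a[0] == 0.0) stop("invalid denominator coefficients");
  std::vector<double> bb(b.begin(), b.end()), aa(a.begin(), a.end());
  for (int i = 0; i < nb; ++i) bb[i] /= aa[0];
  for (int i = 0; i < na; ++i) aa[i] /= aa[0];
  int m = std::max(nb, na);
  std::vector<double> z(m, 0.0);
  bb.resize(m, 0.0);
  aa.resize(m, 0.0);
  NumericVector y(n);
  for (int i = 0; i < n; ++i) {
    double xi = x[i];
    double yi = bb[0] * xi + z[0];
    for (int k = 1; k < m; ++k)
      z[k - 1] = bb[k] * xi - aa[k] * yi + z[k];
    y[i] = yi;
  }
  return y;
}

// Discrete Hilbert transform by convolution with an antisymmetric
// odd-length FIR kernel h (type III; even-index taps are zero).
// Only the positive-lag half taps are passed: hk[j] = h[2j+1], j = 0..m-1,
// so y[i] = sum_j hk[j] * (x[i - (2j+1)] - x[i + (2j+1)]), zero-padded edges.
// [[Rcpp::export]]
NumericVector cpp_fir_hilbert(NumericVector x, NumericVector hk) {
  int n = x.size(), m = hk.size();
  NumericVector y(n);
  double *yp = REAL(y);
  const double *xp = REAL(x);
  // lag-outer accumulation: sequential memory streams per lag
  for (int j = 0; j < m; ++j) {
    int lag = 2 * j + 1;
    double h = hk[j];
    int lo = std::min(lag, n), hi = std::max(n - lag, 0);
    for (int i = lo; i < hi; ++i) yp[i] += h * (xp[i - lag] - xp[i + lag]);
    for (int i = 0; i < lo; ++i) {
      double a = (i - lag >= 0) ? xp[i - lag] : 0.0;
      double b = (i + lag < n) ? xp[i + lag] : 0.0;
      yp[i] += h * (a - b);
    }
    for (int i = std::max(hi, lo); i < n; ++i) {
      double a = (i - lag >= 0) ? xp[i - lag] : 0.0;
      double b = (i + lag < n) ? xp[i + lag] : 0.0;
      yp[i] += h * (a - b);
    }
  }
  return y;
}

// Indices (1-based) of strict-left / non-strict-right local maxima of x
// that exceed thr. Matches which(x[i] > x[i-1] & x[i] >= x[i+1] & x[i] > thr).
// [[Rcpp::export]]
IntegerVector cpp_local_maxima(NumericVector x, double thr) {
  int n = x.size();
  std::vector<int> idx;
  for (int i = 1; i + 1 < n; ++i) {
    if (x[i] > thr && x[i] > x[i - 1] && x[i] >= x[i + 1]) idx.push_back(i + 1);
  }
  return wrap(idx);
}
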