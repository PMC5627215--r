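#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// Per-lag Pearson correlation between a(t) and b(t + lag) over the
// non-missing overlap. Two-pass (means first, then centred sums) for
// numerical agreement with a naive per-lag implementation. Returns NA
// where either series is constant over the overlap; n_overlap counts the
// contributing frames.
// [[Rcpp::export]]
List pearson_lag_curve_cpp(NumericVector a, NumericVector b,
                           IntegerVector lags) {
  const int n = a.size();
  const int nl = lags.size();
  NumericVector curve(nl, NA_REAL);
  IntegerVector nov(nl);
  for (int k = 0; k < nl; ++k) {
    const int lag = lags[k];
    const int lo = (lag >= 0) ? 0 : -lag;
    const int hi = (lag >= 0) ? n - lag : n;
    double sa = 0, sb = 0;
    int m = 0;
    for (int t = lo; t < hi; ++t) {
      const double x = a[t], y = b[t + lag];
      if (ISNAN(x) || ISNAN(y)) continue;
      sa += x;
      sb += y;
      ++m;
    }
    nov[k] = m;
    if (m < 2) continue;
    const double ma = sa / m, mb = sb / m;
    double saa = 0, sbb = 0, sab = 0;
    for (int t = lo; t < hi; ++t) {
      const double x = a[t], y = b[t + lag];
      if (ISNAN(x) || ISNAN(y)) continue;
      saa += (x - ma) * (x - ma);
      sbb += (y - mb) * (y - mb);
      sab += (x - ma) * (y - mb);
    }
    if (saa <= 0 || sbb <= 0) continue;  // constant: correlation undefined
    curve[k] = sab / std::sqrt(saa * sbb);
  }
  return List::create(_["curve"] = curve, _["n_overlap"] = nov);
}

// Per-lag mean dot product of unit headings h_i(t) . h_j(t + lag) over
// frames where both headings are defined.
// [[Rcpp::export]]
List dot_lag_curve_cpp(NumericVector hxi, NumericVector hyi,
                       NumericVector hxj, NumericVector hyj,
                       IntegerVector lags) {
  const int n = hxi.size();
  const int nl = lags.size();
  NumericVector curve(nl, NA_REAL);
  IntegerVector nov(nl);
  for (int k = 0; k < nl; ++k) {
    const int lag = lags[k];
    const int lo = (lag >= 0) ? 0 : -lag;
    const int hi = (lag >= 0) ? n - lag : n;
    double s = 0;
    int m = 0;
    for (int t = lo; t < hi; ++t) {
      const double xi = hxi[t], yi = hyi[t];
      const double xj = hxj[t + lag], yj = hyj[t + lag];
      if (ISNAN(xi) || ISNAN(yi) || ISNAN(xj) || ISNAN(yj)) continue;
      s += xi * xj + yi * yj;
      ++m;
    }
    nov[k] = m;
    if (m > 0) curve[k] = s / m;
  }
  return List::create(_["curve"] = curve, _["n_overlap"] = nov);
}
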