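#include <Rcpp.h>
#include <algorithm>
#include <cmath>
#include <vector>
using namespace Rcpp;

// Per-window sufficient statistics for screening and the current-behavior
// metrics, one column = one window. Returns, per column: min, max, mean,
// centered sum of squares, max |x - mean| (outlier screening), type-7
// median and quartiles, sum |x - median| (MAD), and the sums of
// |10*log10(x/r)| and its cube for the two M-value references.
// [[Rcpp::export(name = ".window_stats_cpp")]]
List window_stats_cpp(NumericMatrix x, double r1, double r2) {
  const int n = x.nrow(), k = x.ncol();
  NumericVector mn(k), mx(k), mean(k), ss(k), maxdev(k),
      med(k), q25(k), q75(k), mad_sum(k),
      m1_sum(k), m1_cube(k), m2_sum(k), m2_cube(k);
  std::vector<double> buf(n);
  const double l1 = std::log10(r1), l2 = std::log10(r2);
  for (int j = 0; j < k; ++j) {
    const double* col = &x(0, j);
    double s = 0, lo = col[0], hi = col[0];
    for (int i = 0; i < n; ++i) {
      const double v = col[i];
      s += v;
      if (v < lo) lo = v;
      if (v > hi) hi = v;
    }
    const double mu = s / n;
    double sq = 0, mdev = 0, s1 = 0, c1 = 0, s2 = 0, c2 = 0;
    for (int i = 0; i < n; ++i) {
      const double v = col[i];
      const double d = v - mu, ad = std::fabs(d);
      sq += d * d;
      if (ad > mdev) mdev = ad;
      const double lv = std::log10(v);
      const double d1 = std::fabs(10.0 * (lv - l1));
      const double d2 = std::fabs(10.0 * (lv - l2));
      s1 += d1; c1 += d1 * d1 * d1;
      s2 += d2; c2 += d2 * d2 * d2;
    }
    std::copy(col, col + n, buf.begin());
    std::sort(buf.begin(), buf.end());
    auto q7 = [&](double p) {
      const double h = (n - 1) * p;
      const int ilo = (int)std::floor(h);
      const double frac = h - ilo;
      return frac > 0 ? buf[ilo] + frac * (buf[ilo + 1] - buf[ilo]) : buf[ilo];
    };
    const double mdn = q7(0.5);
    double madsum = 0;
    for (int i = 0; i < n; ++i) madsum += std::fabs(col[i] - mdn);
    mn[j] = lo; mx[j] = hi; mean[j] = mu; ss[j] = sq; maxdev[j] = mdev;
    med[j] = mdn; q25[j] = q7(0.25); q75[j] = q7(0.75); mad_sum[j] = madsum;
    m1_sum[j] = s1; m1_cube[j] = c1; m2_sum[j] = s2; m2_cube[j] = c2;
  }
  return List::create(
      _["min"] = mn, _["max"] = mx, _["mean"] = mean, _["ss"] = ss,
      _["max_absdev"] = maxdev, _["median"] = med, _["q25"] = q25,
      _["q75"] = q75, _["mad_sum"] = mad_sum, _["m1_sum"] = m1_sum,
      _["m1_cube"] = m1_cube, _["m2_sum"] = m2_sum, _["m2_cube"] = m2_cube);
}

// AR(1) temperature synthesis: state recursion, level addition and
// rounding to the device's two decimals in one pass. Uses R's RNG so a
// set.seed() upstream fixes the output. inno_sd may be a scalar or a
// per-sample vector.
// [[Rcpp::export(name = ".ar1_temp_cpp")]]
NumericVector ar1_temp_cpp(NumericVector level, double phi,
                           NumericVector inno_sd) {
  const int n = level.size();
  const bool scalar_sd = inno_sd.size() == 1;
  NumericVector out(n);
  RNGScope scope;
  double state = norm_rand() * inno_sd[0] / std::sqrt(1.0 - phi * phi);
  for (int i = 0; i < n; ++i) {
    const double sd = scalar_sd ? inno_sd[0] : inno_sd[i];
    state = phi * state + sd * norm_rand();
    out[i] = std::round((level[i] + state) * 100.0) / 100.0;
  }
  return out;
}

// Gather the N trailing samples of each full window into an N x k matrix
// (hi = index of the last sample of each window, 1-based).
// [[Rcpp::export(name = ".gather_windows_cpp")]]
NumericMatrix gather_windows_cpp(NumericVector values, IntegerVector hi,
                                 int n) {
  const int k = hi.size();
  NumericMatrix out(n, k);
  for (int j = 0; j < k; ++j) {
    const int start = hi[j] - n;   // 0-based index of first sample
    std::copy(values.begin() + start, values.begin() + start + n,
              out.begin() + (R_xlen_t)j * n);
  }
  return out;
}
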