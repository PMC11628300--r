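// Empirical mode decomposition core: extrema detection, mirror-extended
// natural-cubic-spline envelopes, Cauchy-type sift stopping, ensemble variant.
#include <Rcpp.h>
#include <cmath>
#include <vector>
using namespace Rcpp;

// Interior extrema of x. Plateaus are compressed: runs of equal values count
// once, at the last sample of the run preceding the direction change.
static void find_extrema(const std::vector<double>& x,
                         std::vector<int>& maxima, std::vector<int>& minima) {
  maxima.clear(); minima.clear();
  const int n = (int)x.size();
  int prev_sign = 0, prev_idx = 0;
  for (int i = 1; i < n; ++i) {
    double d = x[i] - x[i - 1];
    int s = (d > 0) - (d < 0);
    if (s == 0) continue;
    if (prev_sign > 0 && s < 0) maxima.push_back(prev_idx);
    if (prev_sign < 0 && s > 0) minima.push_back(prev_idx);
    prev_sign = s;
    prev_idx = i;
  }
}

// Natural cubic spline through (t, v), evaluated at 0..n-1.
static std::vector<double> nat_spline_eval(const std::vector<double>& t,
                                           const std::vector<double>& v,
                                           int n) {
  const int m = (int)t.size();
  std::vector<double> out(n);
  if (m == 1) { std::fill(out.begin(), out.end(), v[0]); return out; }
  if (m == 2) {
    double slope = (v[1] - v[0]) / (t[1] - t[0]);
    for (int i = 0; i < n; ++i) out[i] = v[0] + slope * (i - t[0]);
    return out;
  }
  // second derivatives via tridiagonal solve (Thomas algorithm)
  std::vector<double> h(m - 1), alpha(m, 0.0), l(m), mu(m), z(m), c(m);
  for (int i = 0; i < m - 1; ++i) h[i] = t[i + 1] - t[i];
  for (int i = 1; i < m - 1; ++i)
    alpha[i] = 3.0 * ((v[i + 1] - v[i]) / h[i] - (v[i] - v[i - 1]) / h[i - 1]);
  l[0] = 1.0; mu[0] = 0.0; z[0] = 0.0;
  for (int i = 1; i < m - 1; ++i) {
    l[i] = 2.0 * (t[i + 1] - t[i - 1]) - h[i - 1] * mu[i - 1];
    mu[i] = h[i] / l[i];
    z[i] = (alpha[i] - h[i - 1] * z[i - 1]) / l[i];
  }
  c[m - 1] = 0.0;
  for (int i = m - 2; i >= 0; --i) c[i] = z[i] - mu[i] * c[i + 1];
  int seg = 0;
  for (int i = 0; i < n; ++i) {
    double ti = (double)i;
    while (seg < m - 2 && t[seg + 1] < ti) ++seg;
    double dt = ti - t[seg], hs = h[seg];
    double b = (v[seg + 1] - v[seg]) / hs - hs * (2.0 * c[seg] + c[seg + 1]) / 3.0;
    double d = (c[seg + 1] - c[seg]) / (3.0 * hs);
    out[i] = v[seg] + b * dt + c[seg] * dt * dt + d * dt * dt * dt;
  }
  return out;
}

// Anchor set for one envelope: the series endpoints (always, so envelopes
// stay clamped to the data at the record ends and secular trends cannot leak
// into an IMF), the interior extrema, and a mirror-extension of up to two
// extrema across each boundary to stabilise the spline ends.
static void envelope_anchors(const std::vector<double>& x,
                             const std::vector<int>& ext, bool upper,
                             std::vector<double>& t, std::vector<double>& v) {
  const int n = (int)x.size();
  t.clear(); v.clear();
  std::vector<double> ti, vi;
  for (int i : ext) { ti.push_back((double)i); vi.push_back(x[i]); }
  // promote an endpoint to an extremum only when it sticks out beyond the
  // nearest one; otherwise the envelope continues freely past the ends and
  // endpoint noise cannot pin the residual.
  if (ti.empty() || (upper ? x[0] > vi.front() : x[0] < vi.front())) {
    ti.insert(ti.begin(), 0.0); vi.insert(vi.begin(), x[0]);
  }
  if (upper ? x[n - 1] > vi.back() : x[n - 1] < vi.back()) {
    ti.push_back((double)(n - 1)); vi.push_back(x[n - 1]);
  }
  const int m = (int)ti.size();
  const double end = (double)(n - 1);
  // mirror the first/last (up to) two anchors across the series boundaries,
  // keeping anchor positions ascending
  for (int k = std::min(1, m - 1); k >= 0; --k) {
    if (ti[k] > 0.0) { t.push_back(-ti[k]); v.push_back(vi[k]); }
  }
  for (int k = 0; k < m; ++k) { t.push_back(ti[k]); v.push_back(vi[k]); }
  for (int k = m - 1; k >= std::max(0, m - 2); --k) {
    if (ti[k] < end) { t.push_back(2.0 * end - ti[k]); v.push_back(vi[k]); }
  }
}

static int n_interior_extrema(const std::vector<double>& x) {
  std::vector<int> mx, mn;
  find_extrema(x, mx, mn);
  return (int)(mx.size() + mn.size());
}

// One EMD pass. Returns list(imfs = n x k matrix, residual = numeric).
// [[Rcpp::export(name = ".emd_cpp")]]
List emd_cpp(NumericVector x, int max_imfs = 12, double sd_tol = 0.2,
             int max_sifts = 10) {
  const int n = x.size();
  std::vector<double> r(x.begin(), x.end());
  std::vector<std::vector<double>> imfs;
  std::vector<int> mx, mn;
  double x_lo = x[0], x_hi = x[0];
  for (int i = 1; i < n; ++i) {
    if (x[i] < x_lo) x_lo = x[i];
    if (x[i] > x_hi) x_hi = x[i];
  }
  const double negligible = 1e-12 * (x_hi - x_lo);
  while ((int)imfs.size() < max_imfs) {
    if (n_interior_extrema(r) < 2) break;
    double r_lo = r[0], r_hi = r[0];
    for (int i = 1; i < n; ++i) {
      if (r[i] < r_lo) r_lo = r[i];
      if (r[i] > r_hi) r_hi = r[i];
    }
    if (r_hi - r_lo <= negligible) break; // remainder is numerically constant
    std::vector<double> h = r;
    for (int s = 0; s < max_sifts; ++s) {
      find_extrema(h, mx, mn);
      if (mx.empty() || mn.empty() || (int)(mx.size() + mn.size()) < 2) break;
      std::vector<double> tu, vu, tl, vl;
      envelope_anchors(h, mx, true, tu, vu);
      envelope_anchors(h, mn, false, tl, vl);
      std::vector<double> up = nat_spline_eval(tu, vu, n);
      std::vector<double> lo = nat_spline_eval(tl, vl, n);
      double num = 0.0, den = 0.0;
      for (int i = 0; i < n; ++i) {
        double m = 0.5 * (up[i] + lo[i]);
        num += m * m; den += h[i] * h[i];
        h[i] -= m;
      }
      if (den > 0.0 && num / den < sd_tol) break;
    }
    imfs.push_back(h);
    for (int i = 0; i < n; ++i) r[i] -= h[i];
  }
  const int k = (int)imfs.size();
  NumericMatrix M(n, k);
  for (int j = 0; j < k; ++j)
    for (int i = 0; i < n; ++i) M(i, j) = imfs[j][i];
  return List::create(_["imfs"] = M,
                      _["residual"] = NumericVector(r.begin(), r.end()));
}

// Ensemble EMD: average member IMFs (aligned by index, zero-padded) and
// residuals over white-noise-perturbed copies. Noise drawn from R's RNG so
// set.seed() in the caller controls reproducibility. With paired = true and
// even ensembles, members use +w / -w pairs so the noise cancels exactly.
// [[Rcpp::export(name = ".eemd_cpp")]]
List eemd_cpp(NumericVector x, int ensemble_size = 100,
              double noise_sd = 0.0, bool paired = true,
              int max_imfs = 12, double sd_tol = 0.2, int max_sifts = 10) {
  const int n = x.size();
  if (ensemble_size <= 1 || noise_sd <= 0.0)
    return emd_cpp(x, max_imfs, sd_tol, max_sifts);
  bool use_pairs = paired && ensemble_size % 2 == 0;
  std::vector<NumericMatrix> member_imfs;
  std::vector<std::vector<double>> member_res;
  member_imfs.reserve(ensemble_size);
  int max_k = 0;
  NumericVector w(n), y(n);
  for (int e = 0; e < ensemble_size; ++e) {
    if (!use_pairs || e % 2 == 0) {
      for (int i = 0; i < n; ++i) w[i] = R::rnorm(0.0, noise_sd);
      for (int i = 0; i < n; ++i) y[i] = x[i] + w[i];
    } else {
      for (int i = 0; i < n; ++i) y[i] = x[i] - w[i];
    }
    List dec = emd_cpp(y, max_imfs, sd_tol, max_sifts);
    NumericMatrix M = dec["imfs"];
    NumericVector r = dec["residual"];
    member_imfs.push_back(M);
    member_res.push_back(std::vector<double>(r.begin(), r.end()));
    if (M.ncol() > max_k) max_k = M.ncol();
  }
  NumericMatrix avg(n, max_k);
  NumericVector res(n);
  for (int e = 0; e < ensemble_size; ++e) {
    const NumericMatrix& M = member_imfs[e];
    for (int j = 0; j < M.ncol(); ++j)
      for (int i = 0; i < n; ++i) avg(i, j) += M(i, j);
    for (int i = 0; i < n; ++i) res[i] += member_res[e][i];
  }
  double inv = 1.0 / ensemble_size;
  for (int j = 0; j < max_k; ++j)
    for (int i = 0; i < n; ++i) avg(i, j) *= inv;
  for (int i = 0; i < n; ++i) res[i] *= inv;
  return List::create(_["imfs"] = avg, _["residual"] = res);
}

// [[Rcpp::export(name = ".n_interior_extrema_cpp")]]
int n_interior_extrema_cpp(NumericVector x) {
  std::vector<double> v(x.begin(), x.end());
  return n_interior_extrema(v);
}
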