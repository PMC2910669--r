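#include <Rcpp.h>
#include <vector>
#include <algorithm>
#include <cmath>
using namespace Rcpp;

// Sifting core for empirical mode decomposition. All indices returned to R
// are 1-based; everything internal is 0-based.

// Local extrema with the plateau rule: a run of equal samples contributes a
// single extremum at the run midpoint (lower index for even-length runs).
// An extremum must be strictly greater (smaller) than both neighbouring runs.
static void find_extrema_core(const double* x, int n,
                              std::vector<int>& maxima,
                              std::vector<int>& minima) {
  maxima.clear();
  minima.clear();
  if (n < 3) return;
  std::vector<int> start;
  std::vector<double> val;
  start.reserve(64);
  val.reserve(64);
  start.push_back(0);
  val.push_back(x[0]);
  for (int i = 1; i < n; ++i) {
    if (x[i] != val.back()) {
      start.push_back(i);
      val.push_back(x[i]);
    }
  }
  const int m = static_cast<int>(val.size());
  if (m < 3) return;
  for (int i = 1; i < m - 1; ++i) {
    const int len = start[i + 1] - start[i];
    const int mid = start[i] + (len - 1) / 2;
    if (val[i] > val[i - 1] && val[i] > val[i + 1]) {
      maxima.push_back(mid);
    } else if (val[i] < val[i - 1] && val[i] < val[i + 1]) {
      minima.push_back(mid);
    }
  }
}

// Natural cubic spline through (xs, ys), xs strictly increasing, evaluated
// at the integers 0..n-1. Linear extrapolation outside the knot range
// (consistent with the natural boundary condition of zero curvature).
static void natural_spline_eval(const std::vector<double>& xs,
                                const std::vector<double>& ys,
                                int n, std::vector<double>& out) {
  const int m = static_cast<int>(xs.size());
  out.assign(n, 0.0);
  if (m == 1) {
    std::fill(out.begin(), out.end(), ys[0]);
    return;
  }
  if (m == 2) {
    const double s = (ys[1] - ys[0]) / (xs[1] - xs[0]);
    for (int t = 0; t < n; ++t) out[t] = ys[0] + s * (t - xs[0]);
    return;
  }
  std::vector<double> h(m - 1);
  for (int i = 0; i < m - 1; ++i) h[i] = xs[i + 1] - xs[i];
  // second derivatives M[0..m-1], natural ends: M[0] = M[m-1] = 0
  std::vector<double> M(m, 0.0);
  const int k = m - 2;  // interior unknowns
  std::vector<double> diag(k), rhs(k), sub(k), sup(k);
  for (int i = 0; i < k; ++i) {
    sub[i] = h[i] / 6.0;
    diag[i] = (h[i] + h[i + 1]) / 3.0;
    sup[i] = h[i + 1] / 6.0;
    rhs[i] = (ys[i + 2] - ys[i + 1]) / h[i + 1] - (ys[i + 1] - ys[i]) / h[i];
  }
  // Thomas algorithm
  for (int i = 1; i < k; ++i) {
    const double w = sub[i] / diag[i - 1];
    diag[i] -= w * sup[i - 1];
    rhs[i] -= w * rhs[i - 1];
  }
  M[k] = rhs[k - 1] / diag[k - 1];
  for (int i = k - 2; i >= 0; --i) {
    M[i + 1] = (rhs[i] - sup[i] * M[i + 2]) / diag[i];
  }
  // evaluation sweep (targets 0..n-1 are sorted)
  int seg = 0;
  for (int t = 0; t < n; ++t) {
    const double xt = static_cast<double>(t);
    if (xt <= xs[0]) {
      const double s0 = (ys[1] - ys[0]) / h[0] - h[0] / 6.0 * (2.0 * M[0] + M[1]);
      out[t] = ys[0] + s0 * (xt - xs[0]);
      continue;
    }
    if (xt >= xs[m - 1]) {
      const double s1 = (ys[m - 1] - ys[m - 2]) / h[m - 2] +
                        h[m - 2] / 6.0 * (M[m - 2] + 2.0 * M[m - 1]);
      out[t] = ys[m - 1] + s1 * (xt - xs[m - 1]);
      continue;
    }
    while (seg < m - 2 && xs[seg + 1] < xt) ++seg;
    const double a = (xs[seg + 1] - xt) / h[seg];
    const double b = (xt - xs[seg]) / h[seg];
    out[t] = a * ys[seg] + b * ys[seg + 1] +
             ((a * a * a - a) * M[seg] + (b * b * b - b) * M[seg + 1]) *
                 (h[seg] * h[seg]) / 6.0;
  }
}

// Mirror-extend up to two extrema about each end of the signal, then fit the
// natural cubic spline envelope through them.
static void spline_envelope(const std::vector<int>& idx, const double* x,
                            int n, std::vector<double>& out) {
  const int k = static_cast<int>(idx.size());
  const int ne = std::min(2, k);
  std::vector<double> xs, ys;
  xs.reserve(k + 4);
  ys.reserve(k + 4);
  for (int i = ne - 1; i >= 0; --i) {  // reflected about sample 0
    xs.push_back(-static_cast<double>(idx[i]));
    ys.push_back(x[idx[i]]);
  }
  for (int i = 0; i < k; ++i) {
    xs.push_back(static_cast<double>(idx[i]));
    ys.push_back(x[idx[i]]);
  }
  for (int i = 0; i < ne; ++i) {  // reflected about sample n-1
    const int j = k - 1 - i;
    xs.push_back(2.0 * (n - 1) - static_cast<double>(idx[j]));
    ys.push_back(x[idx[j]]);
  }
  // drop duplicated abscissae (an extremum sitting exactly on an endpoint)
  std::vector<double> xs2, ys2;
  xs2.reserve(xs.size());
  ys2.reserve(ys.size());
  for (size_t i = 0; i < xs.size(); ++i) {
    if (xs2.empty() || xs[i] > xs2.back()) {
      xs2.push_back(xs[i]);
      ys2.push_back(ys[i]);
    }
  }
  natural_spline_eval(xs2, ys2, n, out);
}

// mean of upper and lower spline envelopes; returns false when the signal
// has no usable oscillation (fewer than one maximum or one minimum).
static bool mean_envelope_core(const double* x, int n,
                               std::vector<double>& env) {
  std::vector<int> ma, mi;
  find_extrema_core(x, n, ma, mi);
  if (ma.size() < 1 || mi.size() < 1) return false;
  std::vector<double> up, lo;
  spline_envelope(ma, x, n, up);
  spline_envelope(mi, x, n, lo);
  env.resize(n);
  for (int i = 0; i < n; ++i) env[i] = 0.5 * (up[i] + lo[i]);
  return true;
}

static int zero_crossings(const double* x, int n) {
  int count = 0;
  double prev = 0.0;
  for (int i = 0; i < n; ++i) {
    if (x[i] == 0.0) continue;
    const double s = x[i] > 0.0 ? 1.0 : -1.0;
    if (prev != 0.0 && s != prev) ++count;
    prev = s;
  }
  return count;
}

// IMF definition check: |#extrema - #zero-crossings| <= 1 and the mean
// envelope stays within tol * peak-to-peak of zero.
static bool is_imf_core(const double* x, int n, double tol) {
  std::vector<int> ma, mi;
  find_extrema_core(x, n, ma, mi);
  if (ma.size() < 1 || mi.size() < 1) return false;
  const int ne = static_cast<int>(ma.size() + mi.size());
  const int nz = zero_crossings(x, n);
  if (std::abs(ne - nz) > 1) return false;
  std::vector<double> env;
  if (!mean_envelope_core(x, n, env)) return false;
  double lo = x[0], hi = x[0], worst = 0.0;
  for (int i = 0; i < n; ++i) {
    lo = std::min(lo, x[i]);
    hi = std::max(hi, x[i]);
  }
  for (int i = 0; i < n; ++i) worst = std::max(worst, std::abs(env[i]));
  return worst <= tol * (hi - lo);
}

// One IMF by iterated envelope-mean subtraction. Terminates when the
// stoppage statistic SD_k = ||h_{k-1}-h_k||^2 / ||h_{k-1}||^2 drops below
// eps AND the working signal passes the IMF definition check, or at the
// iteration cap.
static void extract_imf_core(const std::vector<double>& x, double eps,
                             int max_iters, double imf_tol,
                             std::vector<double>& h, int& iters,
                             double& sd_last, bool& capped) {
  const int n = static_cast<int>(x.size());
  h = x;
  iters = 0;
  sd_last = NA_REAL;
  capped = false;
  std::vector<double> env;
  while (true) {
    if (!mean_envelope_core(h.data(), n, env)) break;
    double num = 0.0, den = 0.0;
    for (int i = 0; i < n; ++i) {
      num += env[i] * env[i];
      den += h[i] * h[i];
      h[i] -= env[i];
    }
    ++iters;
    sd_last = den > 0.0 ? num / den : 0.0;
    if (iters >= max_iters) {
      capped = !(sd_last < eps);
      break;
    }
    if (sd_last < eps && is_imf_core(h.data(), n, imf_tol)) break;
  }
}

static bool is_monotonic_core(const double* x, int n) {
  std::vector<int> ma, mi;
  find_extrema_core(x, n, ma, mi);
  if (static_cast<int>(ma.size() + mi.size()) < 2) return true;
  double lo = x[0], hi = x[0];
  for (int i = 0; i < n; ++i) {
    lo = std::min(lo, x[i]);
    hi = std::max(hi, x[i]);
  }
  const double tol = 1e-12 * (hi - lo);
  bool up = true, down = true;
  for (int i = 1; i < n; ++i) {
    const double d = x[i] - x[i - 1];
    if (d < -tol) up = false;
    if (d > tol) down = false;
    if (!up && !down) return false;
  }
  return true;
}

// [[Rcpp::export(.cppFindExtrema)]]
List cppFindExtrema(NumericVector x) {
  std::vector<int> ma, mi;
  find_extrema_core(x.begin(), x.size(), ma, mi);
  IntegerVector rma(ma.size()), rmi(mi.size());
  for (size_t i = 0; i < ma.size(); ++i) rma[i] = ma[i] + 1;
  for (size_t i = 0; i < mi.size(); ++i) rmi[i] = mi[i] + 1;
  return List::create(_["maxima"] = rma, _["minima"] = rmi);
}

// [[Rcpp::export(.cppMeanEnvelope)]]
SEXP cppMeanEnvelope(NumericVector x, IntegerVector maxima,
                     IntegerVector minima) {
  const int n = x.size();
  if (maxima.size() < 1 || minima.size() < 1) return R_NilValue;
  std::vector<int> ma(maxima.size()), mi(minima.size());
  for (int i = 0; i < maxima.size(); ++i) ma[i] = maxima[i] - 1;
  for (int i = 0; i < minima.size(); ++i) mi[i] = minima[i] - 1;
  std::vector<double> up, lo;
  spline_envelope(ma, x.begin(), n, up);
  spline_envelope(mi, x.begin(), n, lo);
  NumericVector out(n);
  for (int i = 0; i < n; ++i) out[i] = 0.5 * (up[i] + lo[i]);
  return out;
}

// [[Rcpp::export(.cppIsIMF)]]
bool cppIsIMF(NumericVector x, double tol) {
  return is_imf_core(x.begin(), x.size(), tol);
}

// [[Rcpp::export(.cppExtractIMF)]]
List cppExtractIMF(NumericVector x, double eps, int maxIters, double imfTol) {
  std::vector<double> xin(x.begin(), x.end()), h;
  int iters;
  double sd_last;
  bool capped;
  extract_imf_core(xin, eps, maxIters, imfTol, h, iters, sd_last, capped);
  return List::create(_["imf"] = NumericVector(h.begin(), h.end()),
                      _["nIters"] = iters, _["sdLast"] = sd_last,
                      _["capped"] = capped);
}

// [[Rcpp::export(.cppEmd)]]
List cppEmd(NumericVector x, double eps, int maxImfs, int maxSiftIters,
            double imfTol) {
  const int n = x.size();
  std::vector<double> res(x.begin(), x.end()), h;
  std::vector<std::vector<double> > imfs;
  std::vector<int> iters;
  std::vector<bool> capped;
  std::vector<double> sds;
  double lo0 = x[0], hi0 = x[0];
  for (int i = 0; i < n; ++i) {
    lo0 = std::min(lo0, x[i]);
    hi0 = std::max(hi0, x[i]);
  }
  const double ptp0 = hi0 - lo0;
  while (static_cast<int>(imfs.size()) < maxImfs &&
         !is_monotonic_core(res.data(), n)) {
    int it;
    double sd;
    bool cap;
    extract_imf_core(res, eps, maxSiftIters, imfTol, h, it, sd, cap);
    if (it == 0) break;
    // an extracted component at floating-point noise scale means the
    // residue's remaining "extrema" are numerical jitter riding on an
    // otherwise inextricable trend: stop, discarding the component
    double lo = h[0], hi = h[0];
    for (int i = 0; i < n; ++i) {
      lo = std::min(lo, h[i]);
      hi = std::max(hi, h[i]);
    }
    if (hi - lo < 1e-12 * ptp0) break;
    for (int i = 0; i < n; ++i) res[i] -= h[i];
    imfs.push_back(h);
    iters.push_back(it);
    capped.push_back(cap);
    sds.push_back(sd);
  }
  const int J = static_cast<int>(imfs.size());
  NumericMatrix m(J, n);
  for (int j = 0; j < J; ++j)
    for (int i = 0; i < n; ++i) m(j, i) = imfs[j][i];
  return List::create(
      _["imfs"] = m, _["residue"] = NumericVector(res.begin(), res.end()),
      _["siftIters"] = IntegerVector(iters.begin(), iters.end()),
      _["capped"] = LogicalVector(capped.begin(), capped.end()),
      _["sdLast"] = NumericVector(sds.begin(), sds.end()));
}
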