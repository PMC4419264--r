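#include <Rcpp.h>
#include <vector>
using namespace Rcpp;

// Trapezoidal membership of x in a rule core [lo, hi] with linear decay
// of width gamma outside the core (normalized units).
static inline double membership(double x, double lo, double hi, double gamma) {
  double d = 0.0;
  if (x < lo) d = lo - x;
  else if (x > hi) d = x - hi;
  if (d <= 0.0) return 1.0;
  if (gamma <= 0.0) return 0.0;
  double m = 1.0 - d / gamma;
  return m > 0.0 ? m : 0.0;
}

// Conjunctive (min) activation of one sample against one rule.
static inline double activation_row(const double* x, const double* lo,
                                    const double* hi, int m, size_t nrules,
                                    size_t r, double gamma) {
  double a = 1.0;
  for (int j = 0; j < m; ++j) {
    double mu = membership(x[(size_t)j], lo[r + nrules * j],
                           hi[r + nrules * j], gamma);
    if (mu < a) a = mu;
    if (a <= 0.0) return 0.0;
  }
  return a;
}

// One-pass sequential rule learning. X: n x m (normalized to [0,1]),
// y: 0-based dense class codes. Each sample either expands the core of
// the best-matching same-class rule whose activation >= rho_v, or seeds
// a new rule with a point core at the sample.
// [[Rcpp::export]]
List cpp_fit_rules(NumericMatrix X, IntegerVector y,
                   double rho_v, double gamma) {
  int n = X.nrow(), m = X.ncol();
  std::vector<std::vector<double>> lo, hi;   // per rule, length m
  std::vector<int> cls;
  lo.reserve(256); hi.reserve(256); cls.reserve(256);
  std::vector<double> x(m);
  for (int t = 0; t < n; ++t) {
    for (int j = 0; j < m; ++j) x[j] = X(t, j);
    int best = -1;
    double best_a = -1.0;
    for (size_t r = 0; r < cls.size(); ++r) {
      if (cls[r] != y[t]) continue;
      double a = 1.0;
      const std::vector<double>& rl = lo[r];
      const std::vector<double>& rh = hi[r];
      for (int j = 0; j < m; ++j) {
        double mu = membership(x[j], rl[j], rh[j], gamma);
        if (mu < a) a = mu;
        if (a < rho_v) break;  // cannot win the vigilance test anyway
      }
      if (a > best_a) { best_a = a; best = (int)r; }
    }
    if (best >= 0 && best_a >= rho_v) {
      for (int j = 0; j < m; ++j) {
        if (x[j] < lo[best][j]) lo[best][j] = x[j];
        if (x[j] > hi[best][j]) hi[best][j] = x[j];
      }
    } else {
      lo.push_back(x);
      hi.push_back(x);
      cls.push_back(y[t]);
    }
  }
  size_t R = cls.size();
  NumericMatrix out_lo(R, m), out_hi(R, m);
  IntegerVector out_cls(R);
  for (size_t r = 0; r < R; ++r) {
    out_cls[r] = cls[r];
    for (int j = 0; j < m; ++j) {
      out_lo(r, j) = lo[r][j];
      out_hi(r, j) = hi[r][j];
    }
  }
  return List::create(_["core_lo"] = out_lo, _["core_hi"] = out_hi,
                      _["class"] = out_cls);
}

// Winning rule per sample: maximal activation, ties to the lowest rule
// index. Returns 1-based rule indices.
// [[Rcpp::export]]
IntegerVector cpp_winners(NumericMatrix X, NumericMatrix core_lo,
                          NumericMatrix core_hi, double gamma) {
  int n = X.nrow(), m = X.ncol();
  int R = core_lo.nrow();
  if (core_lo.ncol() != m || core_hi.ncol() != m || core_hi.nrow() != R)
    stop("rule matrices do not match the sample arity");
  if (R == 0) stop("model has no rules");
  IntegerVector w(n);
  const double* lo = core_lo.begin();
  const double* hi = core_hi.begin();
  std::vector<double> x(m);
  for (int t = 0; t < n; ++t) {
    for (int j = 0; j < m; ++j) x[j] = X(t, j);
    int best = 0;
    double best_a = -1.0;
    for (int r = 0; r < R; ++r) {
      // min-conjunction with early exit below the incumbent
      double a = 1.0;
      for (int j = 0; j < m; ++j) {
        double mu = membership(x[j], lo[r + (size_t)R * j],
                               hi[r + (size_t)R * j], gamma);
        if (mu < a) a = mu;
        if (a <= best_a) break;
      }
      if (a > best_a) { best_a = a; best = r; }
    }
    w[t] = best + 1;
  }
  return w;
}

// Activation matrix: n samples x R rules.
// [[Rcpp::export]]
NumericMatrix cpp_activations(NumericMatrix X, NumericMatrix core_lo,
                              NumericMatrix core_hi, double gamma) {
  int n = X.nrow(), m = X.ncol();
  int R = core_lo.nrow();
  if (core_lo.ncol() != m || core_hi.ncol() != m || core_hi.nrow() != R)
    stop("rule matrices do not match the sample arity");
  NumericMatrix A(n, R);
  const double* lo = core_lo.begin();
  const double* hi = core_hi.begin();
  std::vector<double> x(m);
  for (int t = 0; t < n; ++t) {
    for (int j = 0; j < m; ++j) x[j] = X(t, j);
    for (int r = 0; r < R; ++r)
      A(t, r) = activation_row(x.data(), lo, hi, m, (size_t)R, (size_t)r, gamma);
  }
  return A;
}
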