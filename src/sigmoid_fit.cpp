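// Bounded Levenberg-Marquardt fitting of the sigmoidal IO curve
//   yhat = y0 + (a - y0) / (1 + exp(-r (x - x0)))
// independently for many cortical elements (columns of X) against one
// shared MEP vector y. Multi-start: a data-driven heuristic start plus
// jittered variants (jitter factors supplied by the caller so that all
// randomness stays under R's seeded RNG), plus an optional warm start.
//
// Box constraints (per element): y0 in [0, q50(y)], a in [q50(y), 2 max(y)],
// r in (0, r_max], x0 in [min(x), max(x)]; steps are projected onto the box.

#include <Rcpp.h>
#include <cmath>
#include <algorithm>
#include <vector>

using namespace Rcpp;

static inline double sigm(double t) {
  if (t >= 0.0) {
    double e = std::exp(-t);
    return 1.0 / (1.0 + e);
  }
  double e = std::exp(t);
  return e / (1.0 + e);
}

// type-7 quantile on a copy (n is small; called once per element)
static double quantile7(std::vector<double> v, double p) {
  const size_t n = v.size();
  if (n == 1) return v[0];
  std::sort(v.begin(), v.end());
  double h = (n - 1) * p;
  size_t lo = (size_t)std::floor(h);
  size_t hi = lo + 1 < n ? lo + 1 : lo;
  return v[lo] + (h - lo) * (v[hi] - v[lo]);
}

static inline double clampd(double x, double lo, double hi) {
  return x < lo ? lo : (x > hi ? hi : x);
}

// solve 4x4 A delta = b in place; returns false if (near-)singular
static bool solve4(double A[4][4], double b[4], double delta[4]) {
  int piv[4] = {0, 1, 2, 3};
  for (int c = 0; c < 4; ++c) {
    int best = c;
    double amax = std::fabs(A[piv[c]][c]);
    for (int r = c + 1; r < 4; ++r) {
      double v = std::fabs(A[piv[r]][c]);
      if (v > amax) { amax = v; best = r; }
    }
    if (amax < 1e-300) return false;
    std::swap(piv[c], piv[best]);
    for (int r = c + 1; r < 4; ++r) {
      double f = A[piv[r]][c] / A[piv[c]][c];
      A[piv[r]][c] = 0.0;
      for (int k = c + 1; k < 4; ++k) A[piv[r]][k] -= f * A[piv[c]][k];
      b[piv[r]] -= f * b[piv[c]];
    }
  }
  for (int c = 3; c >= 0; --c) {
    double s = b[piv[c]];
    for (int k = c + 1; k < 4; ++k) s -= A[piv[c]][k] * delta[k];
    delta[c] = s / A[piv[c]][c];
  }
  for (int c = 0; c < 4; ++c)
    if (!std::isfinite(delta[c])) return false;
  return true;
}

static double sse_at(const double* x, const double* y, int n,
                     const double p[4]) {
  double s = 0.0;
  for (int i = 0; i < n; ++i) {
    double e = p[0] + (p[1] - p[0]) * sigm(p[2] * (x[i] - p[3])) - y[i];
    s += e * e;
  }
  return s;
}

// one bounded LM run from a single start; p is updated in place,
// returns final SSE; *conv set to true on ftol convergence
static double lm_run(const double* x, const double* y, int n, double p[4],
                     const double lo[4], const double hi[4], int max_iter,
                     double ftol, bool* conv) {
  std::vector<double> J(4 * (size_t)n);
  double sse = sse_at(x, y, n, p);
  double lambda = 1e-3;
  *conv = false;
  for (int iter = 0; iter < max_iter; ++iter) {
    // residuals and analytic Jacobian
    double H[4][4] = {{0}}, g[4] = {0};
    for (int i = 0; i < n; ++i) {
      double t = p[2] * (x[i] - p[3]);
      double s = sigm(t);
      double d = p[1] - p[0];
      double sp = s * (1.0 - s);
      double ji[4];
      ji[0] = 1.0 - s;            // d/dy0
      ji[1] = s;                  // d/da
      ji[2] = d * sp * (x[i] - p[3]); // d/dr
      ji[3] = -d * sp * p[2];     // d/dx0
      double e = p[0] + d * s - y[i];
      for (int a = 0; a < 4; ++a) {
        g[a] += ji[a] * e;
        for (int b = a; b < 4; ++b) H[a][b] += ji[a] * ji[b];
      }
    }
    for (int a = 0; a < 4; ++a)
      for (int b = 0; b < a; ++b) H[a][b] = H[b][a];

    bool accepted = false;
    double pnew[4], sse_new = sse;
    for (int tries = 0; tries < 12; ++tries) {
      double A[4][4], b[4], delta[4];
      for (int a = 0; a < 4; ++a) {
        for (int bb = 0; bb < 4; ++bb) A[a][bb] = H[a][bb];
        A[a][a] = H[a][a] * (1.0 + lambda) + 1e-12;
        b[a] = -g[a];
      }
      if (!solve4(A, b, delta)) { lambda *= 10.0; continue; }
      for (int a = 0; a < 4; ++a) pnew[a] = clampd(p[a] + delta[a], lo[a], hi[a]);
      sse_new = sse_at(x, y, n, pnew);
      if (sse_new < sse) {
        accepted = true;
        lambda = std::max(lambda / 3.0, 1e-12);
        break;
      }
      lambda *= 3.0;
    }
    if (!accepted) { *conv = true; break; } // stuck at a (projected) minimum
    double drop = sse - sse_new;
    for (int a = 0; a < 4; ++a) p[a] = pnew[a];
    sse = sse_new;
    if (drop <= ftol * (sse + 1e-300)) { *conv = true; break; }
  }
  return sse;
}

// [[Rcpp::export(name = ".cpp_fit_sigmoid_batch")]]
NumericMatrix cpp_fit_sigmoid_batch(NumericMatrix X, NumericVector y,
                                    NumericMatrix jitter, Nullable<NumericMatrix> warm,
                                    double r_max, int max_iter, double ftol) {
  const int n = X.nrow(), m = X.ncol();
  if ((int)y.size() != n) stop("length(y) must equal nrow(X)");
  const int k = jitter.nrow();
  bool has_warm = warm.isNotNull();
  NumericMatrix W;
  if (has_warm) {
    W = NumericMatrix(warm);
    if (W.nrow() != m || W.ncol() != 4) stop("warm must be n_elements x 4");
  }

  // shared y statistics
  std::vector<double> yv(y.begin(), y.end());
  double y_q05 = quantile7(yv, 0.05), y_q50 = quantile7(yv, 0.50),
         y_q95 = quantile7(yv, 0.95);
  double y_max = *std::max_element(yv.begin(), yv.end());
  double y_mean = 0.0;
  for (int i = 0; i < n; ++i) y_mean += yv[i];
  y_mean /= n;
  double var_y = 0.0;
  for (int i = 0; i < n; ++i) var_y += (yv[i] - y_mean) * (yv[i] - y_mean);
  var_y /= n; // population variance, cancels against the same convention below
  // constant y up to accumulation error: R^2 is 0 by convention
  if (var_y <= 1e-20 * std::max(1.0, y_mean * y_mean)) var_y = 0.0;

  NumericMatrix out(m, 7);
  colnames(out) = CharacterVector::create("y0", "a", "r", "x0", "sse", "r2",
                                          "converged");
  std::vector<double> xv(n);

  for (int j = 0; j < m; ++j) {
    for (int i = 0; i < n; ++i) xv[i] = X(i, j);
    double x_min = *std::min_element(xv.begin(), xv.end());
    double x_max = *std::max_element(xv.begin(), xv.end());

    if (!(x_max - x_min > 1e-12)) { // degenerate input: constant x
      out(j, 0) = y_q50; out(j, 1) = y_q50; out(j, 2) = NA_REAL;
      out(j, 3) = xv[0]; out(j, 4) = NA_REAL; out(j, 5) = 0.0; out(j, 6) = 0.0;
      continue;
    }

    double x_q25 = quantile7(xv, 0.25), x_q50 = quantile7(xv, 0.50),
           x_q75 = quantile7(xv, 0.75);
    double lo[4] = {0.0, y_q50, 1e-8, x_min};
    double hi[4] = {y_q50, 2.0 * y_max, r_max, x_max};
    if (hi[1] <= lo[1]) hi[1] = lo[1] + 1e-12;

    double p0[4];
    p0[0] = clampd(y_q05, lo[0], hi[0]);
    p0[1] = clampd(y_q95, lo[1], hi[1]);
    p0[2] = clampd(4.0 / (x_q75 - x_q25 + 1e-9), lo[2], hi[2]);
    p0[3] = clampd(x_q50, lo[3], hi[3]);

    double best[4] = {p0[0], p0[1], p0[2], p0[3]};
    double best_sse = R_PosInf;
    bool best_conv = false;

    for (int s = 0; s < k + (has_warm ? 1 : 0); ++s) {
      double p[4];
      if (s < k) {
        for (int a = 0; a < 4; ++a)
          p[a] = clampd(p0[a] * jitter(s, a), lo[a], hi[a]);
      } else {
        bool ok = true;
        for (int a = 0; a < 4; ++a) {
          p[a] = W(j, a);
          if (!std::isfinite(p[a])) ok = false;
        }
        if (!ok) continue;
        for (int a = 0; a < 4; ++a) p[a] = clampd(p[a], lo[a], hi[a]);
      }
      bool conv = false;
      double sse = lm_run(xv.data(), yv.data(), n, p, lo, hi, max_iter, ftol,
                          &conv);
      if (sse < best_sse) {
        best_sse = sse;
        best_conv = conv;
        for (int a = 0; a < 4; ++a) best[a] = p[a];
      }
    }

    // R^2 = 1 - VAR(y - yhat) / VAR(y), population variances;
    // flat y (zero variance) scores 0 by convention
    double r2 = 0.0;
    if (var_y > 0.0) {
      double em = 0.0;
      std::vector<double> e(n);
      for (int i = 0; i < n; ++i) {
        e[i] = best[0] + (best[1] - best[0]) *
                             sigm(best[2] * (xv[i] - best[3])) - yv[i];
        em += e[i];
      }
      em /= n;
      double ve = 0.0;
      for (int i = 0; i < n; ++i) ve += (e[i] - em) * (e[i] - em);
      ve /= n;
      r2 = 1.0 - ve / var_y;
    }

    out(j, 0) = best[0]; out(j, 1) = best[1]; out(j, 2) = best[2];
    out(j, 3) = best[3]; out(j, 4) = best_sse; out(j, 5) = r2;
    out(j, 6) = best_conv ? 1.0 : 0.0;
  }
  return out;
}
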