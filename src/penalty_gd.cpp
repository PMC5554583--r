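#include <Rcpp.h>
#include <cmath>
#include <vector>
using namespace Rcpp;

// Gradient-descent fit of a penalized polynomial f(h) = sum_i a_i h^i to
// observations x(k), minimising
//   E = alpha * sum_k (f(h_k) - x_k)^2 + lambda * sum_{i>=1} c_i a_i^2.
// The update is a_i <- a_i - g_i with
//   g_0 = 2 alpha sum_k (f - x),
//   g_i = 2 alpha sum_k (f - x) h^i + 2 lambda c_i a_i  (i >= 1),
// i.e. the alpha embedded in E doubles as the step size. When adapt_step
// is true a scalar damping factor s <= 1 backtracks (halving) whenever a
// step would increase E and grows back toward 1 after accepted steps, so
// accepted iterations never increase the cost; with a stable alpha the
// damping stays at 1 and the update is the plain one.
//
// [[Rcpp::export]]
List gd_fit_cpp(NumericVector h, NumericVector x, NumericVector a_init,
                NumericVector cpen, double alpha, double lambda,
                double tol, bool rel_tol, double max_iter, bool adapt_step,
                bool trace) {
  const int M = h.size();
  const int np = a_init.size();

  // Design matrix of powers, row-major per sample.
  std::vector<double> H((size_t)M * np);
  for (int k = 0; k < M; ++k) {
    double p = 1.0;
    for (int i = 0; i < np; ++i) {
      H[(size_t)k * np + i] = p;
      p *= h[k];
    }
  }

  std::vector<double> a(a_init.begin(), a_init.end());
  std::vector<double> anew(np), g(np);

  auto cost = [&](const std::vector<double> &av) {
    double sse = 0.0;
    for (int k = 0; k < M; ++k) {
      double f = 0.0;
      const double *row = &H[(size_t)k * np];
      for (int i = 0; i < np; ++i) f += av[i] * row[i];
      const double r = f - x[k];
      sse += r * r;
    }
    double pen = 0.0;
    for (int i = 1; i < np; ++i) pen += cpen[i - 1] * av[i] * av[i];
    return alpha * sse + lambda * pen;
  };

  double E = cost(a);
  bool diverged = !std::isfinite(E) || E > 1e12;
  bool converged = false;
  double s = 1.0;
  double iter = 0.0;
  std::vector<double> Etrace;
  if (trace) Etrace.push_back(E);

  while (!diverged && !converged && iter < max_iter) {
    if (((long long)iter) % 100000 == 0) checkUserInterrupt();

    std::fill(g.begin(), g.end(), 0.0);
    for (int k = 0; k < M; ++k) {
      double f = 0.0;
      const double *row = &H[(size_t)k * np];
      for (int i = 0; i < np; ++i) f += a[i] * row[i];
      const double r = f - x[k];
      for (int i = 0; i < np; ++i) g[i] += r * row[i];
    }
    for (int i = 0; i < np; ++i) g[i] *= 2.0 * alpha;
    for (int i = 1; i < np; ++i) g[i] += 2.0 * lambda * cpen[i - 1] * a[i];

    double Enew;
    if (adapt_step) {
      bool accepted = false;
      while (true) {
        for (int i = 0; i < np; ++i) anew[i] = a[i] - s * g[i];
        Enew = cost(anew);
        if (std::isfinite(Enew) && Enew <= E) { accepted = true; break; }
        s *= 0.5;
        if (s < 1e-16) break;
      }
      if (!accepted) { converged = true; break; }  // no descent possible
    } else {
      for (int i = 0; i < np; ++i) anew[i] = a[i] - g[i];
      Enew = cost(anew);
    }

    a.swap(anew);
    iter += 1.0;
    if (trace) Etrace.push_back(Enew);

    if (!std::isfinite(Enew) || Enew > 1e12) { diverged = true; E = Enew; break; }
    const double thresh = rel_tol ? tol * Enew : tol;
    if (std::fabs(E - Enew) <= thresh) { converged = true; E = Enew; break; }
    E = Enew;
    if (adapt_step && s < 1.0) s = std::min(1.0, 2.0 * s);
  }

  List out = List::create(
    _["coeffs"] = NumericVector(a.begin(), a.end()),
    _["iterations"] = iter,
    _["final_cost"] = E,
    _["converged"] = converged,
    _["diverged"] = diverged,
    _["step_scale"] = s);
  if (trace) out["cost_trace"] = NumericVector(Etrace.begin(), Etrace.end());
  return out;
}
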