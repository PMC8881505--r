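// Cyclic coordinate descent for the L1-regularized maximum-entropy
// (Gibbs-over-background) model. Each coordinate subproblem is solved
// exactly: a soft-threshold test at zero, then a warm-started, safeguarded
// Newton/bisection search for the root of E_model[f_j](b) = Ep_j - lambda*s.
// Background weights u = exp(eta - shift) are maintained incrementally so
// the zero-test of inactive coordinates costs one dot product; convergence
// requires both a small objective decrease over a full cycle and the KKT
// conditions |Ep - E_model| <= lambda (equality for active features) within
// kkt_tol.

#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// [[Rcpp::export(name = ".maxent_cd")]]
List maxent_cd(NumericMatrix Xb, NumericVector Ep, NumericVector lambda,
               IntegerVector var_index, int n_vars,
               int max_cycles, double tol, double kkt_tol, double b_cap) {
  const int N = Xb.nrow(), J = Xb.ncol();
  std::vector<double> eta(N, 0.0), u(N, 1.0);
  double shift = 0.0;            // u[i] = exp(eta[i] - shift)
  double S = (double)N;          // sum of u
  std::vector<double> beta(J, 0.0);
  std::vector<double> improvements(n_vars, 0.0);
  bool converged = false;
  int cycles = 0;

  auto refresh = [&]() {         // recompute u, S from eta with a fresh shift
    shift = eta[0];
    for (int i = 1; i < N; ++i) if (eta[i] > shift) shift = eta[i];
    S = 0.0;
    for (int i = 0; i < N; ++i) { u[i] = std::exp(eta[i] - shift); S += u[i]; }
  };
  auto lse = [&]() { return shift + std::log(S); };
  auto objective = [&]() {
    double o = lse();
    for (int j = 0; j < J; ++j) o += -Ep[j] * beta[j] + lambda[j] * std::fabs(beta[j]);
    return o;
  };
  double o_prev = objective();

  // E_model[f] and variance at offset delta from the CURRENT eta for column f
  auto moments = [&](const double* f, double delta, double& m1, double& var) {
    double mm = eta[0] + delta * f[0];
    for (int i = 1; i < N; ++i) {
      double e = eta[i] + delta * f[i];
      if (e > mm) mm = e;
    }
    double sw = 0.0, swf = 0.0, swf2 = 0.0;
    for (int i = 0; i < N; ++i) {
      double w = std::exp(eta[i] + delta * f[i] - mm);
      sw += w; swf += w * f[i]; swf2 += w * f[i] * f[i];
    }
    m1 = swf / sw;
    var = swf2 / sw - m1 * m1;
  };

  for (int cycle = 0; cycle < max_cycles; ++cycle) {
    cycles = cycle + 1;
    for (int j = 0; j < J; ++j) {
      const double* f = &Xb(0, j);
      const double bj = beta[j];
      // expectation at b = 0 for this coordinate (i.e. delta = -bj)
      double E0, var0;
      if (bj == 0.0) {
        double sf = 0.0;
        for (int i = 0; i < N; ++i) sf += u[i] * f[i];
        E0 = sf / S;
      } else {
        moments(f, -bj, E0, var0);
      }
      double b_new;
      if (std::fabs(Ep[j] - E0) <= lambda[j]) {
        b_new = 0.0;
      } else {
        const double s = (Ep[j] - E0 > 0) ? 1.0 : -1.0;
        const double target = Ep[j] - lambda[j] * s;
        // bracket in b (relative to zero of this coordinate)
        double blo = 0.0, bhi = s * b_cap;
        bool lo_ok = false, hi_ok = false; // whether M1 straddles the target
        // warm start from the current coefficient when it has the right sign
        double b = (bj * s > 0) ? bj : s;
        bool done = false;
        for (int it = 0; it < 100; ++it) {
          double m1, var;
          moments(f, b - bj, m1, var);
          double g = m1 - target;
          if (std::fabs(g) < 1e-14) { done = true; break; }
          if ((g > 0) == (s > 0)) { bhi = b; hi_ok = true; }
          else { blo = b; lo_ok = true; }
          double bn;
          if (var > 1e-15) bn = b - g / var; else bn = std::numeric_limits<double>::quiet_NaN();
          double lo = std::min(blo, bhi), hi = std::max(blo, bhi);
          if (std::isfinite(bn) && bn > lo && bn < hi) b = bn;
          else if (lo_ok && hi_ok) b = 0.5 * (blo + bhi);
          else if (!hi_ok) { b = (std::fabs(2.0 * b) < b_cap) ? 2.0 * b : s * b_cap;
                             if (std::fabs(b) >= b_cap) { b = s * b_cap; if (it > 60) break; } }
          else b = 0.5 * (blo + bhi);
          if (std::fabs(hi - lo) < 1e-15 && lo_ok && hi_ok) break;
        }
        (void)done;
        b_new = b;
      }
      if (b_new != bj) {
        // objective improvement of the move (for path attribution)
        double lse_old = lse();
        double delta = b_new - bj;
        for (int i = 0; i < N; ++i) eta[i] += delta * f[i];
        refresh();
        double imp = (-Ep[j] * bj + lse_old + lambda[j] * std::fabs(bj))
                   - (-Ep[j] * b_new + lse() + lambda[j] * std::fabs(b_new));
        if (imp > 0) improvements[var_index[j]] += imp;
        beta[j] = b_new;
      }
    }
    double o_now = objective();
    if (o_prev - o_now < tol) {
      // full KKT pass; recompute eta exactly from beta first so that
      // incremental floating-point drift cannot mask convergence
      for (int i = 0; i < N; ++i) {
        double e = 0.0;
        for (int j = 0; j < J; ++j) if (beta[j] != 0.0) e += beta[j] * Xb(i, j);
        eta[i] = e;
      }
      refresh();
      double viol = 0.0;
      for (int j = 0; j < J; ++j) {
        double Em = 0.0;
        const double* f = &Xb(0, j);
        for (int i = 0; i < N; ++i) Em += u[i] * f[i];
        Em /= S;
        double gap = std::fabs(Ep[j] - Em);
        double v = (beta[j] != 0.0) ? std::fabs(gap - lambda[j])
                                    : std::max(0.0, gap - lambda[j]);
        if (v > viol) viol = v;
      }
      o_prev = objective();
      if (viol < kkt_tol) { converged = true; break; }
    } else {
      o_prev = o_now;
    }
  }
  return List::create(_["beta"] = NumericVector(beta.begin(), beta.end()),
                      _["eta"] = NumericVector(eta.begin(), eta.end()),
                      _["improvements"] = NumericVector(improvements.begin(),
                                                        improvements.end()),
                      _["cycles"] = cycles, _["converged"] = converged,
                      _["objective"] = o_prev);
}
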