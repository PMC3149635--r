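#include <Rcpp.h>
#include <cmath>
#include <vector>

using namespace Rcpp;

// Forward-Euler relaxation of the rate dynamics
//   tau * du_i/dt = -u_i + 0.5 * (1 + tanh(sum_j w_ij u_j + I_i)).
//
// For dt <= tau the update is a convex combination of u and a value in
// (0, 1), so activations stay in [0, 1] without clamping.  Convergence is
// declared when max_i |du_i/dt| < tol (a per-unit-time rate), and the
// integration is capped at t_max.
//
// [[Rcpp::export(name = ".relax_euler")]]
List relax_euler(const NumericMatrix& w, const NumericVector& I,
                 const NumericVector& u0, double tau, double dt,
                 double tol, double t_max, bool record_energy = false) {
  const int n = u0.size();
  NumericVector u = clone(u0);
  const int max_steps = static_cast<int>(std::ceil(t_max / dt));
  std::vector<double> h(n), du(n);
  std::vector<double> energies;
  if (record_energy) energies.reserve(max_steps);
  const double* wp = &w[0];
  bool converged = false;
  int steps = 0;

  for (int step = 0; step < max_steps; ++step) {
    for (int j = 0; j < n; ++j) h[j] = I[j];
    for (int k = 0; k < n; ++k) {
      const double uk = u[k];
      if (uk == 0.0) continue;
      const double* col = wp + static_cast<size_t>(k) * n;  // w(, k)
      for (int j = 0; j < n; ++j) h[j] += col[j] * uk;
    }
    double max_rate = 0.0;
    for (int j = 0; j < n; ++j) {
      const double g = 0.5 * (1.0 + std::tanh(h[j]));
      du[j] = (g - u[j]) / tau;
      const double a = std::fabs(du[j]);
      if (a > max_rate) max_rate = a;
    }
    for (int j = 0; j < n; ++j) {
      u[j] += dt * du[j];
      if (!std::isfinite(u[j]))
        stop("non-finite activation during relaxation (unstable parameters)");
    }
    if (record_energy) {
      // E(u) = -1/2 * u' W u, tracked along the trajectory
      double e = 0.0;
      for (int k = 0; k < n; ++k) {
        const double uk = u[k];
        if (uk == 0.0) continue;
        const double* col = wp + static_cast<size_t>(k) * n;
        double acc = 0.0;
        for (int j = 0; j < n; ++j) acc += col[j] * u[j];
        e += uk * acc;
      }
      energies.push_back(-0.5 * e);
    }
    ++steps;
    if (max_rate < tol) {
      converged = true;
      break;
    }
  }

  List out = List::create(_["u"] = u, _["converged"] = converged,
                          _["steps"] = steps);
  if (record_energy) out["energy"] = wrap(energies);
  return out;
}
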