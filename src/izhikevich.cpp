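#include <Rcpp.h>
using namespace Rcpp;

// Forward-Euler integration of the two-variable quadratic spiking model
//   C dv/dt = k (v - v_r)(v - v_t) - u + I
//     du/dt = a (b (v - v_r) - u)
// with after-spike reset: if v >= v_peak then v <- c, u <- u + d.
//
// Update order (pinned so an independent step-by-step reference can match
// spike-for-spike): both derivatives are evaluated on the current state,
// both variables are advanced simultaneously, then the threshold test runs
// on the updated state. The spike is stamped at the time of the updated
// state (step * dt), before the reset; the recorded trace keeps the raw
// (unclamped) membrane potential.

// [[Rcpp::export]]
List izh_simulate_cpp(double I, double C, double k, double vr, double vt,
                      double vpeak, double a, double b, double creset,
                      double d, double dt, int n_steps, double v0, double u0,
                      bool keep_trace) {
  double v = v0, u = u0;
  std::vector<double> spikes;
  NumericVector tt, tv, tu;
  if (keep_trace) {
    tt = NumericVector(n_steps + 1);
    tv = NumericVector(n_steps + 1);
    tu = NumericVector(n_steps + 1);
    tt[0] = 0.0;
    tv[0] = v;
    tu[0] = u;
  }
  for (int s = 1; s <= n_steps; ++s) {
    double dv = (k * (v - vr) * (v - vt) - u + I) / C;
    double du = a * (b * (v - vr) - u);
    v += dt * dv;
    u += dt * du;
    if (!std::isfinite(v) || !std::isfinite(u))
      stop("integration failure: non-finite state at step %d (t = %g)",
           s, s * dt);
    if (keep_trace) {
      tt[s] = s * dt;
      tv[s] = v;  // pre-reset value; not clamped to v_peak
      tu[s] = u;
    }
    if (v >= vpeak) {
      spikes.push_back(s * dt);
      v = creset;
      u += d;
    }
  }
  List out = List::create(_["spike_times"] = wrap(spikes));
  if (keep_trace)
    out["trace"] = DataFrame::create(_["t"] = tt, _["v"] = tv, _["u"] = tu);
  return out;
}

// Batch spike counts for a vector of constant input currents: the hot path
// of classifier training (one count per pattern per fitness evaluation).

// [[Rcpp::export]]
IntegerVector izh_count_spikes_cpp(NumericVector I, double C, double k,
                                   double vr, double vt, double vpeak,
                                   double a, double b, double creset,
                                   double d, double dt, int n_steps,
                                   double v0, double u0) {
  const int m = I.size();
  IntegerVector counts(m);
  for (int i = 0; i < m; ++i) {
    double v = v0, u = u0;
    const double Ii = I[i];
    int n = 0;
    for (int s = 1; s <= n_steps; ++s) {
      double dv = (k * (v - vr) * (v - vt) - u + Ii) / C;
      double du = a * (b * (v - vr) - u);
      v += dt * dv;
      u += dt * du;
      if (!std::isfinite(v) || !std::isfinite(u))
        stop("integration failure: non-finite state at step %d for current %g",
             s, Ii);
      if (v >= vpeak) {
        ++n;
        v = creset;
        u += d;
      }
    }
    counts[i] = n;
  }
  return counts;
}
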