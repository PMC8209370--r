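#include <Rcpp.h>
#include <cmath>
#include <vector>
using namespace Rcpp;

// Fixed-step forward Euler integration of the AdEx point-neuron model.
//
// State: membrane potential V (mV), adaptation current w (pA).
//   C_m dV/dt = -g_L (V - E_L) + g_L Delta_T exp((V - V_T)/Delta_T) - w + I(t)
//   tau_w dw/dt = a (V - E_L) - w
//   if V > V_peak: record spike, V <- V_r, w <- w + b
//
// Units are dimensionally closed: pA / pF / nS / mV / ms (nS*mV = pA,
// pF*mV/ms = pA). Spike times are returned in seconds.
//
// `par` is the canonical parameter vector:
//   C_m, g_L, E_L, V_T, Delta_T, V_peak, V_r, a, b, tau_w
//
// kind: 0 = step current, 1 = sinusoid (offset + amplitude*sin(2*pi*f*(t-onset)+phase0)).
// The exponential argument is capped at exp_clip; any V > V_peak triggers the
// reset regardless of overshoot, so the cap never changes spike timing at dt
// resolution. A non-finite state sets `diverged` and stops the run.

// [[Rcpp::export]]
List adex_simulate_cpp(NumericVector par, int kind, double amplitude,
                       double offset, double frequency, double phase0,
                       double onset_s, double duration_s,
                       double dt_ms, double v_init, double w_init,
                       double exp_clip, bool record) {
  const double Cm = par[0], gL = par[1], EL = par[2], VT = par[3],
               DT = par[4], Vpeak = par[5], Vr = par[6], a = par[7],
               b = par[8], tauw = par[9];

  const double onset_ms = onset_s * 1000.0;
  const double end_ms   = (onset_s + duration_s) * 1000.0;
  const long nsteps = (long) std::llround(end_ms / dt_ms);
  const double omega = 2.0 * M_PI * frequency / 1000.0; // rad per ms

  double V = v_init, w = w_init;
  bool diverged = false;
  std::vector<double> spikes;

  NumericVector rec_t, rec_V, rec_w;
  if (record) {
    rec_t = NumericVector(nsteps + 1);
    rec_V = NumericVector(nsteps + 1);
    rec_w = NumericVector(nsteps + 1);
    rec_t[0] = 0.0; rec_V[0] = V; rec_w[0] = w;
  }

  for (long k = 0; k < nsteps; ++k) {
    const double t = k * dt_ms;
    double I = 0.0;
    if (t >= onset_ms && t < end_ms) {
      if (kind == 0) {
        I = amplitude;
      } else {
        I = offset + amplitude * std::sin(omega * (t - onset_ms) + phase0);
      }
    }
    double earg = (V - VT) / DT;
    if (earg > exp_clip) earg = exp_clip;
    const double dV = (-gL * (V - EL) + gL * DT * std::exp(earg) - w + I) / Cm;
    const double dw = (a * (V - EL) - w) / tauw;
    V += dt_ms * dV;
    w += dt_ms * dw;

    if (!std::isfinite(V) || !std::isfinite(w)) {
      diverged = true;
      if (record) {
        rec_t[k + 1] = (k + 1) * dt_ms; rec_V[k + 1] = NA_REAL; rec_w[k + 1] = NA_REAL;
        // truncate records at the point of divergence
        rec_t = NumericVector(rec_t.begin(), rec_t.begin() + k + 2);
        rec_V = NumericVector(rec_V.begin(), rec_V.begin() + k + 2);
        rec_w = NumericVector(rec_w.begin(), rec_w.begin() + k + 2);
      }
      break;
    }

    if (V > Vpeak) {
      spikes.push_back((k + 1) * dt_ms / 1000.0);
      V = Vr;
      w += b;
    }

    if (record) {
      rec_t[k + 1] = (k + 1) * dt_ms;
      rec_V[k + 1] = V;
      rec_w[k + 1] = w;
    }
  }

  List out = List::create(
    Named("spike_times") = NumericVector(spikes.begin(), spikes.end()),
    Named("diverged") = diverged);
  if (record) {
    out["trace"] = DataFrame::create(Named("time_ms") = rec_t,
                                     Named("V_mV") = rec_V,
                                     Named("w_pA") = rec_w);
  }
  return out;
}
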