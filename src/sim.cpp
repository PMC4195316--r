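#include <Rcpp.h>
#include <cmath>
#include <vector>
using namespace Rcpp;

// Units throughout: time ms, voltage mV, current pA, capacitance pF,
// conductance nS (1 nS * 1 mV = 1 pA; 1/R[MOhm] * 1000 = g_L[nS]).

static inline double sample_at(const NumericVector& v, R_xlen_t k) {
  return (v.size() == 1) ? v[0] : v[k];
}

// Leaky / resonant integrate-and-fire membrane driven by
//   I_E(t) = scale_x * x(t) + scale_n * noise(t) + I0   [pA].
// Exponential-Euler update for V, exact exponential decay for the
// spike-triggered resonant state b (b += 1 at each spike, conductance
// g_b_nS * b).  Threshold is tested at end-of-step; the recorded spike time
// is shifted by delta_s without affecting the dynamics.  An optional constant
// inhibitory conductance g_I (reversal E_I) can be supplied.
// x / noise of length 1 are treated as constants.
// [[Rcpp::export]]
List sim_if_cpp(NumericVector x, NumericVector noise,
                double scale_x, double scale_n, double I0,
                R_xlen_t n_steps, double dt,
                double C, double R, double E_R, double V_th,
                double g_b_nS, double tau_b, double delta_s,
                double g_I, double E_I,
                double V0, double b0) {
  if (x.size() != 1 && x.size() < n_steps)
    stop("x shorter than n_steps");
  if (noise.size() != 1 && noise.size() < n_steps)
    stop("noise shorter than n_steps");
  const double g_L = 1000.0 / R;
  const double eb = (g_b_nS > 0.0) ? std::exp(-dt / tau_b) : 1.0;
  double V = V0, b = b0;
  std::vector<double> sp;
  sp.reserve(256);
  if (g_b_nS == 0.0 && g_I == 0.0) {
    // constant-conductance fast path
    const double gtot = g_L;
    const double decay = std::exp(-dt * gtot / C);
    for (R_xlen_t k = 0; k < n_steps; ++k) {
      const double IE = scale_x * sample_at(x, k) + scale_n * sample_at(noise, k) + I0;
      if (!std::isfinite(IE)) stop("non-finite drive sample");
      const double Vinf = E_R + IE / gtot;
      V = Vinf + (V - Vinf) * decay;
      if (V >= V_th) {
        sp.push_back((double)(k + 1) * dt + delta_s);
        V = E_R;
      }
    }
  } else {
    for (R_xlen_t k = 0; k < n_steps; ++k) {
      const double IE = scale_x * sample_at(x, k) + scale_n * sample_at(noise, k) + I0;
      if (!std::isfinite(IE)) stop("non-finite drive sample");
      const double gb = g_b_nS * b;
      const double gtot = g_L + gb + g_I;
      const double Vinf = (g_L * E_R + gb * E_R + g_I * E_I + IE) / gtot;
      V = Vinf + (V - Vinf) * std::exp(-dt * gtot / C);
      b *= eb;
      if (V >= V_th) {
        sp.push_back((double)(k + 1) * dt + delta_s);
        V = E_R;
        b += 1.0;
      }
    }
  }
  return List::create(_["times"] = wrap(sp), _["V"] = V, _["b"] = b);
}

// Ideal (no-leak) integrate-and-fire rate encoder: accumulates
// rate(t)*dt with rate(t) = max(scale * x(t) + offset, 0) in spikes/s,
// emits a spike and subtracts 1 whenever the accumulator reaches 1.
// Negative instantaneous rates are clipped to zero (rectification).
// [[Rcpp::export]]
List sim_ideal_cpp(NumericVector x, double scale, double offset,
                   R_xlen_t n_steps, double dt, double acc0) {
  if (x.size() != 1 && x.size() < n_steps)
    stop("x shorter than n_steps");
  const double dts = dt * 1e-3;  // ms -> s, rate is in spikes/s
  double acc = acc0;
  std::vector<double> sp;
  sp.reserve(256);
  for (R_xlen_t k = 0; k < n_steps; ++k) {
    double r = scale * sample_at(x, k) + offset;
    if (!std::isfinite(r)) stop("non-finite rate sample");
    if (r < 0.0) r = 0.0;
    acc += r * dts;
    if (acc >= 1.0) {
      sp.push_back((double)(k + 1) * dt);
      acc -= 1.0;
    }
  }
  return List::create(_["times"] = wrap(sp), _["acc"] = acc);
}

// Signed accumulation of spike counts onto a regular grid (population
// output of sampling-rate-filtered trains without materializing each
// cell's full-grid signal).
// [[Rcpp::export]]
void add_spikes_cpp(NumericVector out, NumericVector times, double bin,
                    double sign) {
  const R_xlen_t n = out.size();
  for (R_xlen_t i = 0; i < times.size(); ++i) {
    R_xlen_t k = (R_xlen_t)std::ceil(times[i] / bin) - 1;
    if (k < 0) k = 0;
    if (k >= n) k = n - 1;
    out[k] += sign;
  }
}
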