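#include <Rcpp.h>
#include <cmath>
#include <vector>
using namespace Rcpp;

// Time-stepped presentation of one input to the competitive spiking layer.
//
// Leaky integrate-and-fire membranes with direct delta-pulse synapses,
// all-to-all lateral inhibition, adaptive thresholds and (optionally) STDP
// applied at each output spike to the firing neuron's afferents, pairing the
// post spike with each channel's most recent pre spike.
// The leak and the threshold relaxation use exact
// exponential decay factors per step; synaptic and inhibitory pulses are
// delivered at step boundaries. Within a step, simultaneous threshold
// crossings are resolved lowest-index-first, and each emitted spike
// immediately inhibits the others before the next crossing is checked.
//
// spikes: p x n_steps matrix of input spike counts per channel and step.
// theta:  total firing thresholds (mV); may be +Inf to disable firing.
// [[Rcpp::export]]
List csnn_present_cpp(IntegerMatrix spikes, NumericMatrix W_in,
                      NumericVector theta_in, bool learning,
                      double tau_u, double u_r, double u_reset,
                      double t_refrac, double dt,
                      double w_inh,
                      double alpha_plus, double alpha_minus,
                      double tau_plus, double tau_minus,
                      double theta0_offset, double alpha_theta_inc,
                      double tau_theta0, double lambda) {
  const int p = spikes.nrow();
  const int n_steps = spikes.ncol();
  const int m = W_in.ncol();
  if (W_in.nrow() != p) stop("weight matrix rows must match input channels");
  if (theta_in.size() != m) stop("threshold length must match neuron count");

  NumericMatrix W = clone(W_in);
  NumericVector theta = clone(theta_in);

  const double leak = std::exp(-dt / tau_u);
  const double th_decay = std::exp(-dt / tau_theta0);
  const int ref_steps = (int)std::lround(t_refrac / dt);

  std::vector<double> u(m, u_r);
  std::vector<int> refrac(m, 0);
  std::vector<double> last_pre(p, -1.0);
  std::vector<double> last_post(m, -1.0);
  std::vector<double> spike_t;
  std::vector<int> spike_id;
  IntegerVector counts(m);
  int first_spiker = NA_INTEGER;

  for (int s = 0; s < n_steps; ++s) {
    const double tnow = (s + 1) * dt;

    for (int j = 0; j < m; ++j) {
      if (th_decay < 1.0 && R_finite(theta[j]))
        theta[j] = theta0_offset + (theta[j] - theta0_offset) * th_decay;
      if (refrac[j] > 0) u[j] = u_reset;
      else u[j] = u_r + (u[j] - u_r) * leak;
    }

    // input spikes: excitation, and the depression branch of STDP
    for (int i = 0; i < p; ++i) {
      const int cnt = spikes(i, s);
      if (cnt == 0) continue;
      for (int j = 0; j < m; ++j) {
        if (refrac[j] <= 0) u[j] += W(i, j) * cnt;
      }
    }

    // threshold crossings, lowest index first; each spike inhibits the rest
    bool fired = true;
    while (fired) {
      fired = false;
      for (int j = 0; j < m; ++j) {
        if (refrac[j] <= 0 && R_finite(theta[j]) && u[j] >= theta[j]) {
          spike_t.push_back(tnow);
          spike_id.push_back(j + 1);
          counts[j] += 1;
          if (first_spiker == NA_INTEGER) first_spiker = j + 1;
          u[j] = u_reset;
          refrac[j] = ref_steps;
          theta[j] += alpha_theta_inc;
          for (int k = 0; k < m; ++k) {
            if (k != j && refrac[k] <= 0) u[k] -= w_inh;
          }
          if (learning) {
            for (int i = 0; i < p; ++i) {
              if (last_pre[i] >= 0.0) {
                const double dtij = tnow - last_pre[i];
                if (dtij > 0.0) {
                  W(i, j) += alpha_plus * std::exp(-dtij / tau_plus);
                } else {  // simultaneous pre/post falls in the depression branch
                  double w = W(i, j) - alpha_minus;
                  W(i, j) = (w > 0.0) ? w : 0.0;
                }
              }
            }
          }
          last_post[j] = tnow;
          fired = true;
          break;  // restart scan so inhibition can veto later crossings
        }
      }
    }

    // traces update after the firing pass: a post spike pairs with each
    // channel's most recent *preceding* pre spike (delta t >= dt, causal)
    if (learning) {
      for (int i = 0; i < p; ++i) {
        if (spikes(i, s) > 0) last_pre[i] = tnow;
      }
    }

    for (int j = 0; j < m; ++j) {
      if (refrac[j] > 0) refrac[j] -= 1;
      if (!R_finite(u[j])) stop("integration diverged: non-finite membrane (dt too large?)");
    }
  }

  if (learning) {  // per-presentation normalization to the lambda budget
    for (int j = 0; j < m; ++j) {
      double s = 0.0;
      for (int i = 0; i < p; ++i) s += W(i, j);
      if (s <= 0.0) stop("degenerate neuron: weight column sums to zero");
      const double f = lambda / s;
      for (int i = 0; i < p; ++i) W(i, j) *= f;
    }
  }

  return List::create(
    _["spike_time"] = wrap(spike_t),
    _["spike_neuron"] = wrap(spike_id),
    _["counts"] = counts,
    _["u"] = wrap(u),
    _["W"] = W,
    _["theta"] = theta,
    _["first_spiker"] = first_spiker);
}
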