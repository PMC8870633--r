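#include <Rcpp.h>
using namespace Rcpp;

// Clock-driven LIF simulation of one cluster's decode layer.
//
// Each input event at time t injects W(channel, j) into the synaptic
// current of every decode neuron j; currents decay exponentially with
// psc_tau. Teacher pulses go into a separate accumulator that is cleared
// when the neuron spikes, so a single encouraging pulse forces exactly one
// spike at its injection time instead of ringing through the refractory
// period. Subthreshold integration is exponential-Euler: the leak term is
// exact, the current term is held constant over a step.
//
// ev_channel: 0-based channel per event, sorted by ev_time.
// teach_target: 0-based decode-neuron index; teach_amp is signed
// (positive = encourage, negative = punish/hyperpolarize).
// [[Rcpp::export]]
List lif_cluster_sim(IntegerVector ev_channel, NumericVector ev_time,
                     NumericMatrix W,
                     IntegerVector teach_target, NumericVector teach_time,
                     NumericVector teach_amp,
                     double tau_m, double v_rest, double v_thresh,
                     double v_reset, double t_ref, double psc_tau,
                     double dt, double window_ms) {
  const int n_dec = W.ncol();
  const int n_in = W.nrow();
  const int n_steps = (int)std::lround(window_ms / dt);
  const int n_ev = ev_channel.size();
  const int n_te = teach_target.size();

  const double decay_m = std::exp(-dt / tau_m);
  const double decay_s = std::exp(-dt / psc_tau);
  const double gain = dt / tau_m;

  std::vector<double> v(n_dec, v_rest), i_syn(n_dec, 0.0),
      i_teach(n_dec, 0.0), ref_until(n_dec, -1.0);
  std::vector<std::vector<double>> spikes(n_dec);

  std::vector<int> ev_step(n_ev), te_step(n_te);
  for (int e = 0; e < n_ev; ++e) {
    int s = (int)std::floor(ev_time[e] / dt);
    if (s >= n_steps) s = n_steps - 1;
    ev_step[e] = s;
  }
  for (int k = 0; k < n_te; ++k) {
    int s = (int)std::floor(teach_time[k] / dt);
    if (s >= n_steps) s = n_steps - 1;
    te_step[k] = s;
  }

  int ptr = 0;
  for (int s = 0; s < n_steps; ++s) {
    const double t = s * dt;

    while (ptr < n_ev && ev_step[ptr] == s) {
      const int c = ev_channel[ptr];
      if (c < 0 || c >= n_in) stop("channel index out of range");
      for (int j = 0; j < n_dec; ++j) i_syn[j] += W(c, j);
      ++ptr;
    }
    for (int k = 0; k < n_te; ++k)
      if (te_step[k] == s) i_teach[teach_target[k]] += teach_amp[k];

    for (int j = 0; j < n_dec; ++j) {
      if (t < ref_until[j]) {
        v[j] = v_reset;  // clamped; inputs ignored while refractory
      } else {
        v[j] = v_rest + (v[j] - v_rest) * decay_m +
               (i_syn[j] + i_teach[j]) * gain;
        if (v[j] >= v_thresh) {
          spikes[j].push_back(t);
          v[j] = v_reset;
          ref_until[j] = t + t_ref;
          i_teach[j] = 0.0;
        }
      }
      i_syn[j] *= decay_s;
      i_teach[j] *= decay_s;
    }
  }

  List out(n_dec);
  for (int j = 0; j < n_dec; ++j) out[j] = NumericVector(spikes[j].begin(), spikes[j].end());
  return out;
}
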