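#include <Rcpp.h>
#include <cmath>
#include <vector>
using namespace Rcpp;

// Clock-driven step loop for one liquid. Mirrors the pure-R engine
// operation-for-operation (same arithmetic expressions and summation order)
// so the two produce bitwise-identical spike records:
//   per step k (end time t_k = k*dt):
//     1. deliver input spikes binned to this step, then recurrent E spikes
//        from step k-1 (ascending index), then recurrent I spikes;
//     2. decay conductances by exp(-dt/tau_g);
//     3. integrate membranes exactly with conductances frozen over the step;
//     4. threshold, reset, start refractory; at most one spike per step.
//
// w_in:  (n x n_inputs) input weights onto g_e (zero rows for I neurons)
// w_exc: (n x n_e)      recurrent weights from E neurons onto g_e
// w_inh: (n x n_i)      recurrent weights from I neurons onto g_i
// in_step/in_id: delivery step (1-based) and input line of each input spike,
//                sorted by (step, id)
// [[Rcpp::export(name = ".run_liquid_cpp")]]
List run_liquid_cpp(NumericMatrix w_in, NumericMatrix w_exc,
                    NumericMatrix w_inh, IntegerVector in_step,
                    IntegerVector in_id, int n_steps, double dt, List pop) {
  const NumericVector tau_mem = pop["tau_mem"], e_rest = pop["e_rest"],
                      thresh = pop["thresh"], v_reset = pop["v_reset"],
                      t_refrac = pop["t_refrac"];
  const double tau_ge = pop["tau_ge"], tau_gi = pop["tau_gi"];
  const double e_exc = pop["e_exc"], e_inh = pop["e_inh"];
  const int n_e = pop["n_e"], n_i = pop["n_i"];
  const int n = n_e + n_i;

  std::vector<double> v(e_rest.begin(), e_rest.end());
  std::vector<double> ge(n, 0.0), gi(n, 0.0), ref_until(n, 0.0);
  std::vector<int> fired_e_prev, fired_i_prev, fired_e_cur, fired_i_cur;
  std::vector<int> out_neuron;
  std::vector<double> out_time;

  const double decay_e = std::exp(-dt / tau_ge);
  const double decay_i = std::exp(-dt / tau_gi);

  R_xlen_t spike_ptr = 0;
  const R_xlen_t n_in_spikes = in_step.size();

  for (int k = 1; k <= n_steps; ++k) {
    const double t_k = k * dt;

    // 1. deliver: input spikes binned to this step...
    while (spike_ptr < n_in_spikes && in_step[spike_ptr] == k) {
      const int j = in_id[spike_ptr] - 1;
      for (int i = 0; i < n; ++i) ge[i] += w_in(i, j);
      ++spike_ptr;
    }
    // ...then recurrent spikes from the previous step
    for (size_t s = 0; s < fired_e_prev.size(); ++s) {
      const int j = fired_e_prev[s];
      for (int i = 0; i < n; ++i) ge[i] += w_exc(i, j);
    }
    for (size_t s = 0; s < fired_i_prev.size(); ++s) {
      const int j = fired_i_prev[s];
      for (int i = 0; i < n; ++i) gi[i] += w_inh(i, j);
    }

    // 2. exact exponential conductance decay
    for (int i = 0; i < n; ++i) {
      ge[i] *= decay_e;
      gi[i] *= decay_i;
    }

    // 3. membrane integration, conductances frozen within the step;
    //    refractory neurons hold v = v_reset
    for (int i = 0; i < n; ++i) {
      if (t_k <= ref_until[i]) continue;
      const double denom = (1.0 + ge[i]) + gi[i];
      const double vinf = ((e_rest[i] + ge[i] * e_exc) + gi[i] * e_inh) / denom;
      v[i] = vinf + (v[i] - vinf) * std::exp(-(dt * denom) / tau_mem[i]);
    }

    // 4. threshold and reset
    fired_e_cur.clear();
    fired_i_cur.clear();
    for (int i = 0; i < n; ++i) {
      if (t_k <= ref_until[i]) continue;
      if (v[i] >= thresh[i]) {
        v[i] = v_reset[i];
        ref_until[i] = t_k + t_refrac[i];
        out_neuron.push_back(i + 1);
        out_time.push_back(t_k);
        if (i < n_e) fired_e_cur.push_back(i);
        else fired_i_cur.push_back(i - n_e);
      }
    }
    fired_e_prev.swap(fired_e_cur);
    fired_i_prev.swap(fired_i_cur);
  }

  return List::create(_["neuron"] = wrap(out_neuron),
                      _["time"] = wrap(out_time));
}
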