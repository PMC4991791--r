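#include <Rcpp.h>
#include <vector>
#include <algorithm>
using namespace Rcpp;

// One trial of the conductance-based leaky integrate-and-fire network.
//
// Synapses are exponential conductances in units of the leak conductance:
//   tau_m dV/dt = (E_leak - V) + g_e (E_e - V) + g_i (E_i - V) + g_t (E_t - V)
// with exact exponential decay of g_e, g_i each step and forward-Euler on V.
// A spike arriving at step s increments the target conductance at step s+1
// (no transmission delay beyond the integration step).
//
// Recurrent connectivity arrives in compressed sparse rows by source:
// syn_ptr (length n+1, 0-based), syn_tgt (0-based targets), syn_w (weights,
// g_leak multiples). is_inh flags inhibitory sources (their weights enter g_i).
// Input-pool projections use the same layout over n_input Poisson units firing
// at input_rate Hz during the first t_input ms.
//
// Returns spike ids (1-based), spike times (ms from trial start), and, when
// n_record_v > 0, the membrane potential of neurons 0..n_record_v-1 sampled
// every 1 ms through the recording window.
// [[Rcpp::export]]
List lif_trial_cpp(IntegerVector syn_ptr, IntegerVector syn_tgt, NumericVector syn_w,
                   LogicalVector is_inh,
                   IntegerVector inp_ptr, IntegerVector inp_tgt, NumericVector inp_w,
                   NumericVector par, int n_record_v,
                   NumericVector V0, NumericVector ge0, NumericVector gi0) {
  const double dt = par["dt"], t_input = par["t_input"], t_record = par["t_record"];
  const double input_rate = par["input_rate"];
  const double E_e = par["E_e"], E_i = par["E_i"], E_t = par["E_t"], E_L = par["E_leak"];
  const double V_th = par["V_thresh"], V_re = par["V_reset"];
  const double tau_m = par["tau_m"], tau_e = par["tau_e"], tau_i = par["tau_i"];
  const double g_t = par["g_t"];
  const int n = is_inh.size();
  const int n_input = inp_ptr.size() - 1;
  const int steps = (int) std::lround((t_input + t_record) / dt);
  const int input_steps = (int) std::lround(t_input / dt);
  const int refr_steps = (int) std::lround(par["refractory"] / dt);
  const double de = std::exp(-dt / tau_e), di = std::exp(-dt / tau_i);
  const double p_in = input_rate * dt / 1000.0;
  const int v_stride = (int) std::lround(1.0 / dt);
  const int n_vsamp = (int) std::lround(t_record);

  std::vector<double> V(n, E_L), ge(n, 0.0), gi(n, 0.0), inc_e(n, 0.0), inc_i(n, 0.0);
  if (V0.size() == n) for (int i = 0; i < n; ++i) V[i] = V0[i];
  if (ge0.size() == n) for (int i = 0; i < n; ++i) ge[i] = ge0[i];
  if (gi0.size() == n) for (int i = 0; i < n; ++i) gi[i] = gi0[i];
  std::vector<int> refr(n, 0);
  std::vector<int> spk_id;
  std::vector<double> spk_t;
  NumericMatrix Vrec(n_record_v > 0 ? n_record_v : 1, n_record_v > 0 ? n_vsamp : 1);

  for (int s = 0; s < steps; ++s) {
    for (int i = 0; i < n; ++i) {
      ge[i] = ge[i] * de + inc_e[i];
      gi[i] = gi[i] * di + inc_i[i];
      inc_e[i] = 0.0;
      inc_i[i] = 0.0;
    }
    if (s < input_steps) {
      for (int u = 0; u < n_input; ++u) {
        if (unif_rand() < p_in) {
          for (int k = inp_ptr[u]; k < inp_ptr[u + 1]; ++k) inc_e[inp_tgt[k]] += inp_w[k];
        }
      }
    }
    const double t_next = (s + 1) * dt;
    for (int i = 0; i < n; ++i) {
      if (refr[i] > 0) { refr[i]--; continue; }
      double v = V[i];
      v += dt / tau_m * ((E_L - v) + ge[i] * (E_e - v) + gi[i] * (E_i - v) + g_t * (E_t - v));
      if (v >= V_th) {
        spk_id.push_back(i + 1);
        spk_t.push_back(t_next);
        v = V_re;
        refr[i] = refr_steps;
        for (int k = syn_ptr[i]; k < syn_ptr[i + 1]; ++k) {
          if (is_inh[i]) inc_i[syn_tgt[k]] += syn_w[k]; else inc_e[syn_tgt[k]] += syn_w[k];
        }
      }
      if (v < E_i - 10.0 || v > E_e + 10.0)
        stop("membrane potential diverged (V = %f mV at t = %f ms); reduce dt = %f ms",
             v, t_next, dt);
      V[i] = v;
    }
    if (n_record_v > 0 && (s + 1) % v_stride == 0) {
      int ms = (s + 1) / v_stride - input_steps / v_stride; // 1-based ms into recording
      if (ms >= 1 && ms <= n_vsamp)
        for (int i = 0; i < n_record_v; ++i) Vrec(i, ms - 1) = V[i];
    }
  }

  List out = List::create(_["id"] = wrap(spk_id), _["time"] = wrap(spk_t),
                          _["V_final"] = wrap(V), _["ge_final"] = wrap(ge),
                          _["gi_final"] = wrap(gi));
  if (n_record_v > 0) out["V"] = Vrec;
  return out;
}

// Count excitatory presynaptic spikes in the `window` ms preceding each
// excitatory postsynaptic spike (exclusive of the spike time itself, truncated
// at trial start). Spikes arrive sorted by trial then time; pre_ptr/pre_src is
// compressed sparse column adjacency (for each target, its presynaptic
// excitatory sources, 0-based). Returns one count per postsynaptic spike of an
// excitatory neuron (id <= n_e), in input order.
// [[Rcpp::export]]
NumericVector presyn_window_counts_cpp(IntegerVector trial, IntegerVector neuron,
                                       NumericVector time, int n_neurons, int n_e,
                                       IntegerVector pre_ptr, IntegerVector pre_src,
                                       double window) {
  const int m = trial.size();
  std::vector< std::vector<double> > times(n_neurons);
  std::vector<double> out;
  out.reserve(m);
  int start = 0;
  while (start < m) {
    int end = start;
    while (end < m && trial[end] == trial[start]) ++end;
    for (int k = start; k < end; ++k) times[neuron[k] - 1].push_back(time[k]);
    for (int k = start; k < end; ++k) {
      int post = neuron[k] - 1;
      if (post >= n_e) continue;
      double t1 = time[k], t0 = t1 - window;
      int cnt = 0;
      for (int p = pre_ptr[post]; p < pre_ptr[post + 1]; ++p) {
        const std::vector<double> &ts = times[pre_src[p]];
        for (size_t q = 0; q < ts.size(); ++q)
          if (ts[q] >= t0 && ts[q] < t1) ++cnt;
      }
      out.push_back((double) cnt);
    }
    for (int k = start; k < end; ++k) times[neuron[k] - 1].clear();
    start = end;
  }
  return wrap(out);
}

// Coincident-epoch scan for neuron triplets (a, b, post). Spike positions are
// encoded as trial * span + time so that windows never straddle trials, and
// arrive concatenated per neuron (nspk_ptr, 0-based offsets; keys sorted within
// each neuron). A coincident epoch is a post spike with >= 1 spike of both a
// and b inside the centered window. For each epoch the spike of a (and of b)
// nearest the post spike defines its timing. Returns per-triplet epoch counts
// together with the signed presynaptic interval t_b - t_a per epoch.
// [[Rcpp::export]]
List coincidence_scan_cpp(IntegerMatrix triplets, IntegerVector nspk_ptr,
                          NumericVector nspk_key, double half_window) {
  const int m = triplets.nrow();
  IntegerVector counts(m);
  std::vector<double> dts;   // t_b - t_a
  std::vector<int> trip_idx; // 1-based triplet of each epoch
  for (int r = 0; r < m; ++r) {
    const int a = triplets(r, 0) - 1, b = triplets(r, 1) - 1, p = triplets(r, 2) - 1;
    const double *ka0 = &nspk_key[0] + nspk_ptr[a], *ka1 = &nspk_key[0] + nspk_ptr[a + 1];
    const double *kb0 = &nspk_key[0] + nspk_ptr[b], *kb1 = &nspk_key[0] + nspk_ptr[b + 1];
    int cnt = 0;
    for (int q = nspk_ptr[p]; q < nspk_ptr[p + 1]; ++q) {
      const double key = nspk_key[q];
      const double lo = key - half_window, hi = key + half_window;
      const double *la = std::lower_bound(ka0, ka1, lo);
      if (la == ka1 || *la > hi) continue;
      const double *lb = std::lower_bound(kb0, kb1, lo);
      if (lb == kb1 || *lb > hi) continue;
      // nearest spike of each presynaptic neuron to the post spike
      double best_a = *la, best_b = *lb;
      for (const double *x = la; x != ka1 && *x <= hi; ++x)
        if (std::fabs(*x - key) < std::fabs(best_a - key)) best_a = *x;
      for (const double *x = lb; x != kb1 && *x <= hi; ++x)
        if (std::fabs(*x - key) < std::fabs(best_b - key)) best_b = *x;
      ++cnt;
      dts.push_back(best_b - best_a);
      trip_idx.push_back(r + 1);
    }
    counts[r] = cnt;
  }
  return List::create(_["counts"] = counts, _["dt"] = wrap(dts),
                      _["triplet"] = wrap(trip_idx));
}
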