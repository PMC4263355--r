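// Time-stepped network simulation engine.
//
// Conductance-based leaky integrate-and-fire neurons with double-exponential
// synaptic kernels (exact at step resolution via rise/decay accumulators),
// optional nonlinear-dendrite bookkeeping (windowed excitatory sum, capped,
// all-or-none somatic current pulse after a fixed latency), delayed spike
// delivery along the network edges, explicit external events, engine-internal
// Poisson background and thinned delivery of oscillatory source spikes.
//
// Units: pF, nS, mV, ms; currents handled internally in pA (nS*mV), injected
// and dendritic currents are passed in nA.
//
// All engine randomness comes from a dedicated mt19937_64 per source
// (background, oscillation delivery, nothing else), so a run is fully
// deterministic given its seeds and independent of R's RNG state.

#include <Rcpp.h>
#include <random>
#include <deque>
#include <vector>
#include <cmath>

using namespace Rcpp;

struct Delivery {
  int tgt;
  double strength;
  int8_t sign;
};

static inline double u01(std::mt19937_64 &rng) {
  // 53-bit uniform in (0,1)
  return ((rng() >> 11) + 0.5) * (1.0 / 9007199254740992.0);
}

// [[Rcpp::export(name = ".sim_run_cpp")]]
List sim_run_cpp(int n_neurons,
                 List neuron,      // C_m, g_L, E_L, V_theta, V_reset, t_ref
                 List kernel_ex,   // tau_rise, tau_decay, E_rev, norm_const
                 List kernel_in,
                 bool nonadditive,
                 List dendrite,    // window, threshold, cap, latency, amps, taus, t_ref_d
                 IntegerVector e_src, IntegerVector e_tgt,
                 IntegerVector e_sign, NumericVector e_strength,
                 NumericVector e_delay,
                 IntegerVector x_neuron, NumericVector x_time,
                 IntegerVector x_sign, NumericVector x_strength,
                 double bg_rate_ex, double bg_rate_in,
                 double bg_eps_ex, double bg_eps_in, double bg_seed,
                 NumericVector osc_times, double osc_p_ex, double osc_p_in,
                 double osc_eps_ex, double osc_eps_in, double osc_seed,
                 IntegerVector f_neuron, NumericVector f_time,
                 NumericVector I_inj,   // nA per neuron
                 double dt, double duration,
                 NumericVector V0,
                 IntegerVector record_ids) {

  const double C_m = neuron["C_m"], g_L = neuron["g_L"], E_L = neuron["E_L"];
  const double V_theta = neuron["V_theta"], V_reset = neuron["V_reset"];
  const double t_ref = neuron["t_ref"];
  const double ex_tr = kernel_ex["tau_rise"], ex_td = kernel_ex["tau_decay"];
  const double ex_Er = kernel_ex["E_rev"], ex_nc = kernel_ex["norm_const"];
  const double in_tr = kernel_in["tau_rise"], in_td = kernel_in["tau_decay"];
  const double in_Er = kernel_in["E_rev"], in_nc = kernel_in["norm_const"];

  double d_window = 0, d_theta = 0, d_cap = 0, d_latency = 0, d_refd = 0;
  double d_amp[3] = {0, 0, 0}, d_dec[3] = {1, 1, 1};
  if (nonadditive) {
    d_window = dendrite["window"];
    d_theta = dendrite["threshold"];
    d_cap = dendrite["cap"];
    d_latency = dendrite["latency"];
    d_refd = dendrite["t_ref_d"];
    NumericVector amps = dendrite["amps"], taus = dendrite["taus"];
    for (int k = 0; k < 3; ++k) {
      d_amp[k] = amps[k];
      d_dec[k] = std::exp(-dt / taus[k]);
    }
  }

  const int n_steps = (int)std::llround(duration / dt);
  const double dec_exd = std::exp(-dt / ex_td), dec_exr = std::exp(-dt / ex_tr);
  const double dec_ind = std::exp(-dt / in_td), dec_inr = std::exp(-dt / in_tr);

  // --- outgoing-edge CSR ---------------------------------------------------
  const int n_edges = e_src.size();
  std::vector<int> out_count(n_neurons, 0);
  for (int e = 0; e < n_edges; ++e) out_count[e_src[e] - 1]++;
  std::vector<int> out_start(n_neurons + 1, 0);
  for (int i = 0; i < n_neurons; ++i) out_start[i + 1] = out_start[i] + out_count[i];
  std::vector<int> fill(n_neurons, 0);
  std::vector<int> oe_tgt(n_edges), oe_dstep(n_edges);
  std::vector<double> oe_str(n_edges);
  std::vector<int8_t> oe_sign(n_edges);
  for (int e = 0; e < n_edges; ++e) {
    int s = e_src[e] - 1;
    int pos = out_start[s] + fill[s]++;
    oe_tgt[pos] = e_tgt[e] - 1;
    oe_str[pos] = e_strength[e];
    oe_sign[pos] = (int8_t)e_sign[e];
    int ds = (int)std::llround(e_delay[e] / dt);
    oe_dstep[pos] = ds < 1 ? 1 : ds;
  }

  // --- per-step buckets ----------------------------------------------------
  std::vector<std::vector<Delivery>> bucket(n_steps + 1);
  for (int k = 0; k < x_neuron.size(); ++k) {
    int s = (int)std::llround(x_time[k] / dt);
    if (s < 0 || s > n_steps) stop("external event outside [0, duration]");
    if (s == n_steps) s = n_steps - 1;
    bucket[s].push_back({x_neuron[k] - 1, x_strength[k],
                         (int8_t)x_sign[k]});
  }
  std::vector<std::vector<int>> forced(n_steps + 1);
  for (int k = 0; k < f_neuron.size(); ++k) {
    int s = (int)std::llround(f_time[k] / dt);
    if (s < 0 || s >= n_steps) stop("forced spike outside [0, duration)");
    forced[s].push_back(f_neuron[k] - 1);
  }
  // oscillation source times must be sorted and inside [0, duration)
  std::vector<int> osc_step(osc_times.size());
  for (int k = 0; k < osc_times.size(); ++k) {
    int s = (int)std::llround(osc_times[k] / dt);
    if (s < 0) s = 0;
    if (s >= n_steps) s = n_steps - 1;
    osc_step[k] = s;
  }
  std::vector<std::vector<int>> onset(n_steps + 2);  // dendritic current onsets

  // --- state ---------------------------------------------------------------
  std::vector<double> V(V0.begin(), V0.end());
  std::vector<double> Dex(n_neurons, 0), Rex(n_neurons, 0);
  std::vector<double> Din(n_neurons, 0), Rin(n_neurons, 0);
  std::vector<double> c1(n_neurons, 0), c2(n_neurons, 0), c3(n_neurons, 0);
  std::vector<double> refrac_until(n_neurons, -1e300);
  std::vector<double> drefrac_until(n_neurons, -1e300);
  std::vector<std::deque<std::pair<double, double>>> win(nonadditive ? n_neurons : 0);
  std::vector<double> win_sum(nonadditive ? n_neurons : 0, 0.0);

  std::mt19937_64 rng_bg((uint64_t)bg_seed + 0x9E3779B97F4A7C15ULL);
  std::mt19937_64 rng_osc((uint64_t)osc_seed + 0xBF58476D1CE4E5B9ULL);

  // next background event time per neuron/sign (exponential gaps)
  std::vector<double> next_bg_ex(n_neurons, 1e300), next_bg_in(n_neurons, 1e300);
  const bool has_bg_ex = bg_rate_ex > 0 && bg_eps_ex > 0;
  const bool has_bg_in = bg_rate_in > 0 && bg_eps_in > 0;
  for (int i = 0; i < n_neurons; ++i) {
    if (has_bg_ex) next_bg_ex[i] = -std::log(u01(rng_bg)) / bg_rate_ex;
    if (has_bg_in) next_bg_in[i] = -std::log(u01(rng_bg)) / bg_rate_in;
  }

  // --- recording -----------------------------------------------------------
  std::vector<int> spike_id;
  std::vector<double> spike_t;
  spike_id.reserve(1024);
  spike_t.reserve(1024);
  const int n_rec = record_ids.size();
  NumericMatrix recV(n_rec > 0 ? n_steps + 1 : 0, n_rec);
  NumericMatrix recGex(n_rec > 0 ? n_steps + 1 : 0, n_rec);
  NumericMatrix recGin(n_rec > 0 ? n_steps + 1 : 0, n_rec);
  if (n_rec > 0) {
    for (int r = 0; r < n_rec; ++r) {
      int i = record_ids[r] - 1;
      recV(0, r) = V[i];
    }
  }

  int osc_idx = 0;
  const int n_osc_spikes = osc_step.size();
  // osc_times assumed sorted ascending (R side sorts)

  auto excitatory_delivery = [&](int i, double s, double t) {
    // returns the conductance increment actually applied
    if (!nonadditive) {
      Dex[i] += s * ex_nc;
      Rex[i] += s * ex_nc;
      return;
    }
    if (t < drefrac_until[i]) {
      // refractory dendrite: ordinary conductance, no window participation
      Dex[i] += s * ex_nc;
      Rex[i] += s * ex_nc;
      return;
    }
    auto &q = win[i];
    while (!q.empty() && q.front().first <= t - d_window) {
      win_sum[i] -= q.front().second;
      q.pop_front();
    }
    double before = std::min(win_sum[i], d_cap);
    double raw_after = win_sum[i] + s;
    double after = std::min(raw_after, d_cap);
    double inc = after - before;
    if (inc > 0) {
      Dex[i] += inc * ex_nc;
      Rex[i] += inc * ex_nc;
    }
    q.push_back({t, s});
    win_sum[i] = raw_after;
    if (after >= d_theta) {
      int os = (int)std::llround((t + d_latency) / dt);
      if (os <= n_steps) onset[os < 0 ? 0 : os].push_back(i);
      drefrac_until[i] = t + d_refd;
      q.clear();
      win_sum[i] = 0;
    }
  };

  // `step` is the step whose time equals the spike time, so an edge with
  // delay d delivers at exactly spike_time + round(d/dt)*dt
  auto emit_spike = [&](int i, double t, int step) {
    spike_id.push_back(i + 1);
    spike_t.push_back(t);
    V[i] = V_reset;
    refrac_until[i] = t + t_ref;
    for (int p = out_start[i]; p < out_start[i + 1]; ++p) {
      int as = step + oe_dstep[p];
      if (as < n_steps) bucket[as].push_back({oe_tgt[p], oe_str[p], oe_sign[p]});
    }
  };

  for (int s = 0; s < n_steps; ++s) {
    const double t = s * dt;

    // forced spikes
    for (int i : forced[s]) emit_spike(i, t, s);

    // background events up to end of this step
    const double t_end = t + dt;
    if (has_bg_ex || has_bg_in) {
      for (int i = 0; i < n_neurons; ++i) {
        while (next_bg_ex[i] < t_end) {
          excitatory_delivery(i, bg_eps_ex, next_bg_ex[i]);
          next_bg_ex[i] += -std::log(u01(rng_bg)) / bg_rate_ex;
        }
        while (next_bg_in[i] < t_end) {
          Din[i] += bg_eps_in * in_nc;
          Rin[i] += bg_eps_in * in_nc;
          next_bg_in[i] += -std::log(u01(rng_bg)) / bg_rate_in;
        }
      }
    }

    // oscillatory source spikes in this step: thinned delivery to every neuron
    while (osc_idx < n_osc_spikes && osc_step[osc_idx] == s) {
      double ts = osc_times[osc_idx];
      for (int i = 0; i < n_neurons; ++i) {
        if (osc_p_ex > 0 && u01(rng_osc) < osc_p_ex)
          excitatory_delivery(i, osc_eps_ex, ts);
        if (osc_p_in > 0 && u01(rng_osc) < osc_p_in) {
          Din[i] += osc_eps_in * in_nc;
          Rin[i] += osc_eps_in * in_nc;
        }
      }
      ++osc_idx;
    }

    // network + external deliveries
    for (const Delivery &d : bucket[s]) {
      if (d.sign > 0) excitatory_delivery(d.tgt, d.strength, t);
      else {
        Din[d.tgt] += d.strength * in_nc;
        Rin[d.tgt] += d.strength * in_nc;
      }
    }
    bucket[s].clear();
    bucket[s].shrink_to_fit();

    // dendritic current onsets scheduled for this step
    for (int i : onset[s]) {
      c1[i] += d_amp[0];
      c2[i] += d_amp[1];
      c3[i] += d_amp[2];
    }

    // membrane update
    for (int i = 0; i < n_neurons; ++i) {
      if (t < refrac_until[i]) {
        V[i] = V_reset;
      } else {
        double gex = Dex[i] - Rex[i];
        double gin = Din[i] - Rin[i];
        double I = (I_inj[i] + c1[i] + c2[i] + c3[i]) * 1000.0;  // nA -> pA
        double g_tot = g_L + gex + gin;
        double V_inf = (g_L * E_L + gex * ex_Er + gin * in_Er + I) / g_tot;
        V[i] = V_inf + (V[i] - V_inf) * std::exp(-dt * g_tot / C_m);
        if (V[i] >= V_theta) emit_spike(i, t + dt, s + 1);
      }
    }

    // decay accumulators
    for (int i = 0; i < n_neurons; ++i) {
      Dex[i] *= dec_exd; Rex[i] *= dec_exr;
      Din[i] *= dec_ind; Rin[i] *= dec_inr;
      if (nonadditive) { c1[i] *= d_dec[0]; c2[i] *= d_dec[1]; c3[i] *= d_dec[2]; }
    }

    if (n_rec > 0) {
      for (int r = 0; r < n_rec; ++r) {
        int i = record_ids[r] - 1;
        recV(s + 1, r) = V[i];
        recGex(s + 1, r) = Dex[i] - Rex[i];
        recGin(s + 1, r) = Din[i] - Rin[i];
      }
    }
  }

  return List::create(_["id"] = wrap(spike_id),
                      _["time"] = wrap(spike_t),
                      _["V"] = recV,
                      _["g_ex"] = recGex,
                      _["g_in"] = recGin);
}
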