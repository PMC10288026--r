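// Core Euler integrator for the columnar conductance-based LIF network.
//
// Synaptic bookkeeping uses the fact that all synapses sharing a presynaptic
// activation class decay with one factor per step: per-class conductance
// vectors decay in O(n) and are incremented by one weight-matrix column walk
// per presynaptic spike, so the cost per step is O(n + n * spikes) rather
// than a dense matrix-vector product.

#include <Rcpp.h>
#include <cmath>
#include <cstdint>
#include <random>
#include <vector>

using namespace Rcpp;

namespace {

// splitmix64, used only to seed the main engine from an R integer
inline uint64_t splitmix64(uint64_t &x) {
  x += 0x9e3779b97f4a7c15ULL;
  uint64_t z = x;
  z = (z ^ (z >> 30)) * 0xbf58476d1ce4e5b9ULL;
  z = (z ^ (z >> 27)) * 0x94d049bb133111ebULL;
  return z ^ (z >> 31);
}

struct Rng {
  std::mt19937_64 eng;
  bool has_spare;
  double spare;
  explicit Rng(uint64_t seed) : has_spare(false), spare(0.0) {
    uint64_t s = seed;
    eng.seed(splitmix64(s));
  }
  inline double unif() {
    // 53-bit uniform in (0, 1]
    return ((eng() >> 11) + 1.0) * (1.0 / 9007199254740992.0);
  }
  // explicit Box-Muller so the stream does not depend on the stdlib's
  // std::normal_distribution implementation
  inline double norm() {
    if (has_spare) {
      has_spare = false;
      return spare;
    }
    double u1 = unif(), u2 = unif();
    double m = std::sqrt(-2.0 * std::log(u1));
    double a = 6.283185307179586476925286766559 * u2;
    spare = m * std::sin(a);
    has_spare = true;
    return m * std::cos(a);
  }
};

} // namespace

// [[Rcpp::export(name = ".sim_trial_cpp")]]
List sim_trial_cpp(NumericMatrix W,          // n x n weights, W(post, pre)
                   IntegerVector sclass,     // per-neuron activation class: 0 T, 1 I, 2 M
                   NumericVector V_th_i,     // per-neuron spike threshold (mV)
                   NumericMatrix Wslow,      // n x n slow-pathway weights
                   double tau_slow,          // slow activation decay (ms)
                   double rho_slow,          // slow activation increment
                   NumericMatrix Wgate,      // n x n fast-pathway weights
                   double tau_gate,          // fast activation decay (ms)
                   double rho_gate,          // fast activation increment
                   NumericMatrix Win,        // n x n_channels input weights
                   NumericMatrix Yin,        // per (target, channel) envelope increments
                   NumericMatrix Yn,         // per (target, presyn) envelope increments
                   NumericVector Gslow,      // per-neuron envelope conductance scale
                   double tau_y,             // envelope trace decay (ms)
                   IntegerVector in_step,    // 0-based step of each input spike (sorted)
                   IntegerVector in_ch,      // 0-based channel of each input spike
                   List neuron,              // C, g_L, E_L, E_E, E_I, V_th, V_hold, t_ref, sigma_L
                   List synapse,             // rho, tau_T, tau_I, tau_M, tau_input
                   double dt,
                   int n_steps,
                   IntegerVector laser_start, // laser windows, 0-based steps, half-open
                   IntegerVector laser_end,
                   IntegerVector opto_targets, // 0-based neuron indices
                   double g_opsin,
                   double N_eff,
                   double opto_sd,
                   bool do_traces,
                   IntegerVector plast_pre,   // 0-based, per plastic synapse
                   IntegerVector plast_post,
                   List trace_par,            // tau_p, tau_d, eta_p, eta_d, T_p_max, T_d_max, tau_rate, substeps, consume_on_reward
                   IntegerVector snap_steps,  // 0-based steps at which traces are snapshotted
                   int seed,
                   NumericVector V0) {        // initial voltages (empty: E_L)
  const int n = W.nrow();
  if (W.ncol() != n) stop("weight matrix must be square");
  const int n_ch = Win.ncol();
  const int n_in = in_step.size();
  const int n_plast = do_traces ? plast_pre.size() : 0;
  const int n_snap = do_traces ? snap_steps.size() : 0;

  const double C = neuron["C"], gL = neuron["g_L"], EL = neuron["E_L"];
  const double EE = neuron["E_E"], EI = neuron["E_I"];
  const double Vhold = neuron["V_hold"], t_ref = neuron["t_ref"];
  const double sigmaL = neuron["sigma_L"];
  const double rho = synapse["rho"];
  const double tauT = synapse["tau_T"], tauI = synapse["tau_I"];
  const double tauM = synapse["tau_M"], tauIn = synapse["tau_input"];

  const double dec_s[3] = {std::exp(-dt / tauT), std::exp(-dt / tauI),
                           std::exp(-dt / tauM)};
  const double dec_in = std::exp(-dt / tauIn);
  const double dt_over_C = dt / C;

  double tau_p = 0, tau_d = 0, eta_p = 0, eta_d = 0, Tpmax = 1, Tdmax = 1,
         tau_rate = 25;
  int K = 10;
  bool consume = false;
  if (do_traces) {
    if (trace_par.containsElementNamed("consume_on_reward"))
      consume = as<bool>(trace_par["consume_on_reward"]);
    tau_p = trace_par["tau_p"];
    tau_d = trace_par["tau_d"];
    eta_p = trace_par["eta_p"];
    eta_d = trace_par["eta_d"];
    Tpmax = trace_par["T_p_max"];
    Tdmax = trace_par["T_d_max"];
    tau_rate = trace_par["tau_rate"];
    K = trace_par["trace_substeps"];
  }
  const double dt_e = dt * K;
  const double dec_rate = std::exp(-dt_e / tau_rate);
  const double rate_inc = 1000.0 / tau_rate; // Hz per spike for the filter

  std::vector<double> V(n, EL), refr(n, 0.0), s(n, 0.0), sS(n, 0.0);
  if (V0.size() == n) for (int i = 0; i < n; ++i) V[i] = V0[i];
  std::vector<double> gT(n, 0.0), gI(n, 0.0), gM(n, 0.0), gIn(n, 0.0),
      gS(n, 0.0);
  const double dec_slow = std::exp(-dt / tau_slow);
  const double dec_gate = std::exp(-dt / tau_gate);
  std::vector<double> sG(n, 0.0), gG(n, 0.0);
  // neurons with outgoing auxiliary-pathway synapses (skip walks otherwise)
  std::vector<bool> has_slow(n, false), has_gate(n, false);
  for (int j = 0; j < n; ++j) {
    const double *cs = Wslow.begin() + static_cast<size_t>(n) * j;
    const double *cg = Wgate.begin() + static_cast<size_t>(n) * j;
    for (int i = 0; i < n; ++i)
      if (cs[i] != 0.0) { has_slow[j] = true; break; }
    for (int i = 0; i < n; ++i)
      if (cg[i] != 0.0) { has_gate[j] = true; break; }
  }
  std::vector<double> sIn(n_ch, 0.0);
  // y: saturating postsynaptic envelope trace in [0, 1]; any suprathreshold
  // ignition drives it towards 1, so the timing envelope is stereotyped
  std::vector<double> y(n, 0.0);
  const double dec_y = std::exp(-dt / tau_y);
  std::vector<bool> has_yn(n, false);
  for (int j = 0; j < n; ++j) {
    const double *cy = Yn.begin() + static_cast<size_t>(n) * j;
    for (int i = 0; i < n; ++i)
      if (cy[i] != 0.0) { has_yn[j] = true; break; }
  }
  std::vector<double> rate(n, 0.0);
  std::vector<double> Tp(n_plast, 0.0), Td(n_plast, 0.0);
  std::vector<bool> is_target(n, false);
  for (int k = 0; k < opto_targets.size(); ++k)
    is_target[opto_targets[k]] = true;

  NumericMatrix Tp_snap(n_plast, n_snap), Td_snap(n_plast, n_snap);

  Rng rng(static_cast<uint64_t>(static_cast<int64_t>(seed)) + 0x51ed2701ULL);

  std::vector<int> raster_neuron, raster_step;
  raster_neuron.reserve(4096);
  raster_step.reserve(4096);
  std::vector<int> fired;
  fired.reserve(256);

  const double *Wp = W.begin();
  const double *Winp = Win.begin();

  int in_ptr = 0, snap_ptr = 0, laser_ptr = 0;
  const int n_laser = laser_start.size();

  for (int t = 0; t < n_steps; ++t) {
    // laser indicator (windows are sorted, half-open in steps)
    while (laser_ptr < n_laser && t >= laser_end[laser_ptr]) ++laser_ptr;
    const bool laser_on =
        (laser_ptr < n_laser && t >= laser_start[laser_ptr]);

    // decay conductances and activations
    const double dT = dec_s[0], dI = dec_s[1], dM = dec_s[2];
    for (int i = 0; i < n; ++i) {
      gT[i] *= dT;
      gI[i] *= dI;
      gM[i] *= dM;
      gIn[i] *= dec_in;
      gS[i] *= dec_slow;
      gG[i] *= dec_gate;
      s[i] *= dec_s[sclass[i]];
      sS[i] *= dec_slow;
      sG[i] *= dec_gate;
    }
    for (int c = 0; c < n_ch; ++c) sIn[c] *= dec_in;
    for (int i = 0; i < n; ++i) y[i] *= dec_y;

    // feed-forward input spikes arriving this step
    while (in_ptr < n_in && in_step[in_ptr] == t) {
      const int ch = in_ch[in_ptr];
      const double ds = rho * (1.0 - sIn[ch]);
      sIn[ch] += ds;
      const double *col = Winp + static_cast<size_t>(n) * ch;
      for (int i = 0; i < n; ++i) gIn[i] += col[i] * ds;
      const double *ycol = Yin.begin() + static_cast<size_t>(n) * ch;
      for (int i = 0; i < n; ++i)
        if (ycol[i] != 0.0) y[i] += ycol[i] * (1.0 - y[i]);
      ++in_ptr;
    }

    // membrane update
    fired.clear();
    for (int i = 0; i < n; ++i) {
      if (refr[i] > 0.0) {
        refr[i] -= dt;
        V[i] = Vhold;
        continue;
      }
      const double gE = gT[i] + gM[i] + gIn[i] + Gslow[i] * y[i] + gS[i] + gG[i];
      const double noise =
          (sigmaL > 0.0) ? (1.0 + sigmaL * rng.norm()) : 1.0;
      double Iop = 0.0;
      if (laser_on && is_target[i]) {
        const double sr =
            (opto_sd > 0.0) ? (1.0 + opto_sd * rng.norm()) : 1.0;
        Iop = -g_opsin * N_eff * sr; // positive g_opsin hyperpolarizes
      }
      double v = V[i];
      v += dt_over_C * (gL * (EL - v) * noise + gE * (EE - v) +
                        gI[i] * (EI - v) + Iop);
      if (!(v > -200.0 && v < 60.0))
        stop("membrane voltage left the stable range at step %d "
             "(numerical instability; reduce dt or weights)", t);
      if (v >= V_th_i[i]) {
        V[i] = Vhold;
        refr[i] = t_ref;
        fired.push_back(i);
        raster_neuron.push_back(i);
        raster_step.push_back(t);
        if (do_traces) rate[i] += rate_inc;
      } else {
        V[i] = v;
      }
    }

    // propagate spikes into the class conductances
    for (size_t k = 0; k < fired.size(); ++k) {
      const int j = fired[k];
      const double ds = rho * (1.0 - s[j]);
      s[j] += ds;
      const double *col = Wp + static_cast<size_t>(n) * j;
      double *g = (sclass[j] == 0) ? gT.data()
                                   : (sclass[j] == 1 ? gI.data() : gM.data());
      for (int i = 0; i < n; ++i) g[i] += col[i] * ds;
      if (has_slow[j]) {
        const double dss = rho_slow * (1.0 - sS[j]);
        sS[j] += dss;
        const double *cs = Wslow.begin() + static_cast<size_t>(n) * j;
        for (int i = 0; i < n; ++i) gS[i] += cs[i] * dss;
      }
      if (has_yn[j]) {
        const double *ycol = Yn.begin() + static_cast<size_t>(n) * j;
        for (int i = 0; i < n; ++i)
          if (ycol[i] != 0.0) y[i] += ycol[i] * (1.0 - y[i]);
      }
      if (has_gate[j]) {
        const double dsg = rho_gate * (1.0 - sG[j]);
        sG[j] += dsg;
        const double *cg = Wgate.begin() + static_cast<size_t>(n) * j;
        for (int i = 0; i < n; ++i) gG[i] += cg[i] * dsg;
      }
    }

    // eligibility traces and filtered rates on the coarse sub-grid
    if (do_traces && ((t + 1) % K == 0)) {
      for (int i = 0; i < n; ++i) rate[i] *= dec_rate;
      const double ap = dt_e / tau_p, ad = dt_e / tau_d;
      for (int k = 0; k < n_plast; ++k) {
        const double H = rate[plast_pre[k]] * rate[plast_post[k]];
        const double tp = Tp[k], td = Td[k];
        Tp[k] = tp + ap * (-tp + eta_p * H * (Tpmax - tp) / Tpmax);
        Td[k] = td + ad * (-td + eta_d * H * (Tdmax - td) / Tdmax);
      }
    }
    if (do_traces && snap_ptr < n_snap && snap_steps[snap_ptr] == t) {
      for (int k = 0; k < n_plast; ++k) {
        Tp_snap(k, snap_ptr) = Tp[k];
        Td_snap(k, snap_ptr) = Td[k];
        if (consume) { Tp[k] = 0.0; Td[k] = 0.0; }
      }
      ++snap_ptr;
    }
  }

  return List::create(
      Named("spike_neuron") = IntegerVector(raster_neuron.begin(),
                                            raster_neuron.end()),
      Named("spike_step") = IntegerVector(raster_step.begin(),
                                          raster_step.end()),
      Named("Tp") = Tp_snap, Named("Td") = Td_snap,
      Named("V") = NumericVector(V.begin(), V.end()));
}
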