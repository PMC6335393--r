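#include <Rcpp.h>
#include <random>
#include <vector>
#include <cmath>
using namespace Rcpp;

// Clock-driven integration of a conductance-based LIF network.
//
// Membrane:  C dV/dt = -gL (V - VL) - I_syn + I_noise + I_ext
// with I_syn summed over receptor classes; the subthreshold update is a
// first-order exponential integrator: the leak is integrated exactly and
// the synaptic/noise currents are held constant over the step.
//
// Fast receptors (AMPA, ACh, GABA_A) use the exact linear reduction: one
// conductance-weighted gating variable S per receptor class per neuron,
// decaying exponentially and incremented by g_ij * D_j at each
// presynaptic spike. NMDA keeps per-synapse two-variable gating (x, s)
// with saturating activation and a voltage-dependent magnesium block.
//
// Short-term depression: one depression variable D per presynaptic
// neuron (its dynamics depend only on that neuron's spike train, so a
// per-neuron variable is exactly equivalent to per-synapse variables
// with shared parameters). On a spike the transmitted conductance uses
// the pre-jump D, then D <- D * p_v; between spikes D relaxes to 1 with
// time constant tau_D.
//
// Per-step order: (1) accumulate NMDA conductance, (2) draw noise and
// update V (clamp |dV| <= dv_max, threshold/reset/refractory), (3) NMDA
// x/s update, (4) fast S decay, (5) deliver this step's spikes
// (increments + D jumps; targets see them from the next step), (6) D
// recovery. A spike at step end carries time (step+1)*dt.

// [[Rcpp::export(name = ".sim_core_cpp")]]
List sim_core_cpp(List neu, List syn, List kin, List cfg) {
  // --- neurons ---
  NumericVector Cm = neu["C_m"], gL = neu["g_L"], VL = neu["V_resting"],
                Vth = neu["V_threshold"], Vre = neu["V_reset"],
                Tref = neu["T_refract"], muI = neu["mu_I"],
                sigI = neu["sigma_I"], Iext = neu["I_ext"], V0 = neu["V0"];
  const int n = Cm.size();

  // --- fast synapses, CSR by presynaptic neuron ---
  IntegerVector f_ptr = syn["fast_ptr"];    // length n+1, 0-based offsets
  IntegerVector f_post = syn["fast_post"];  // 0-based
  IntegerVector f_cls = syn["fast_cls"];    // 0 AMPA, 1 ACh, 2 GABA_A
  NumericVector f_g = syn["fast_g"];        // nS (B * k * N)
  // --- NMDA synapses, CSR by presynaptic neuron ---
  IntegerVector m_ptr = syn["nmda_ptr"];
  IntegerVector m_post = syn["nmda_post"];
  NumericVector m_g = syn["nmda_g"];
  const int mn = m_post.size();

  // --- kinetics ---
  const double tau_ampa = kin["tau_ampa"], tau_ach = kin["tau_ach"],
               tau_gaba = kin["tau_gaba"], tau_s = kin["tau_nmda_s"],
               tau_x = kin["tau_nmda_x"], alpha = kin["alpha"],
               mg = kin["mg"], mg_scale = kin["mg_scale"],
               mg_slope = kin["mg_slope"], v_exc = kin["v_rev_exc"],
               v_inh = kin["v_rev_inh"];
  const double tau_D = kin["tau_d"], p_v = kin["p_v"];
  const bool std_on = tau_D > 0.0 && p_v < 1.0;

  // --- config ---
  const double dt = cfg["dt"], duration = cfg["duration"];
  const double stim_until = cfg["stim_until"];  // I_ext active while t < this
  const double dv_max = cfg["dv_max"];
  const bool thr_on = cfg["threshold_on"];
  const int seed = cfg["seed"];
  IntegerVector rec_idx = cfg["record_idx"];  // 0-based neuron indices
  const int stride = cfg["record_stride"];
  const bool rec_gates = cfg["record_gates"];

  const long nsteps = (long)std::llround(duration / dt);
  const double e_ampa = std::exp(-dt / tau_ampa),
               e_ach = std::exp(-dt / tau_ach),
               e_gaba = std::exp(-dt / tau_gaba),
               e_x = std::exp(-dt / tau_x),
               e_D = std_on ? std::exp(-dt / tau_D) : 1.0;
  std::vector<double> e_leak(n);
  for (int i = 0; i < n; ++i) e_leak[i] = std::exp(-dt * gL[i] / Cm[i]);

  // --- state ---
  std::vector<double> V(V0.begin(), V0.end());
  std::vector<double> ref(n, 0.0);
  std::vector<double> Sa(n, 0.0), Sc(n, 0.0), Sg(n, 0.0);  // AMPA, ACh, GABA
  std::vector<double> Gn(n, 0.0);                          // NMDA agg, per step
  std::vector<double> x(mn, 0.0), s(mn, 0.0);
  std::vector<double> D(n, 1.0);
  std::vector<int> counts(n, 0);

  std::mt19937_64 rng((uint64_t)seed);
  std::normal_distribution<double> gauss(0.0, 1.0);

  std::vector<int> sp_id;
  std::vector<double> sp_t;
  std::vector<int> spiked;
  spiked.reserve(256);

  const int nrec = rec_idx.size();
  long nsnap = (nrec > 0 && stride > 0) ? (nsteps / stride) : 0;
  NumericMatrix vm(nsnap, nrec);
  NumericMatrix ga(rec_gates ? nsnap : 0, rec_gates ? nrec : 0),
                gc(rec_gates ? nsnap : 0, rec_gates ? nrec : 0),
                gg(rec_gates ? nsnap : 0, rec_gates ? nrec : 0);
  NumericVector vm_t(nsnap);
  long isnap = 0;

  for (long step = 0; step < nsteps; ++step) {
    // (1) NMDA aggregate conductance
    if (mn > 0) {
      std::fill(Gn.begin(), Gn.end(), 0.0);
      for (int j = 0; j < n; ++j) {
        if (m_ptr[j] == m_ptr[j + 1]) continue;
        const double Dj = D[j];
        for (int m = m_ptr[j]; m < m_ptr[j + 1]; ++m)
          Gn[m_post[m]] += m_g[m] * s[m] * Dj;
      }
    }

    // (2) membrane update
    spiked.clear();
    for (int i = 0; i < n; ++i) {
      if (ref[i] > 0.0) {
        ref[i] -= dt;
        V[i] = Vre[i];
        continue;
      }
      double Isyn = Sa[i] * (V[i] - v_exc) + Sc[i] * (V[i] - v_exc) +
                    Sg[i] * (V[i] - v_inh);
      if (mn > 0 && Gn[i] != 0.0) {
        double block = 1.0 / (1.0 + (mg / mg_scale) * std::exp(-mg_slope * V[i]));
        Isyn += Gn[i] * block * (V[i] - v_exc);
      }
      double Inoise = (sigI[i] > 0.0 || muI[i] != 0.0)
                          ? muI[i] + sigI[i] * gauss(rng)
                          : 0.0;
      double Idrive = (step * dt < stim_until) ? Iext[i] : 0.0;
      double Vinf = VL[i] + (Inoise + Idrive - Isyn) / gL[i];
      double Vnew = Vinf + (V[i] - Vinf) * e_leak[i];
      double dV = Vnew - V[i];
      if (dV > dv_max) Vnew = V[i] + dv_max;
      else if (dV < -dv_max) Vnew = V[i] - dv_max;
      if (thr_on && Vnew >= Vth[i]) {
        sp_id.push_back(i);
        sp_t.push_back((step + 1) * dt);
        counts[i]++;
        spiked.push_back(i);
        V[i] = Vre[i];
        ref[i] = Tref[i];
      } else {
        V[i] = Vnew;
      }
      if (!std::isfinite(V[i]))
        stop("non-finite membrane potential in neuron %d at t = %f ms",
             i + 1, (step + 1) * dt);
    }

    // (3) NMDA gating
    for (int m = 0; m < mn; ++m) {
      double sm = s[m] + dt * (alpha * x[m] * (1.0 - s[m]) - s[m] / tau_s);
      s[m] = sm < 0.0 ? 0.0 : (sm > 1.0 ? 1.0 : sm);
      x[m] *= e_x;
    }

    // (4) fast gating decay
    for (int i = 0; i < n; ++i) {
      Sa[i] *= e_ampa;
      Sc[i] *= e_ach;
      Sg[i] *= e_gaba;
    }

    // (5) spike delivery
    for (int j : spiked) {
      const double Dj = D[j];
      for (int k = f_ptr[j]; k < f_ptr[j + 1]; ++k) {
        const double w = f_g[k] * Dj;
        switch (f_cls[k]) {
          case 0: Sa[f_post[k]] += w; break;
          case 1: Sc[f_post[k]] += w; break;
          default: Sg[f_post[k]] += w;
        }
      }
      for (int m = m_ptr[j]; m < m_ptr[j + 1]; ++m) x[m] += 1.0;
      if (std_on) D[j] *= p_v;
    }

    // (6) depression recovery
    if (std_on)
      for (int i = 0; i < n; ++i) D[i] = 1.0 - (1.0 - D[i]) * e_D;

    // recording
    if (nsnap > 0 && (step + 1) % stride == 0 && isnap < nsnap) {
      for (int r = 0; r < nrec; ++r) {
        vm(isnap, r) = V[rec_idx[r]];
        if (rec_gates) {
          ga(isnap, r) = Sa[rec_idx[r]];
          gc(isnap, r) = Sc[rec_idx[r]];
          gg(isnap, r) = Sg[rec_idx[r]];
        }
      }
      vm_t[isnap] = (step + 1) * dt;
      ++isnap;
    }
    if (step % 100000 == 0) Rcpp::checkUserInterrupt();
  }

  List out = List::create(
      _["spike_id"] = IntegerVector(sp_id.begin(), sp_id.end()),
      _["spike_t"] = NumericVector(sp_t.begin(), sp_t.end()),
      _["counts"] = IntegerVector(counts.begin(), counts.end()),
      _["vm"] = vm, _["vm_t"] = vm_t,
      _["V_final"] = NumericVector(V.begin(), V.end()),
      _["D_final"] = NumericVector(D.begin(), D.end()));
  if (rec_gates) {
    out["S_ampa"] = ga;
    out["S_ach"] = gc;
    out["S_gaba"] = gg;
  }
  return out;
}
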