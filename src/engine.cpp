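// Fixed-step network integrator for conductance-based two-compartment
// neurons with event-driven Tsodyks-Markram synapses and ohmic gap
// junctions.  All units: mV, ms, pA, pF, nS (pA/pF = mV/ms).
//
// The scheme is exponential Euler per compartment and per gating variable;
// cross-compartment (axial) and cross-cell (gap-junction) terms use the
// previous step's voltages, which keeps the update explicit and, for the
// conductances used here (g/C << 1/dt), stable at dt = 0.1 ms.

#include <Rcpp.h>
#include <vector>
#include <map>
#include <cmath>

using namespace Rcpp;

// Wang-Buzsaki style fast-spiking kinetics (m instantaneous).
static inline double alpha_m(double v) {
  double x = v + 35.0;
  if (std::fabs(x) < 1e-6) return 1.0;
  return 0.1 * x / (1.0 - std::exp(-x / 10.0));
}
static inline double beta_m(double v) { return 4.0 * std::exp(-(v + 60.0) / 18.0); }
static inline double alpha_h(double v) { return 0.07 * std::exp(-(v + 58.0) / 20.0); }
static inline double beta_h(double v) { return 1.0 / (1.0 + std::exp(-(v + 28.0) / 10.0)); }
static inline double alpha_n(double v) {
  double x = v + 34.0;
  if (std::fabs(x) < 1e-6) return 0.1;
  return 0.01 * x / (1.0 - std::exp(-x / 10.0));
}
static inline double beta_n(double v) { return 0.125 * std::exp(-(v + 44.0) / 80.0); }

static inline double minf(double v) {
  double a = alpha_m(v), b = beta_m(v);
  return a / (a + b);
}
// H-current activation (slow inward rectifier producing sag).
static inline double rinf(double v) { return 1.0 / (1.0 + std::exp((v + 80.0) / 8.0)); }

struct SynGroup {
  int post;
  int comp;     // 0 soma, 1 dendrite
  double decay; // exp(-dt/tau)
  double E;
  double g;     // running conductance
};

// [[Rcpp::export]]
List sim_network_cpp(List cells, List chem, List gj, List ext, List drive,
                     List control) {
  // --- cell parameters -------------------------------------------------
  NumericVector Cs = cells["Cs"], Cd = cells["Cd"];
  NumericVector gLs = cells["gL_s"], gLd = cells["gL_d"];
  NumericVector EL = cells["EL"];
  NumericVector gNa = cells["gNa"], gK = cells["gK"];
  NumericVector ENa = cells["ENa"], EK = cells["EK"];
  NumericVector phi = cells["phi"];
  NumericVector gax = cells["g_axial"];
  NumericVector gH = cells["g_h"], EH = cells["E_h"], tauH = cells["tau_h_gate"];
  NumericVector bAhp = cells["b_ahp"], tauAhp = cells["tau_ahp"], EAhp = cells["E_ahp"];
  IntegerVector twoc = cells["two_comp"];
  const int n = Cs.size();

  // --- control ---------------------------------------------------------
  const double dt = as<double>(control["dt"]);       // ms
  const double Tms = as<double>(control["T"]);       // ms
  const int nsteps = (int)std::lround(Tms / dt);
  IntegerVector rec_idx = control["record_idx"];     // 0-based
  List mean_groups = control["mean_groups"];         // list of 0-based ivec
  const int clamp_idx = as<int>(control["clamp_idx"]); // -1 = none
  const double clamp_V = as<double>(control["clamp_V"]);
  const double spike_thr = 0.0, refractory = 1.0;    // mV, ms

  // --- chemical synapse edges ------------------------------------------
  IntegerVector e_pre = chem["pre"];   // 0-based; >= n indexes ext source
  IntegerVector e_post = chem["post"];
  NumericVector e_g = chem["g"], e_E = chem["E"], e_tau = chem["tau"];
  NumericVector e_del = chem["delay"], e_U = chem["U"];
  NumericVector e_trec = chem["tau_rec"], e_tfac = chem["tau_facil"];
  IntegerVector e_comp = chem["comp"];
  const int ne = e_pre.size();

  // group edges by (post, comp, tau, E)
  std::vector<SynGroup> groups;
  std::vector<int> edge_group(ne);
  {
    std::map<std::tuple<int, int, long long, long long>, int> gm;
    for (int e = 0; e < ne; ++e) {
      auto key = std::make_tuple(e_post[e], e_comp[e],
                                 (long long)std::llround(e_tau[e] * 1e6),
                                 (long long)std::llround(e_E[e] * 1e6));
      auto it = gm.find(key);
      if (it == gm.end()) {
        SynGroup sg;
        sg.post = e_post[e];
        sg.comp = e_comp[e];
        sg.decay = std::exp(-dt / e_tau[e]);
        sg.E = e_E[e];
        sg.g = 0.0;
        gm[key] = (int)groups.size();
        edge_group[e] = (int)groups.size();
        groups.push_back(sg);
      } else {
        edge_group[e] = it->second;
      }
    }
  }
  const int ng = (int)groups.size();

  // --- gap junctions ----------------------------------------------------
  IntegerVector j_a = gj["a"], j_b = gj["b"];
  NumericVector j_g = gj["g"];
  IntegerVector j_comp = gj["comp"];
  const int nj = j_a.size();

  // --- external spike sources -------------------------------------------
  const int next = ext.size();
  std::vector<NumericVector> ext_tr(next);
  std::vector<int> ext_ptr(next, 0);
  for (int s = 0; s < next; ++s) ext_tr[s] = as<NumericVector>(ext[s]);

  // out-edge lists for internal neurons and external sources
  std::vector<std::vector<int>> out(n + next);
  for (int e = 0; e < ne; ++e) {
    if (e_pre[e] < 0 || e_pre[e] >= n + next)
      stop("edge %d references invalid presynaptic index", e + 1);
    out[e_pre[e]].push_back(e);
  }

  // --- drive -------------------------------------------------------------
  NumericVector I_const = drive["I_const"];
  List I_traces = drive["I_traces"]; // list of list(idx, comp, trace)
  std::vector<int> tr_idx, tr_comp;
  std::vector<NumericVector> tr_val;
  for (int k = 0; k < I_traces.size(); ++k) {
    List tr = I_traces[k];
    tr_idx.push_back(as<int>(tr["idx"]));
    tr_comp.push_back(as<int>(tr["comp"]));
    tr_val.push_back(as<NumericVector>(tr["trace"]));
  }

  // --- state -------------------------------------------------------------
  std::vector<double> Vs(n), Vd(n), hh(n), nn(n), rr(n), gahp(n, 0.0);
  NumericVector v_init = drive["v_init"]; // length n
  for (int i = 0; i < n; ++i) {
    double v0 = v_init[i];
    Vs[i] = v0;
    Vd[i] = v0;
    hh[i] = alpha_h(v0) / (alpha_h(v0) + beta_h(v0));
    nn[i] = alpha_n(v0) / (alpha_n(v0) + beta_n(v0));
    rr[i] = rinf(v0);
  }
  if (clamp_idx >= 0) Vs[clamp_idx] = clamp_V;

  // TM state per edge
  std::vector<double> tmx(ne, 1.0), tmu(ne, 0.0), tlast(ne, -1e18);

  // pending conductance increments ring buffer
  int maxdel = 1;
  for (int e = 0; e < ne; ++e) {
    int ds = (int)std::lround(e_del[e] / dt);
    if (ds < 1) ds = 1;
    if (ds > maxdel) maxdel = ds;
  }
  const int PB = maxdel + 2;
  std::vector<std::vector<std::pair<int, double>>> pend(PB);

  // --- output ------------------------------------------------------------
  std::vector<std::vector<double>> spikes(n);
  std::vector<double> tspk(n, -1e18);
  const int nrec = rec_idx.size();
  NumericMatrix v_soma(nrec > 0 ? nsteps : 0, nrec);
  NumericMatrix v_dend(nrec > 0 ? nsteps : 0, nrec);
  const int nmg = mean_groups.size();
  std::vector<IntegerVector> mg(nmg);
  for (int k = 0; k < nmg; ++k) mg[k] = as<IntegerVector>(mean_groups[k]);
  NumericMatrix mean_v(nmg > 0 ? nsteps : 0, nmg);
  NumericVector clamp_I(clamp_idx >= 0 ? nsteps : 0);

  std::vector<double> VsP(n), VdP(n);
  std::vector<double> Gs_syn(n), GEs_syn(n), Gd_syn(n), GEd_syn(n);

  // deliver a presynaptic spike on edge e at time tnow (schedules the
  // conductance increment after the axonal+synaptic delay)
  auto deliver = [&](int e, double tnow, int step_now) {
    double x, u;
    if (tlast[e] < -1e17) {
      x = 1.0;
      u = 0.0;
    } else {
      double d = tnow - tlast[e];
      x = 1.0 + (tmx[e] - 1.0) * std::exp(-d / e_trec[e]);
      u = (e_tfac[e] > 0.0) ? tmu[e] * std::exp(-d / e_tfac[e]) : 0.0;
    }
    u += e_U[e] * (1.0 - u);
    double rel = u * x;
    x -= rel;
    tmx[e] = x;
    tmu[e] = u;
    tlast[e] = tnow;
    int ds = (int)std::lround(e_del[e] / dt);
    if (ds < 1) ds = 1;
    int due = step_now + ds;
    pend[due % PB].push_back(std::make_pair(edge_group[e], e_g[e] * rel));
  };

  for (int s = 0; s < nsteps; ++s) {
    const double t = s * dt;

    // apply conductance increments due at this step
    {
      auto &slot = pend[s % PB];
      for (size_t q = 0; q < slot.size(); ++q)
        groups[slot[q].first].g += slot[q].second;
      slot.clear();
    }

    // external source spikes in [t, t+dt)
    for (int src = 0; src < next; ++src) {
      const NumericVector &tr = ext_tr[src];
      while (ext_ptr[src] < tr.size() && tr[ext_ptr[src]] < t + dt) {
        double ts = tr[ext_ptr[src]];
        for (size_t q = 0; q < out[n + src].size(); ++q)
          deliver(out[n + src][q], ts, s);
        ++ext_ptr[src];
      }
    }

    // decay synaptic conductances and accumulate per-neuron sums
    std::fill(Gs_syn.begin(), Gs_syn.end(), 0.0);
    std::fill(GEs_syn.begin(), GEs_syn.end(), 0.0);
    std::fill(Gd_syn.begin(), Gd_syn.end(), 0.0);
    std::fill(GEd_syn.begin(), GEd_syn.end(), 0.0);
    for (int g = 0; g < ng; ++g) {
      groups[g].g *= groups[g].decay;
      if (groups[g].comp == 0) {
        Gs_syn[groups[g].post] += groups[g].g;
        GEs_syn[groups[g].post] += groups[g].g * groups[g].E;
      } else {
        Gd_syn[groups[g].post] += groups[g].g;
        GEd_syn[groups[g].post] += groups[g].g * groups[g].E;
      }
    }

    // snapshot voltages
    std::copy(Vs.begin(), Vs.end(), VsP.begin());
    std::copy(Vd.begin(), Vd.end(), VdP.begin());

    // gap-junction contributions (conductance toward the partner's
    // previous-step voltage; antisymmetric by construction)
    for (int j = 0; j < nj; ++j) {
      int a = j_a[j], b = j_b[j];
      double va = (j_comp[j] == 1 && twoc[a]) ? VdP[a] : VsP[a];
      double vb = (j_comp[j] == 1 && twoc[b]) ? VdP[b] : VsP[b];
      if (j_comp[j] == 1 && twoc[a]) {
        Gd_syn[a] += j_g[j];
        GEd_syn[a] += j_g[j] * vb;
      } else {
        Gs_syn[a] += j_g[j];
        GEs_syn[a] += j_g[j] * vb;
      }
      if (j_comp[j] == 1 && twoc[b]) {
        Gd_syn[b] += j_g[j];
        GEd_syn[b] += j_g[j] * va;
      } else {
        Gs_syn[b] += j_g[j];
        GEs_syn[b] += j_g[j] * va;
      }
    }

    // extra injected current traces
    std::vector<double> I_extra_s, I_extra_d;
    // (small vectors allocated once outside would be faster; n is small)
    I_extra_s.assign(n, 0.0);
    I_extra_d.assign(n, 0.0);
    for (size_t k = 0; k < tr_idx.size(); ++k) {
      double val = (s < tr_val[k].size()) ? tr_val[k][s] : 0.0;
      if (tr_comp[k] == 0)
        I_extra_s[tr_idx[k]] += val;
      else
        I_extra_d[tr_idx[k]] += val;
    }

    for (int i = 0; i < n; ++i) {
      const double v = VsP[i];
      const double m = minf(v);
      const double m3 = m * m * m;
      const double n4 = nn[i] * nn[i] * nn[i] * nn[i];
      const double GNav = gNa[i] * m3 * hh[i];
      const double GKv = gK[i] * n4;
      const double Ghv = gH[i] * rr[i];

      double G = GNav + GKv + gLs[i] + gahp[i] + Ghv + Gs_syn[i];
      double NUMion = GNav * ENa[i] + GKv * EK[i] + gLs[i] * EL[i] +
                      gahp[i] * EAhp[i] + Ghv * EH[i] + GEs_syn[i];
      if (twoc[i]) {
        G += gax[i];
        NUMion += gax[i] * VdP[i];
      }
      const double Iinj = I_const[i] + I_extra_s[i];

      if (i == clamp_idx) {
        // electrode current needed to hold the soma (outward positive)
        clamp_I[s] = G * clamp_V - NUMion - Iinj;
        Vs[i] = clamp_V;
      } else {
        const double Vinfty = (NUMion + Iinj) / G;
        Vs[i] = Vinfty + (v - Vinfty) * std::exp(-dt * G / Cs[i]);
        if (!std::isfinite(Vs[i]) || std::fabs(Vs[i]) > 1000.0)
          stop("membrane potential diverged (neuron %d, t = %.3f ms)", i + 1, t);
      }

      if (twoc[i]) {
        double Gd = gLd[i] + gax[i] + Gd_syn[i];
        double NUMd = gLd[i] * EL[i] + gax[i] * v + GEd_syn[i] + I_extra_d[i];
        const double Vinfd = NUMd / Gd;
        Vd[i] = Vinfd + (VdP[i] - Vinfd) * std::exp(-dt * Gd / Cd[i]);
      }

      // gating (exponential Euler with rates at the midpoint voltage,
      // halving the splitting error of the voltage/gating staggering)
      {
        const double vm = 0.5 * (v + Vs[i]);
        double ah = alpha_h(vm), bh = beta_h(vm);
        double hinfv = ah / (ah + bh), tauh = 1.0 / (phi[i] * (ah + bh));
        hh[i] = hinfv + (hh[i] - hinfv) * std::exp(-dt / tauh);
        double an = alpha_n(vm), bn = beta_n(vm);
        double ninfv = an / (an + bn), taun = 1.0 / (phi[i] * (an + bn));
        nn[i] = ninfv + (nn[i] - ninfv) * std::exp(-dt / taun);
        if (gH[i] > 0.0) {
          double ri = rinf(vm);
          rr[i] = ri + (rr[i] - ri) * std::exp(-dt / tauH[i]);
        }
        if (bAhp[i] > 0.0) gahp[i] *= std::exp(-dt / tauAhp[i]);
      }

      // spike detection: upward crossing of 0 mV with 1 ms lockout
      if (i != clamp_idx && v < spike_thr && Vs[i] >= spike_thr &&
          (t + dt - tspk[i]) >= refractory) {
        const double ts = t + dt;
        tspk[i] = ts;
        spikes[i].push_back(ts);
        if (bAhp[i] > 0.0) gahp[i] += bAhp[i];
        for (size_t q = 0; q < out[i].size(); ++q) deliver(out[i][q], ts, s);
      }
    }

    // recording (state at the end of the step, time (s+1)*dt)
    for (int k = 0; k < nrec; ++k) {
      v_soma(s, k) = Vs[rec_idx[k]];
      v_dend(s, k) = twoc[rec_idx[k]] ? Vd[rec_idx[k]] : Vs[rec_idx[k]];
    }
    for (int k = 0; k < nmg; ++k) {
      double acc = 0.0;
      const IntegerVector &ix = mg[k];
      for (int q = 0; q < ix.size(); ++q) acc += Vs[ix[q]];
      mean_v(s, k) = acc / ix.size();
    }
  }

  List spk(n);
  for (int i = 0; i < n; ++i) spk[i] = wrap(spikes[i]);

  NumericVector tout(nsteps);
  for (int s = 0; s < nsteps; ++s) tout[s] = (s + 1) * dt;

  return List::create(_["spikes"] = spk, _["t"] = tout,
                      _["v_soma"] = v_soma, _["v_dend"] = v_dend,
                      _["mean_v"] = mean_v, _["clamp_I"] = clamp_I);
}
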