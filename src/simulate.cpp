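// Implicit (backward Euler) integrator for the branched cable with
// Hodgkin-Huxley-style channels, dual-exponential synapses and a
// single-pool calcium mechanism.
//
// Units: V mV, t ms, conductance uS, current nA, capacitance nF, Ca uM.
// Compartments are Hines-ordered (parent index < child index), so one
// child-to-root elimination pass and one root-to-leaf substitution solve
// the tree exactly per step. Voltage-dependent gate steady states and
// relaxation factors are tabulated on a voltage grid at the fixed dt.

#include <Rcpp.h>
#include <cmath>
#include <vector>
using namespace Rcpp;

static const double VMIN = -120.0, VMAX = 60.0, VSTEP = 0.25;
static const int NTAB = (int)((VMAX - VMIN) / VSTEP) + 1;

struct GateTab {
  std::vector<double> xinf, efac; // steady state and exp(-dt/tau) per V bin
};

static double tau_of(double v, double tmin, double tamp, double vpeak,
                     double vsig) {
  if (tamp <= 0.0) return tmin;
  double z = (v - vpeak) / vsig;
  return tmin + tamp * std::exp(-z * z);
}

static void build_tab(GateTab &g, double vhalf, double k, double tmin,
                      double tamp, double vpeak, double vsig, double dt) {
  g.xinf.resize(NTAB);
  g.efac.resize(NTAB);
  for (int i = 0; i < NTAB; ++i) {
    double v = VMIN + i * VSTEP;
    g.xinf[i] = 1.0 / (1.0 + std::exp((vhalf - v) / k));
    double tau = tau_of(v, tmin, tamp, vpeak, vsig);
    g.efac[i] = std::exp(-dt / tau);
  }
}

static inline int vbin(double v) {
  int i = (int)((v - VMIN) / VSTEP);
  if (i < 0) i = 0;
  if (i >= NTAB) i = NTAB - 1;
  return i;
}

struct Channel {
  std::string name;
  double erev;
  int p, q;
  bool ca_gated, is_ca;
  double ca_half, ca_hill, z_tau;
  GateTab mt, ht;
  std::vector<int> comps;      // compartments with gbar > 0
  std::vector<double> gbar;    // uS, same order as comps
  std::vector<double> m, h;    // gate states per active compartment
};

static inline double ipow(double x, int n) {
  double r = 1.0;
  for (int i = 0; i < n; ++i) r *= x;
  return r;
}

// [[Rcpp::export(name = ".simulate_core")]]
List simulate_core(IntegerVector parent, NumericVector g_axial,
                   NumericVector c_m, NumericVector g_leak, double e_leak,
                   List channels, NumericVector ca0_v, double tau_ca,
                   NumericVector phi, List syn, DataFrame events,
                   DataFrame iclamp, double dt, double duration, double v_init,
                   IntegerVector v_probes, IntegerVector ca_probes,
                   int stride) {
  const int N = parent.size();
  const int nsteps = (int)std::llround(duration / dt);

  // channels
  std::vector<Channel> ch;
  for (int c = 0; c < channels.size(); ++c) {
    List cl = channels[c];
    Channel C;
    C.name = as<std::string>(cl["name"]);
    C.erev = as<double>(cl["e_rev"]);
    C.p = as<int>(cl["p"]);
    C.q = as<int>(cl["q"]);
    C.ca_gated = as<bool>(cl["ca_gated"]);
    C.is_ca = as<bool>(cl["is_ca"]);
    NumericVector gb = cl["gbar"]; // length N, uS
    for (int i = 0; i < N; ++i)
      if (gb[i] > 0) {
        C.comps.push_back(i);
        C.gbar.push_back(gb[i]);
      }
    if (C.ca_gated) {
      C.ca_half = as<double>(cl["ca_half"]);
      C.ca_hill = as<double>(cl["ca_hill"]);
      C.z_tau = as<double>(cl["z_tau"]);
    } else {
      NumericVector mt = cl["m_tau"];
      build_tab(C.mt, as<double>(cl["m_vhalf"]), as<double>(cl["m_k"]),
                mt[0], mt[1], mt[2], mt[3], dt);
      if (C.q > 0) {
        NumericVector ht = cl["h_tau"];
        build_tab(C.ht, as<double>(cl["h_vhalf"]), as<double>(cl["h_k"]),
                  ht[0], ht[1], ht[2], ht[3], dt);
      }
    }
    C.m.assign(C.comps.size(), 0.0);
    C.h.assign(C.comps.size(), 1.0);
    ch.push_back(C);
  }

  // initialize gates at v_init / ca0
  for (size_t c = 0; c < ch.size(); ++c) {
    Channel &C = ch[c];
    for (size_t j = 0; j < C.comps.size(); ++j) {
      if (C.ca_gated) {
        double can = std::pow(ca0_v[C.comps[j]], C.ca_hill);
        double kn = std::pow(C.ca_half, C.ca_hill);
        C.m[j] = can / (can + kn);
      } else {
        int b = vbin(v_init);
        C.m[j] = C.mt.xinf[b];
        if (C.q > 0) C.h[j] = C.ht.xinf[b];
      }
    }
  }

  // synapses: aggregated dual-exponential state per kind per compartment
  NumericVector s_taud = syn["tau_decay"], s_taur = syn["tau_rise"],
                s_erev = syn["e_rev"];
  double mg = as<double>(syn["mg"]), mg_gamma = as<double>(syn["mg_gamma"]),
         mg_scale = as<double>(syn["mg_scale"]);
  double decd[3], decr[3];
  for (int k = 0; k < 3; ++k) {
    decd[k] = std::exp(-dt / s_taud[k]);
    decr[k] = std::exp(-dt / s_taur[k]);
  }
  std::vector<std::vector<double> > A(3, std::vector<double>(N, 0.0)),
      B(3, std::vector<double>(N, 0.0));

  IntegerVector ev_comp = events["comp"], ev_kind = events["kind"];
  NumericVector ev_onset = events["onset"], ev_ginc = events["g_inc"];
  const int nev = ev_comp.size();
  int ev_next = 0;

  IntegerVector ic_comp, ic_n;
  NumericVector ic_start, ic_dur, ic_amp;
  int nic = 0;
  if (iclamp.nrows() > 0) {
    ic_comp = iclamp["comp"];
    ic_start = iclamp["start"];
    ic_dur = iclamp["dur"];
    ic_amp = iclamp["amp"];
    nic = ic_comp.size();
  }

  // state
  std::vector<double> V(N, v_init), ca(N);
  for (int i = 0; i < N; ++i) ca[i] = ca0_v[i];
  std::vector<double> d(N), rhs(N), gch(N), ge(N), ica(N);

  // recording
  const int nrec = nsteps / stride + 1;
  NumericMatrix vrec(nrec, v_probes.size());
  NumericMatrix carec(nrec, ca_probes.size());
  NumericVector trec(nrec);
  int ri = 0;
  for (int pz = 0; pz < v_probes.size(); ++pz) vrec(0, pz) = v_init;
  for (int pz = 0; pz < ca_probes.size(); ++pz) carec(0, pz) = ca[ca_probes[pz]];
  trec[0] = 0.0;
  ri = 1;

  const double cinv = 1.0 / dt;

  for (int step = 1; step <= nsteps; ++step) {
    double t = step * dt;

    // gate updates from previous-step V / Ca, accumulate conductances
    std::fill(gch.begin(), gch.end(), 0.0);
    std::fill(ge.begin(), ge.end(), 0.0);
    for (size_t c = 0; c < ch.size(); ++c) {
      Channel &C = ch[c];
      const size_t nc = C.comps.size();
      if (C.ca_gated) {
        double kn = std::pow(C.ca_half, C.ca_hill);
        double ef = std::exp(-dt / C.z_tau);
        for (size_t j = 0; j < nc; ++j) {
          double c2 = ca[C.comps[j]] * ca[C.comps[j]];
          double can = c2 * c2; // Hill n = 4
          if (C.ca_hill != 4.0) can = std::pow(ca[C.comps[j]], C.ca_hill);
          double zi = can / (can + kn);
          C.m[j] = zi + (C.m[j] - zi) * ef;
          double g = C.gbar[j] * ipow(C.m[j], C.p);
          gch[C.comps[j]] += g;
          ge[C.comps[j]] += g * C.erev;
        }
      } else {
        for (size_t j = 0; j < nc; ++j) {
          int i = C.comps[j];
          int b = vbin(V[i]);
          C.m[j] = C.mt.xinf[b] + (C.m[j] - C.mt.xinf[b]) * C.mt.efac[b];
          double g = C.gbar[j] * ipow(C.m[j], C.p);
          if (C.q > 0) {
            C.h[j] = C.ht.xinf[b] + (C.h[j] - C.ht.xinf[b]) * C.ht.efac[b];
            g *= ipow(C.h[j], C.q);
          }
          gch[i] += g;
          ge[i] += g * C.erev;
        }
      }
    }

    // synapse state: decay, then add events whose onset falls in (t-dt, t]
    for (int k = 0; k < 3; ++k) {
      std::vector<double> &Ak = A[k], &Bk = B[k];
      for (int i = 0; i < N; ++i) {
        Ak[i] *= decd[k];
        Bk[i] *= decr[k];
      }
    }
    while (ev_next < nev && ev_onset[ev_next] <= t) {
      int k = ev_kind[ev_next], i = ev_comp[ev_next];
      A[k][i] += ev_ginc[ev_next];
      B[k][i] += ev_ginc[ev_next];
      ++ev_next;
    }
    // add synaptic conductances (NMDA gated by Mg block at previous V)
    for (int k = 0; k < 3; ++k) {
      std::vector<double> &Ak = A[k], &Bk = B[k];
      for (int i = 0; i < N; ++i) {
        double g = Ak[i] - Bk[i];
        if (g <= 0) continue;
        if (k == 1) g *= 1.0 / (1.0 + (mg / mg_scale) *
                                         std::exp(-mg_gamma * V[i]));
        gch[i] += g;
        ge[i] += g * s_erev[k];
      }
    }

    // assemble
    for (int i = 0; i < N; ++i) {
      d[i] = c_m[i] * cinv + g_leak[i] + gch[i];
      rhs[i] = c_m[i] * cinv * V[i] + g_leak[i] * e_leak + ge[i];
    }
    for (int i = 1; i < N; ++i) {
      d[i] += g_axial[i];
      d[parent[i]] += g_axial[i];
    }
    for (int j = 0; j < nic; ++j) {
      if (t >= ic_start[j] && t < ic_start[j] + ic_dur[j])
        rhs[ic_comp[j]] += ic_amp[j];
    }
    // Hines elimination (children first) and back substitution
    for (int i = N - 1; i >= 1; --i) {
      double f = g_axial[i] / d[i];
      d[parent[i]] -= f * g_axial[i];
      rhs[parent[i]] += f * rhs[i];
    }
    V[0] = rhs[0] / d[0];
    for (int i = 1; i < N; ++i)
      V[i] = (rhs[i] + g_axial[i] * V[parent[i]]) / d[i];

    // calcium update from Ca-channel currents at the new voltage
    std::fill(ica.begin(), ica.end(), 0.0);
    for (size_t c = 0; c < ch.size(); ++c) {
      Channel &C = ch[c];
      if (!C.is_ca) continue;
      for (size_t j = 0; j < C.comps.size(); ++j) {
        int i = C.comps[j];
        double g = C.gbar[j] * ipow(C.m[j], C.p);
        if (C.q > 0) g *= ipow(C.h[j], C.q);
        ica[i] += g * (V[i] - C.erev); // negative = inward
      }
    }
    double efca = std::exp(-dt / tau_ca);
    for (int i = 0; i < N; ++i) {
      double cinf = ca0_v[i] - tau_ca * phi[i] * ica[i];
      ca[i] = cinf + (ca[i] - cinf) * efca;
      if (ca[i] < 0) ca[i] = 0;
    }

    if (step % 400 == 0 || step == nsteps) {
      for (int i = 0; i < N; ++i) {
        if (!std::isfinite(V[i]) || V[i] < -200.0 || V[i] > 200.0)
          stop("numerical failure at t = %.3f ms, compartment %d (V = %g)",
               t, i + 1, V[i]);
      }
    }

    if (step % stride == 0 && ri < nrec) {
      trec[ri] = t;
      for (int pz = 0; pz < v_probes.size(); ++pz) vrec(ri, pz) = V[v_probes[pz]];
      for (int pz = 0; pz < ca_probes.size(); ++pz)
        carec(ri, pz) = ca[ca_probes[pz]];
      ++ri;
    }
  }

  NumericVector vfin(N), cafin(N);
  for (int i = 0; i < N; ++i) {
    vfin[i] = V[i];
    cafin[i] = ca[i];
  }
  return List::create(_["time"] = trec, _["v"] = vrec, _["ca"] = carec,
                      _["v_final"] = vfin, _["ca_final"] = cafin,
                      _["n_events_applied"] = ev_next);
}
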