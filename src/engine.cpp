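// Compiled network integrator for the thalamocortical sleep-stage model.
//
// Cells: two-compartment cortical PY/IN (zero-capacitance axo-somatic
// compartment solved algebraically each step) and single-compartment TC/RE.
// Gating variables advance by exponential Euler with voltage-dependent
// rates tabulated on a fine grid; synapse open fractions are shared per
// presynaptic neuron and receptor type, and per-target conductances are
// accumulated through prefix sums over the contiguous fan-in ranges of the
// one-dimensional topology. Miniature PSPs are an event-driven
// inhomogeneous Poisson process per connection (binary heap, lazy
// invalidation on presynaptic spikes).

#include <Rcpp.h>
#include <vector>
#include <queue>
#include <map>
#include <string>
#include <cmath>
#include <random>

using namespace Rcpp;

// ---------------------------------------------------------------- constants
struct Consts {
  std::map<std::string, double> m;
  double operator()(const std::string& k) const {
    auto it = m.find(k);
    if (it == m.end()) stop("missing constant: " + k);
    return it->second;
  }
};

static Consts make_consts(const NumericVector& flat) {
  Consts c;
  CharacterVector nm = flat.names();
  for (int i = 0; i < flat.size(); ++i) c.m[std::string(nm[i])] = flat[i];
  return c;
}

// ---------------------------------------------------------------- rate math
static inline double vtrap(double x, double y) {
  if (std::fabs(x / y) < 1e-6) return y * (1.0 - x / y / 2.0);
  return x / (std::exp(x / y) - 1.0);
}

struct Rates { double minf, taum, hinf, tauh; };

static Rates cx_na(double v, double tadj, double shift) {
  v -= shift;
  double am = 0.182 * vtrap(-(v + 35.0), 9.0);
  double bm = 0.124 * vtrap(v + 35.0, 9.0);
  double ah = 0.024 * vtrap(-(v + 50.0), 5.0);
  double bh = 0.0091 * vtrap(v + 75.0, 5.0);
  Rates r;
  r.minf = am / (am + bm); r.taum = 1.0 / ((am + bm) * tadj);
  r.hinf = 1.0 / (1.0 + std::exp((v + 65.0) / 6.2));
  r.tauh = 1.0 / ((ah + bh) * tadj);
  return r;
}

static Rates cx_k(double v, double tadj) {
  double aa = 0.02 * vtrap(-(v - 25.0), 9.0);
  double bb = 0.002 * vtrap(v - 25.0, 9.0);
  Rates r; r.minf = aa / (aa + bb); r.taum = 1.0 / ((aa + bb) * tadj);
  r.hinf = 0; r.tauh = 1; return r;
}

static Rates cx_km(double v, double tadj, double rr) {
  double a = rr * vtrap(-(v + 30.0), 9.0);
  double b = rr * vtrap(v + 30.0, 9.0);
  Rates r; r.minf = a / (a + b); r.taum = 1.0 / ((a + b) * tadj);
  r.hinf = 0; r.tauh = 1; return r;
}

static Rates cx_ca(double v, double tadj) {
  double am = 0.055 * vtrap(-27.0 - v, 3.8);
  double bm = 0.94 * std::exp((-75.0 - v) / 17.0);
  double ah = 0.000457 * std::exp((-13.0 - v) / 50.0);
  double bh = 0.0065 / (std::exp((-15.0 - v) / 28.0) + 1.0);
  Rates r;
  r.minf = am / (am + bm); r.taum = 1.0 / ((am + bm) * tadj);
  r.hinf = ah / (ah + bh); r.tauh = 1.0 / ((ah + bh) * tadj);
  return r;
}

static Rates th_na(double v, double vtr) {
  double v2 = v - vtr;
  double am = 0.32 * vtrap(13.0 - v2, 4.0);
  double bm = 0.28 * vtrap(v2 - 40.0, 5.0);
  double ah = 0.128 * std::exp((17.0 - v2) / 18.0);
  double bh = 4.0 / (1.0 + std::exp((40.0 - v2) / 5.0));
  Rates r;
  r.minf = am / (am + bm); r.taum = 1.0 / (am + bm);
  r.hinf = ah / (ah + bh); r.tauh = 1.0 / (ah + bh);
  return r;
}

static Rates th_k(double v, double vtr) {
  double v2 = v - vtr;
  double an = 0.032 * vtrap(15.0 - v2, 5.0);
  double bn = 0.5 * std::exp((10.0 - v2) / 40.0);
  Rates r; r.minf = an / (an + bn); r.taum = 1.0 / (an + bn);
  r.hinf = 0; r.tauh = 1; return r;
}

static Rates tc_it(double v, double msh, double hsh, double phim, double phih) {
  Rates r;
  r.minf = 1.0 / (1.0 + std::exp(-(v + msh) / 6.2));
  r.hinf = 1.0 / (1.0 + std::exp((v + hsh) / 4.0));
  r.taum = (0.612 + 1.0 / (std::exp(-(v + 132.0) / 16.7) + std::exp((v + 16.8) / 18.2))) / phim;
  r.tauh = (v < -80.0 ? std::exp((v + 467.0) / 66.6) : 28.0 + std::exp(-(v + 22.0) / 10.5)) / phih;
  return r;
}

static Rates re_it(double v, double msh, double hsh, double phim, double phih) {
  Rates r;
  r.minf = 1.0 / (1.0 + std::exp(-(v + msh) / 7.4));
  r.hinf = 1.0 / (1.0 + std::exp((v + hsh) / 5.0));
  r.taum = (3.0 + 1.0 / (std::exp((v + 27.0) / 10.0) + std::exp(-(v + 102.0) / 15.0))) / phim;
  r.tauh = (85.0 + 1.0 / (std::exp((v + 48.0) / 4.0) + std::exp(-(v + 407.0) / 50.0))) / phih;
  return r;
}

// ------------------------------------------------------------- rate tables
static const double VMIN = -130.0, VMAX = 60.0, DV = 0.05;
static const int NV = (int)((VMAX - VMIN) / DV) + 2;

struct Probe { int i; double f; };
static inline Probe probe_v(double v) {
  if (v < VMIN) v = VMIN;
  if (v > VMAX - DV) v = VMAX - DV;
  double x = (v - VMIN) / DV;
  Probe p;
  p.i = (int)x;
  p.f = x - p.i;
  return p;
}

struct Tab {
  std::vector<double> y;
  Tab() : y(NV, 0.0) {}
  inline double operator()(double v) const {
    Probe p = probe_v(v);
    return at(p);
  }
  inline double at(const Probe& p) const {
    return y[p.i] * (1.0 - p.f) + y[p.i + 1] * p.f;
  }
};

struct Tables {
  Tab cxna_m, cxna_h, cxna_em, cxna_eh;
  Tab cxk_n, cxk_en;
  Tab cxkm_m, cxkm_em;
  Tab cxca_m, cxca_em, cxca_h, cxca_eh;
  Tab nap_m;           // pure sigmoid; the activation cap multiplies the current
  Tab thna_m, thna_h, thna_em, thna_eh;
  Tab thk_n, thk_en;
  Tab tcit_m, tcit_h, tcit_em, tcit_eh;
  Tab reit_m, reit_h, reit_em, reit_eh;
  Tab ih_hinf, ih_invtau;
  Tab mgblock;
  double tadj_cx;
};

static Tables make_tables(const Consts& C, double dt) {
  Tables T;
  double temp = C("temperature_C");
  double tadj = std::pow(C("cortex.kinetics.q10_na"),
                         (temp - C("cortex.kinetics.base_temp_cortex")) / 10.0);
  T.tadj_cx = tadj;
  double nash = C("cortex.kinetics.na_shift");
  double kmr = C("cortex.kinetics.km_rate");
  double napc = C("cortex.kinetics.nap_act_max");
  double vtr = C("thalamus.kinetics.vtr");
  double vtrk = C("thalamus.kinetics.vtr_k");
  double phim_tc = std::pow(C("thalamus.kinetics.q10_it_m"),
                            (temp - C("thalamus.kinetics.base_temp_it")) / 10.0);
  double phih_tc = std::pow(C("thalamus.kinetics.q10_it_h"),
                            (temp - C("thalamus.kinetics.base_temp_it")) / 10.0);
  double ihvh = C("ih.vhalf"), ihsl = C("ih.slope"), ihtf = C("ih.tau_floor");
  double mgv = C("synapse.nmda.mg_vhalf"), mgs = C("synapse.nmda.mg_slope");
  for (int i = 0; i < NV; ++i) {
    double v = VMIN + i * DV;
    Rates r = cx_na(v, tadj, nash);
    T.cxna_m.y[i] = r.minf; T.cxna_h.y[i] = r.hinf;
    T.cxna_em.y[i] = std::exp(-dt / r.taum); T.cxna_eh.y[i] = std::exp(-dt / r.tauh);
    r = cx_k(v, tadj);
    T.cxk_n.y[i] = r.minf; T.cxk_en.y[i] = std::exp(-dt / r.taum);
    r = cx_km(v, tadj, kmr);
    T.cxkm_m.y[i] = r.minf; T.cxkm_em.y[i] = std::exp(-dt / r.taum);
    r = cx_ca(v, tadj);
    T.cxca_m.y[i] = r.minf; T.cxca_em.y[i] = std::exp(-dt / r.taum);
    T.cxca_h.y[i] = r.hinf; T.cxca_eh.y[i] = std::exp(-dt / r.tauh);
    T.nap_m.y[i] = 1.0 / (1.0 + std::exp(-(v + 42.0) / 5.0));
    r = th_na(v, vtr);
    T.thna_m.y[i] = r.minf; T.thna_h.y[i] = r.hinf;
    T.thna_em.y[i] = std::exp(-dt / r.taum); T.thna_eh.y[i] = std::exp(-dt / r.tauh);
    r = th_k(v, vtrk);
    T.thk_n.y[i] = r.minf; T.thk_en.y[i] = std::exp(-dt / r.taum);
    r = tc_it(v, C("thalamus.kinetics.it_tc_mshift"), C("thalamus.kinetics.it_tc_hshift"),
              phim_tc, phih_tc);
    T.tcit_m.y[i] = r.minf; T.tcit_h.y[i] = r.hinf;
    T.tcit_em.y[i] = std::exp(-dt / r.taum); T.tcit_eh.y[i] = std::exp(-dt / r.tauh);
    r = re_it(v, C("thalamus.kinetics.it_re_mshift"), C("thalamus.kinetics.it_re_hshift"),
              std::pow(5.0, 1.2), std::pow(3.0, 1.2));
    T.reit_m.y[i] = r.minf; T.reit_h.y[i] = r.hinf;
    T.reit_em.y[i] = std::exp(-dt / r.taum); T.reit_eh.y[i] = std::exp(-dt / r.tauh);
    T.ih_hinf.y[i] = 1.0 / (1.0 + std::exp((v + ihvh) / ihsl));
    double taus = ihtf + 1000.0 / (std::exp((v + 71.5) / 14.2) + std::exp(-(v + 89.0) / 11.6));
    T.ih_invtau.y[i] = 1.0 / taus;
    T.mgblock.y[i] = 1.0 / (1.0 + std::exp(-(v - mgv) / mgs));
  }
  return T;
}

// --------------------------------------------------------------- cell state
struct CxPop {
  int n = 0;
  double g_kleak, g_clleak, g_na_d, g_nap_d, g_ca_d, g_kca_d, g_km_d;
  double g_na_s, g_k_s, g_nap_s;
  double cm, area_d, area_s, gcs_d, gcs_s;
  std::vector<double> vd, vs, m_nad, h_nad, m_nap, m_ca, h_ca, m_km, m_kca,
      m_nas, h_nas, n_ks, cai, last_spike;
};

struct ThPop {
  int n = 0;
  bool is_tc = true;
  double g_leak, g_kleak, g_na, g_k, g_lca, g_h, e_leak;
  double cm, area;
  std::vector<double> v, m_na, h_na, n_k, m_it, h_it, o_h, p1_h, ol_h, cai, last_spike;
};

struct GateRange {
  double lo = 1e9, hi = -1e9;
  inline void upd(double x) { if (x < lo) lo = x; if (x > hi) hi = x; }
};

struct Proj {
  int type;              // 0 AMPA, 1 NMDA, 2 GABAA, 3 GABAB
  int src_pop, tgt_pop;  // 0 PY, 1 IN, 2 TC, 3 RE
  int l_class;           // 0 none, 1 LACh, 2 LGABA
  bool depression;
  std::vector<int> lo, hi;     // per-target fan-in range (0-based, inclusive)
  std::vector<int> self_ex;    // subtract own index from the range sum?
  std::vector<double> w;       // per-edge conductance (uS)
};

struct MiniEdge {
  int src_pop, src, tgt_pop, tgt;
  int cls;   // 0 AMPA (LACh-scaled), 1 AMPA (unscaled), 2 GABA-A (tonic scale)
  double g;  // uS
};

struct MiniEvent {
  double t; int edge; double t0;
  bool operator>(const MiniEvent& o) const { return t > o.t; }
};

struct Stim { int pop; double amp, from, to; };

struct Engine {
  Consts C;
  Tables T;
  double dt = 0.02;

  CxPop py, inn;
  ThPop tc, re;
  std::vector<Proj> projs;

  std::vector<MiniEdge> minis;
  std::vector<double> mini_t0;
  std::priority_queue<MiniEvent, std::vector<MiniEvent>, std::greater<MiniEvent>> heap;
  std::vector<std::vector<int>> mini_by_src[4];

  std::mt19937_64 rng;
  std::uniform_real_distribution<double> unif{0.0, 1.0};

  // shared per-presynaptic-neuron synapse states
  std::vector<double> o_ampa[4], o_nmda[4], o_gabaa[4];
  std::vector<double> r_gabab, g_gabab; // RE only
  std::vector<double> e_dep;            // PY only (intracortical depression)
  std::vector<double> pulse_end[4];

  // per-target accumulators (uS) and mini aggregates
  std::vector<double> accA[4], accN[4], accGA[4], accGB[4];
  std::vector<double> miniA[4], miniG[4];
  std::vector<double> prefix; // scratch

  // cached constants
  double e_na, e_k, e_cl, e_h, e_ca_cx, e_ampa, e_gaba, ca_o, rtf2;
  double tpulse_ms, tconc;
  double a_ampa, b_ampa, a_nmda, b_nmda, a_gabaa, b_gabaa;
  double gb_k1, gb_k2, gb_k3, gb_k4, gb_kd;
  double dep_u, dep_tau;
  double mini_tau, mini_cap, jumpA, jumpG;
  double cadrive_cx, cafloor_cx, catau_cx, e_catau_cx;
  double cadrive_th, cafloor_th, catau_th, e_catau_th;
  double ih_k1, ih_k2, ih_k3, ih_k4, ih_klock;
  double kca_a, kca_b, nap_cap, nap_tau_e;
  double spk_thresh, refrac, soma_tol;
  int soma_maxit = 60;
  bool extended = false; // also scale dendritic KCa, Km, Nap by AChPY

  GateRange gr;

  // ---- mini process helpers ----
  double mini_H(double d) const {
    double x = d / mini_tau;
    double l = (x > 30.0) ? x + std::log1p(std::exp(-x)) : std::log1p(std::exp(x));
    return (2.0 * mini_tau * (l - std::log(2.0)) - d) / mini_cap;
  }
  double mini_rate_f(double d) const {
    return (2.0 / (1.0 + std::exp(-d / mini_tau)) - 1.0) / mini_cap;
  }
  double mini_sample(double t0, double from) {
    double base = std::max(from - t0, 0.0);
    double target = mini_H(base) - std::log(std::max(unif(rng), 1e-300));
    double d = std::max(base + 1.0, mini_cap * target + 2.0 * mini_tau);
    for (int i = 0; i < 80; ++i) {
      double f = mini_H(d) - target;
      double fp = std::max(mini_rate_f(d), 1e-12);
      double dn = d - f / fp;
      if (dn <= base) dn = 0.5 * (d + base);
      if (std::fabs(dn - d) < 1e-6) { d = dn; break; }
      d = dn;
    }
    return t0 + d;
  }
  void mini_schedule(int e, double from) {
    heap.push(MiniEvent{mini_sample(mini_t0[e], from), e, mini_t0[e]});
  }

  void cache_consts() {
    e_na = C("reversals.e_na"); e_k = C("reversals.e_k");
    e_cl = C("reversals.e_cl_cortex"); e_h = C("reversals.e_h");
    e_ca_cx = C("reversals.e_ca_cortex");
    e_ampa = C("reversals.e_ampa"); e_gaba = C("reversals.e_gaba");
    ca_o = C("reversals.ca_o_mM");
    rtf2 = 1000.0 * 8.31441 * (273.15 + C("temperature_C")) / (2.0 * 96485.3);
    tpulse_ms = C("synapse.t_pulse_ms"); tconc = C("synapse.t_pulse_mM");
    a_ampa = C("synapse.ampa.alpha"); b_ampa = C("synapse.ampa.beta");
    a_nmda = C("synapse.nmda.alpha"); b_nmda = C("synapse.nmda.beta");
    a_gabaa = C("synapse.gabaa.alpha"); b_gabaa = C("synapse.gabaa.beta");
    gb_k1 = C("synapse.gabab.k1"); gb_k2 = C("synapse.gabab.k2");
    gb_k3 = C("synapse.gabab.k3"); gb_k4 = C("synapse.gabab.k4");
    gb_kd = C("synapse.gabab.kd");
    dep_u = C("synapse.depression.use"); dep_tau = C("synapse.depression.tau_rec");
    mini_tau = C("synapse.mini.rate_tau"); mini_cap = C("synapse.mini.rate_cap");
    // open-fraction jump equivalent to one transmitter pulse from O = 0
    {
      double at = a_ampa * tconc;
      jumpA = at / (at + b_ampa) * (1.0 - std::exp(-(at + b_ampa) * tpulse_ms));
      at = a_gabaa * tconc;
      jumpG = at / (at + b_gabaa) * (1.0 - std::exp(-(at + b_gabaa) * tpulse_ms));
    }
    cadrive_cx = C("cortex.calcium.drive"); cafloor_cx = C("cortex.calcium.floor_mM");
    catau_cx = C("cortex.calcium.tau_ms"); e_catau_cx = std::exp(-dt / catau_cx);
    cadrive_th = C("thalamus.calcium.drive"); cafloor_th = C("thalamus.calcium.floor_mM");
    catau_th = C("thalamus.calcium.tau_ms"); e_catau_th = std::exp(-dt / catau_th);
    ih_k1 = C("ih.k1"); ih_k2 = C("ih.k2"); ih_k3 = C("ih.k3"); ih_k4 = C("ih.k4");
    ih_klock = C("ih.k_locked");
    kca_a = C("cortex.kinetics.kca_alpha_per_mM"); kca_b = C("cortex.kinetics.kca_beta");
    nap_cap = C("cortex.kinetics.nap_act_max");
    nap_tau_e = std::exp(-dt / C("cortex.kinetics.nap_tau"));
    spk_thresh = C("engine.spike_threshold_mV");
    refrac = C("engine.spike_refractory_ms");
    soma_tol = C("engine.soma_tol_mV");
    soma_maxit = (int)C("engine.soma_max_iter");
  }
};

static void init_cx(Engine& E, CxPop& p, bool is_py, int n) {
  const Consts& C = E.C;
  std::string k = is_py ? "cortex.py." : "cortex.in.";
  p.n = n;
  p.g_kleak = C(k + "g_kleak"); p.g_clleak = C(k + "g_clleak");
  p.g_na_d = C(k + "g_na_dend"); p.g_nap_d = C(k + "g_nap_dend");
  p.g_ca_d = C(k + "g_ca_dend"); p.g_kca_d = C(k + "g_kca_dend");
  p.g_km_d = C(k + "g_km_dend");
  p.g_na_s = C(k + "g_na_soma"); p.g_k_s = C(k + "g_k_soma"); p.g_nap_s = C(k + "g_nap_soma");
  p.cm = C("cortex.cm");
  p.area_s = C("areas.soma_cm2");
  p.area_d = p.area_s * (is_py ? C("areas.rho_py") : C("areas.rho_in"));
  double gtot_mS = 1.0 / (C("cortex.kappa_Mohm") * 1e6) * 1e3;
  p.gcs_s = gtot_mS / p.area_s;
  p.gcs_d = gtot_mS / p.area_d;
  for (auto* v : {&p.vd, &p.vs, &p.m_nad, &p.h_nad, &p.m_nap, &p.m_ca, &p.h_ca,
                  &p.m_km, &p.m_kca, &p.m_nas, &p.h_nas, &p.n_ks, &p.cai, &p.last_spike})
    v->assign(n, 0.0);
}

static void init_th(Engine& E, ThPop& p, bool is_tc, int n) {
  const Consts& C = E.C;
  std::string k = is_tc ? "thalamus.tc." : "thalamus.re.";
  p.n = n; p.is_tc = is_tc;
  p.g_leak = C(k + "g_leak"); p.g_kleak = C(k + "g_kleak");
  p.g_na = C(k + "g_na"); p.g_k = C(k + "g_k"); p.g_lca = C(k + "g_lca");
  p.g_h = is_tc ? C("thalamus.tc.g_h") : 0.0;
  p.e_leak = is_tc ? C("reversals.e_leak_tc") : C("reversals.e_leak_re");
  p.cm = C("thalamus.cm");
  p.area = is_tc ? C("areas.tc_cm2") : C("areas.re_cm2");
  for (auto* v : {&p.v, &p.m_na, &p.h_na, &p.n_k, &p.m_it, &p.h_it, &p.o_h,
                  &p.p1_h, &p.ol_h, &p.cai, &p.last_spike})
    v->assign(n, 0.0);
}

static void seed_cx_state(Engine& E, CxPop& p, double vbase, double jitter) {
  for (int i = 0; i < p.n; ++i) {
    double vv = vbase + jitter * (2.0 * E.unif(E.rng) - 1.0);
    p.vd[i] = vv; p.vs[i] = vv;
    p.m_nad[i] = E.T.cxna_m(vv); p.h_nad[i] = E.T.cxna_h(vv);
    p.m_nas[i] = E.T.cxna_m(vv); p.h_nas[i] = E.T.cxna_h(vv);
    p.n_ks[i] = E.T.cxk_n(vv);
    p.m_nap[i] = E.T.nap_m(vv);
    p.m_ca[i] = E.T.cxca_m(vv); p.h_ca[i] = E.T.cxca_h(vv);
    p.m_km[i] = E.T.cxkm_m(vv); p.m_kca[i] = 0.0;
    p.cai[i] = E.cafloor_cx;
    p.last_spike[i] = -1e9;
  }
}

static void seed_th_state(Engine& E, ThPop& p, double vbase, double jitter, double shift) {
  for (int i = 0; i < p.n; ++i) {
    double v = vbase + jitter * (2.0 * E.unif(E.rng) - 1.0);
    p.v[i] = v;
    p.m_na[i] = E.T.thna_m(v); p.h_na[i] = E.T.thna_h(v);
    p.n_k[i] = E.T.thk_n(v);
    if (p.is_tc) {
      p.m_it[i] = E.T.tcit_m(v); p.h_it[i] = E.T.tcit_h(v);
      p.o_h[i] = E.T.ih_hinf(v + shift);
    } else {
      p.m_it[i] = E.T.reit_m(v); p.h_it[i] = E.T.reit_h(v);
    }
    p.p1_h[i] = 0.0; p.ol_h[i] = 0.0;
    p.cai[i] = E.cafloor_th;
    p.last_spike[i] = -1e9;
  }
}

// one step for cortical cell i; gA.. in uS; returns spike flag
static inline bool step_cx_cell(Engine& E, CxPop& p, int i, double t,
                                double achpy, double gA, double gN,
                                double gGA, double i_inj_nA) {
  Tables& T = E.T;
  double vd = p.vd[i], vs = p.vs[i];
  double ext = E.extended ? achpy : 1.0;
  double i_kl = achpy * p.g_kleak * (vd - E.e_k);
  double i_cl = p.g_clleak * (vd - E.e_cl);
  double m3 = p.m_nad[i] * p.m_nad[i] * p.m_nad[i];
  double i_na = p.g_na_d * m3 * p.h_nad[i] * (vd - E.e_na);
  double i_nap = ext * p.g_nap_d * E.nap_cap * p.m_nap[i] * (vd - E.e_na);
  double i_ca = p.g_ca_d * p.m_ca[i] * p.m_ca[i] * p.h_ca[i] * (vd - E.e_ca_cx);
  double i_kca = ext * T.tadj_cx * p.g_kca_d * p.m_kca[i] * (vd - E.e_k);
  double i_km = ext * T.tadj_cx * p.g_km_d * p.m_km[i] * (vd - E.e_k);

  Probe pd = probe_v(vd);
  double isyn_nA = gA * (vd - E.e_ampa) + gN * T.mgblock.at(pd) * (vd - E.e_ampa) +
                   gGA * (vd - E.e_gaba);
  double isyn = isyn_nA * 1e-3 / p.area_d;
  double iinj = i_inj_nA * 1e-3 / p.area_d;

  // zero-capacitance soma: damped fixed-point on the current balance
  // fixed-point iteration; the map is strongly contractive (only the
  // instantaneous persistent-Na term depends on Vs), so plain iteration
  // reaches the tolerance in a few steps
  double g1 = p.g_na_s * p.m_nas[i] * p.m_nas[i] * p.m_nas[i] * p.h_nas[i];
  double g2 = p.g_k_s * p.n_ks[i];
  for (int it = 0; it < E.soma_maxit; ++it) {
    double g3 = p.g_nap_s * E.nap_cap * T.nap_m(vs);
    double vs_new = (p.gcs_s * vd + g1 * E.e_na + g2 * E.e_k + g3 * E.e_na) /
                    (p.gcs_s + g1 + g2 + g3);
    double delta = vs_new - vs;
    vs = vs_new;
    if (std::fabs(delta) < E.soma_tol) break;
  }

  double dvd = (-(i_kl + i_cl + i_na + i_nap + i_ca + i_kca + i_km) -
                p.gcs_d * (vd - vs) - isyn + iinj) / p.cm;
  double vd_new = vd + E.dt * dvd;

  double x;
  x = T.cxna_m.at(pd); p.m_nad[i] = x + (p.m_nad[i] - x) * T.cxna_em.at(pd);
  x = T.cxna_h.at(pd); p.h_nad[i] = x + (p.h_nad[i] - x) * T.cxna_eh.at(pd);
  x = T.nap_m.at(pd); p.m_nap[i] = x + (p.m_nap[i] - x) * E.nap_tau_e;
  x = T.cxca_m.at(pd); p.m_ca[i] = x + (p.m_ca[i] - x) * T.cxca_em.at(pd);
  x = T.cxca_h.at(pd); p.h_ca[i] = x + (p.h_ca[i] - x) * T.cxca_eh.at(pd);
  x = T.cxkm_m.at(pd); p.m_km[i] = x + (p.m_km[i] - x) * T.cxkm_em.at(pd);
  {
    double a = E.kca_a * p.cai[i];
    p.m_kca[i] += E.dt * T.tadj_cx * (a * (1.0 - p.m_kca[i]) - E.kca_b * p.m_kca[i]);
    if (p.m_kca[i] < 0) p.m_kca[i] = 0;
    if (p.m_kca[i] > 1) p.m_kca[i] = 1;
  }
  Probe ps = probe_v(vs);
  x = T.cxna_m.at(ps); p.m_nas[i] = x + (p.m_nas[i] - x) * T.cxna_em.at(ps);
  x = T.cxna_h.at(ps); p.h_nas[i] = x + (p.h_nas[i] - x) * T.cxna_eh.at(ps);
  x = T.cxk_n.at(ps); p.n_ks[i] = x + (p.n_ks[i] - x) * T.cxk_en.at(ps);
  {
    double influx = -E.cadrive_cx * std::min(i_ca, 0.0);
    double target = E.cafloor_cx + influx * E.catau_cx;
    p.cai[i] = target + (p.cai[i] - target) * E.e_catau_cx;
    if (p.cai[i] < 0) p.cai[i] = 0;
  }

  bool spike = false;
  if (p.vs[i] < E.spk_thresh && vs >= E.spk_thresh && t - p.last_spike[i] > E.refrac) {
    spike = true;
    p.last_spike[i] = t;
  }
  p.vd[i] = vd_new;
  p.vs[i] = vs;
  return spike;
}

// one step for thalamic cell i
static inline bool step_th_cell(Engine& E, ThPop& p, int i, double t,
                                double ach, double shift_ha,
                                double gA, double gGA, double gGB,
                                double i_inj_nA) {
  Tables& T = E.T;
  double v = p.v[i];
  double eca = E.rtf2 * std::log(E.ca_o / std::max(p.cai[i], 1e-9));
  double i_kl = ach * p.g_kleak * (v - E.e_k);
  double i_l = p.g_leak * (v - p.e_leak);
  double m3 = p.m_na[i] * p.m_na[i] * p.m_na[i];
  double i_na = p.g_na * m3 * p.h_na[i] * (v - E.e_na);
  double n2 = p.n_k[i] * p.n_k[i];
  double i_k = p.g_k * n2 * n2 * (v - E.e_k);
  double i_t = p.g_lca * p.m_it[i] * p.m_it[i] * p.h_it[i] * (v - eca);
  double i_h = 0.0;
  if (p.is_tc) i_h = p.g_h * (p.o_h[i] + E.ih_klock * p.ol_h[i]) * (v - E.e_h);

  double isyn_nA = gA * (v - E.e_ampa) + gGA * (v - E.e_gaba) + gGB * (v - E.e_k);
  double isyn = isyn_nA * 1e-3 / p.area;
  double iinj = i_inj_nA * 1e-3 / p.area;

  double dv = (-(i_kl + i_l + i_na + i_k + i_t + i_h) - isyn + iinj) / p.cm;
  double v_new = v + E.dt * dv;

  double x;
  Probe pv = probe_v(v);
  x = T.thna_m.at(pv); p.m_na[i] = x + (p.m_na[i] - x) * T.thna_em.at(pv);
  x = T.thna_h.at(pv); p.h_na[i] = x + (p.h_na[i] - x) * T.thna_eh.at(pv);
  x = T.thk_n.at(pv); p.n_k[i] = x + (p.n_k[i] - x) * T.thk_en.at(pv);
  if (p.is_tc) {
    x = T.tcit_m.at(pv); p.m_it[i] = x + (p.m_it[i] - x) * T.tcit_em.at(pv);
    x = T.tcit_h.at(pv); p.h_it[i] = x + (p.h_it[i] - x) * T.tcit_eh.at(pv);
    // calcium-gated h-current (semi-implicit exponential updates)
    double hb = T.ih_hinf(v + shift_ha);
    double invt = T.ih_invtau.at(pv);
    double alpha = hb * invt, beta = (1.0 - hb) * invt;
    double o = p.o_h[i], p1 = p.p1_h[i], ol = p.ol_h[i];
    double ca4 = p.cai[i] * p.cai[i]; ca4 *= ca4;
    double rp = E.ih_k1 * ca4 + E.ih_k2;
    double p1inf = E.ih_k1 * ca4 / rp;
    p1 = p1inf + (p1 - p1inf) * std::exp(-E.dt * rp);
    // dO/dt = alpha(1-O-OL) - beta O - k3 O P1 + k4 OL, alpha+beta = 1/tau_s
    double ro = invt + E.ih_k3 * p1;
    double otgt = (alpha * (1.0 - ol) + E.ih_k4 * ol) / ro;
    o = otgt + (o - otgt) * std::exp(-E.dt * ro);
    double src = E.ih_k3 * o * p1;
    double oltgt = src / E.ih_k4;
    ol = oltgt + (ol - oltgt) * std::exp(-E.dt * E.ih_k4);
    if (o < 0) o = 0; if (o > 1) o = 1;
    if (ol < 0) ol = 0; if (ol > 1) ol = 1;
    if (o + ol > 1) { double s = 1.0 / (o + ol); o *= s; ol *= s; }
    p.o_h[i] = o; p.p1_h[i] = p1; p.ol_h[i] = ol;
  } else {
    x = T.reit_m.at(pv); p.m_it[i] = x + (p.m_it[i] - x) * T.reit_em.at(pv);
    x = T.reit_h.at(pv); p.h_it[i] = x + (p.h_it[i] - x) * T.reit_eh.at(pv);
  }
  {
    double influx = -E.cadrive_th * std::min(i_t, 0.0);
    double target = E.cafloor_th + influx * E.catau_th;
    p.cai[i] = target + (p.cai[i] - target) * E.e_catau_th;
    if (p.cai[i] < 0) p.cai[i] = 0;
  }

  bool spike = false;
  if (v < E.spk_thresh && v_new >= E.spk_thresh && t - p.last_spike[i] > E.refrac) {
    spike = true;
    p.last_spike[i] = t;
  }
  p.v[i] = v_new;
  return spike;
}

static inline int pop_size(const Engine& E, int pop) {
  switch (pop) {
    case 0: return E.py.n;
    case 1: return E.inn.n;
    case 2: return E.tc.n;
    default: return E.re.n;
  }
}

// ------------------------------------------------------------ entry points

// [[Rcpp::export]]
List run_network_cpp(NumericVector consts_flat, List pops, List projections,
                     DataFrame mini_edges, NumericMatrix scalars, List cfg) {
  Engine E;
  E.C = make_consts(consts_flat);
  E.dt = as<double>(cfg["dt"]);
  E.T = make_tables(E.C, E.dt);
  E.cache_consts();
  E.extended = as<bool>(cfg["extended"]);
  E.rng.seed((uint64_t)as<double>(cfg["seed"]));

  init_cx(E, E.py, true, as<int>(pops["n_py"]));
  init_cx(E, E.inn, false, as<int>(pops["n_in"]));
  init_th(E, E.tc, true, as<int>(pops["n_tc"]));
  init_th(E, E.re, false, as<int>(pops["n_re"]));

  double jitter = as<double>(cfg["v_jitter"]);
  double shift0 = scalars(0, 7); // column 7 = shift_ha (column 0 is time)
  // TC cells have a stable depolarized rest near -58 mV alongside a
  // delta-oscillation basin; start them in the rest basin
  seed_cx_state(E, E.py, -68.0, jitter);
  seed_cx_state(E, E.inn, -68.0, jitter);
  seed_th_state(E, E.tc, -60.0, jitter, shift0);
  seed_th_state(E, E.re, -77.0, jitter, 0.0);

  for (int pp = 0; pp < 4; ++pp) {
    int n = pop_size(E, pp);
    E.o_ampa[pp].assign(n, 0.0);
    E.o_nmda[pp].assign(n, 0.0);
    E.o_gabaa[pp].assign(n, 0.0);
    E.pulse_end[pp].assign(n, -1.0);
    E.accA[pp].assign(n, 0.0); E.accN[pp].assign(n, 0.0);
    E.accGA[pp].assign(n, 0.0); E.accGB[pp].assign(n, 0.0);
    E.miniA[pp].assign(n, 0.0); E.miniG[pp].assign(n, 0.0);
    E.mini_by_src[pp].assign(n, std::vector<int>());
  }
  E.r_gabab.assign(E.re.n, 0.0);
  E.g_gabab.assign(E.re.n, 0.0);
  E.e_dep.assign(E.py.n, 1.0);

  // projections
  int npr = projections.size();
  E.projs.resize(npr);
  int max_src = std::max(std::max(E.py.n, E.inn.n), std::max(E.tc.n, E.re.n));
  E.prefix.assign(max_src + 1, 0.0);
  for (int p = 0; p < npr; ++p) {
    List pl = projections[p];
    Proj& pr = E.projs[p];
    pr.type = as<int>(pl["type"]);
    pr.src_pop = as<int>(pl["src_pop"]);
    pr.tgt_pop = as<int>(pl["tgt_pop"]);
    pr.l_class = as<int>(pl["l_class"]);
    pr.depression = as<bool>(pl["depression"]);
    pr.lo = as<std::vector<int>>(pl["lo"]);
    pr.hi = as<std::vector<int>>(pl["hi"]);
    pr.self_ex = as<std::vector<int>>(pl["self_ex"]);
    pr.w = as<std::vector<double>>(pl["w"]);
  }

  // mini edges
  {
    IntegerVector sp = mini_edges["src_pop"], s = mini_edges["src"],
                  tp = mini_edges["tgt_pop"], tg = mini_edges["tgt"],
                  cl = mini_edges["cls"];
    NumericVector g = mini_edges["g"];
    int nme = sp.size();
    E.minis.resize(nme);
    E.mini_t0.assign(nme, 0.0);
    for (int e = 0; e < nme; ++e) {
      E.minis[e] = MiniEdge{sp[e], s[e], tp[e], tg[e], cl[e], g[e]};
      E.mini_by_src[sp[e]][s[e]].push_back(e);
      E.mini_schedule(e, 0.0);
    }
  }

  // stimulation events
  std::vector<Stim> stims;
  {
    List sl = cfg["stim"];
    for (int i = 0; i < sl.size(); ++i) {
      List s = sl[i];
      stims.push_back(Stim{as<int>(s["pop"]), as<double>(s["amp"]),
                           as<double>(s["from"]), as<double>(s["to"])});
    }
  }

  double duration = as<double>(cfg["duration_ms"]);
  int nsteps = (int)std::round(duration / E.dt);
  int rec_stride = std::max(1, (int)std::round(as<double>(cfg["record_dt_ms"]) / E.dt));
  int nrec = nsteps / rec_stride;
  bool rec_py = as<bool>(cfg["record_py_v"]);

  NumericMatrix py_vd(rec_py ? nrec : 0, rec_py ? E.py.n : 0);
  NumericMatrix pop_mean(nrec, 4);
  NumericMatrix exemplar(nrec, 4);
  NumericMatrix scal_trace(nrec, 9);
  NumericVector rec_time(nrec);

  std::vector<double> spk_t[4];
  std::vector<int> spk_c[4];

  int nbp = scalars.nrow();
  int bp = 0;

  double sc[9];
  int exi[4] = {E.py.n / 2, E.inn.n / 2, E.tc.n / 2, E.re.n / 2};

  for (int step = 0; step < nsteps; ++step) {
    double t = step * E.dt;

    // scalar time course (piecewise-linear breakpoints)
    while (bp < nbp - 2 && t >= scalars(bp + 1, 0)) ++bp;
    {
      double t0 = scalars(bp, 0), t1 = scalars(std::min(bp + 1, nbp - 1), 0);
      double f = (t1 > t0) ? std::min(std::max((t - t0) / (t1 - t0), 0.0), 1.0) : 1.0;
      for (int j = 0; j < 9; ++j)
        sc[j] = scalars(bp, j + 1) * (1.0 - f) + scalars(std::min(bp + 1, nbp - 1), j + 1) * f;
    }
    double ach_py = sc[0], ach_tc = sc[1], ach_re = sc[2], lach = sc[3],
           lgaba_cx = sc[4], lgaba_th = sc[5], shift_ha = sc[6],
           mini_scale = sc[7], tau_scale = sc[8];
    double b_gabaa_eff = E.b_gabaa / tau_scale;

    // ---- shared synapse state updates ----
    double eA = std::exp(-E.b_ampa * E.dt), eN = std::exp(-E.b_nmda * E.dt);
    double eG = std::exp(-b_gabaa_eff * E.dt);
    double atA = E.a_ampa * E.tconc, atN = E.a_nmda * E.tconc, atG = E.a_gabaa * E.tconc;
    double eAp = std::exp(-(atA + E.b_ampa) * E.dt);
    double eNp = std::exp(-(atN + E.b_nmda) * E.dt);
    double eGp = std::exp(-(atG + b_gabaa_eff) * E.dt);
    double oiA = atA / (atA + E.b_ampa), oiN = atN / (atN + E.b_nmda);
    double oiG = atG / (atG + b_gabaa_eff);

    for (int pp = 0; pp < 4; ++pp) {
      int n = pop_size(E, pp);
      for (int i = 0; i < n; ++i) {
        bool on = t < E.pulse_end[pp][i];
        double& oa = E.o_ampa[pp][i];
        double& on_ = E.o_nmda[pp][i];
        double& og = E.o_gabaa[pp][i];
        if (on) {
          oa = oiA + (oa - oiA) * eAp;
          on_ = oiN + (on_ - oiN) * eNp;
          og = oiG + (og - oiG) * eGp;
        } else {
          oa *= eA; on_ *= eN; og *= eG;
        }
      }
    }
    // GABA-B cascade (RE sources)
    for (int i = 0; i < E.re.n; ++i) {
      double tt = (t < E.pulse_end[3][i]) ? E.tconc : 0.0;
      double r = E.r_gabab[i], g = E.g_gabab[i];
      r += E.dt * (E.gb_k1 * tt * (1.0 - r) - E.gb_k2 * r);
      g += E.dt * (E.gb_k3 * r - E.gb_k4 * g);
      if (r < 0) r = 0; if (r > 1) r = 1; if (g < 0) g = 0;
      E.r_gabab[i] = r; E.g_gabab[i] = g;
    }
    // depression recovery (PY sources)
    {
      double er = std::exp(-E.dt / E.dep_tau);
      for (int i = 0; i < E.py.n; ++i) E.e_dep[i] = 1.0 + (E.e_dep[i] - 1.0) * er;
    }

    // ---- mini events up to t ----
    while (!E.heap.empty() && E.heap.top().t <= t) {
      MiniEvent ev = E.heap.top(); E.heap.pop();
      if (ev.t0 != E.mini_t0[ev.edge]) continue; // stale (presynaptic spike since)
      const MiniEdge& me = E.minis[ev.edge];
      if (me.cls == 2) {
        E.miniG[me.tgt_pop][me.tgt] += me.g * E.jumpG * mini_scale;
      } else {
        double l = (me.cls == 0) ? lach : 1.0;
        E.miniA[me.tgt_pop][me.tgt] += me.g * E.jumpA * l;
      }
      E.mini_schedule(ev.edge, ev.t);
    }
    // mini aggregate decay
    for (int pp = 0; pp < 2; ++pp) {
      int n = pop_size(E, pp);
      for (int i = 0; i < n; ++i) { E.miniA[pp][i] *= eA; E.miniG[pp][i] *= eG; }
    }

    // ---- per-target conductance accumulation (prefix sums) ----
    for (int pp = 0; pp < 4; ++pp) {
      std::fill(E.accA[pp].begin(), E.accA[pp].end(), 0.0);
      std::fill(E.accN[pp].begin(), E.accN[pp].end(), 0.0);
      std::fill(E.accGA[pp].begin(), E.accGA[pp].end(), 0.0);
      std::fill(E.accGB[pp].begin(), E.accGB[pp].end(), 0.0);
    }
    for (auto& pr : E.projs) {
      int ns = pop_size(E, pr.src_pop);
      int nt = pop_size(E, pr.tgt_pop);
      const std::vector<double>* state;
      switch (pr.type) {
        case 0: state = &E.o_ampa[pr.src_pop]; break;
        case 1: state = &E.o_nmda[pr.src_pop]; break;
        case 2: state = &E.o_gabaa[pr.src_pop]; break;
        default: state = nullptr; break;
      }
      double L = 1.0;
      if (pr.l_class == 1) L = lach;
      else if (pr.l_class == 2) L = lgaba_cx;
      else if (pr.l_class == 3) L = lgaba_th;
      double* pf = E.prefix.data();
      if (pr.type == 3) { // GABA-B: activation from the G-protein cascade
        pf[0] = 0.0;
        for (int i = 0; i < ns; ++i) {
          double g = E.g_gabab[i];
          double g4 = g * g; g4 *= g4;
          pf[i + 1] = pf[i] + g4 / (g4 + E.gb_kd);
        }
      } else if (pr.depression) {
        pf[0] = 0.0;
        for (int i = 0; i < ns; ++i) pf[i + 1] = pf[i] + (*state)[i] * E.e_dep[i];
      } else {
        pf[0] = 0.0;
        for (int i = 0; i < ns; ++i) pf[i + 1] = pf[i] + (*state)[i];
      }
      std::vector<double>* acc;
      switch (pr.type) {
        case 0: acc = &E.accA[pr.tgt_pop]; break;
        case 1: acc = &E.accN[pr.tgt_pop]; break;
        case 2: acc = &E.accGA[pr.tgt_pop]; break;
        default: acc = &E.accGB[pr.tgt_pop]; break;
      }
      for (int j = 0; j < nt; ++j) {
        int lo = pr.lo[j], hi = pr.hi[j];
        if (lo > hi) continue;
        double s = pf[hi + 1] - pf[lo];
        if (pr.self_ex[j]) {
          if (pr.type == 3) {
            double g = E.g_gabab[j]; double g4 = g * g; g4 *= g4;
            s -= g4 / (g4 + E.gb_kd);
          } else if (pr.depression) {
            s -= (*state)[j] * E.e_dep[j];
          } else {
            s -= (*state)[j];
          }
        }
        (*acc)[j] += L * pr.w[j] * s;
      }
    }

    // ---- stimulation ----
    double inj[4] = {0, 0, 0, 0};
    for (auto& s : stims)
      if (t >= s.from && t < s.to) inj[s.pop] += s.amp;

    // ---- cell updates ----
    for (int i = 0; i < E.py.n; ++i) {
      bool spk = step_cx_cell(E, E.py, i, t, ach_py,
                              E.accA[0][i] + E.miniA[0][i], E.accN[0][i],
                              E.accGA[0][i] + E.miniG[0][i], inj[0]);
      if (spk) {
        E.pulse_end[0][i] = t + E.tpulse_ms;
        E.e_dep[i] *= (1.0 - E.dep_u);
        spk_t[0].push_back(t); spk_c[0].push_back(i);
        for (int e : E.mini_by_src[0][i]) { E.mini_t0[e] = t; E.mini_schedule(e, t); }
      }
    }
    for (int i = 0; i < E.inn.n; ++i) {
      bool spk = step_cx_cell(E, E.inn, i, t, ach_py,
                              E.accA[1][i] + E.miniA[1][i], E.accN[1][i],
                              E.accGA[1][i] + E.miniG[1][i], inj[1]);
      if (spk) {
        E.pulse_end[1][i] = t + E.tpulse_ms;
        spk_t[1].push_back(t); spk_c[1].push_back(i);
        for (int e : E.mini_by_src[1][i]) { E.mini_t0[e] = t; E.mini_schedule(e, t); }
      }
    }
    for (int i = 0; i < E.tc.n; ++i) {
      bool spk = step_th_cell(E, E.tc, i, t, ach_tc, shift_ha,
                              E.accA[2][i], E.accGA[2][i], E.accGB[2][i], inj[2]);
      if (spk) {
        E.pulse_end[2][i] = t + E.tpulse_ms;
        spk_t[2].push_back(t); spk_c[2].push_back(i);
      }
    }
    for (int i = 0; i < E.re.n; ++i) {
      bool spk = step_th_cell(E, E.re, i, t, ach_re, 0.0,
                              E.accA[3][i], E.accGA[3][i], E.accGB[3][i], inj[3]);
      if (spk) {
        E.pulse_end[3][i] = t + E.tpulse_ms;
        spk_t[3].push_back(t); spk_c[3].push_back(i);
      }
    }

    // ---- recording ----
    if ((step + 1) % rec_stride == 0) {
      int r = (step + 1) / rec_stride - 1;
      if (r >= nrec) continue;
      rec_time[r] = (t + E.dt) / 1000.0;
      double msum;
      msum = 0; for (int i = 0; i < E.py.n; ++i) { msum += E.py.vd[i]; if (rec_py) py_vd(r, i) = E.py.vd[i]; }
      pop_mean(r, 0) = msum / std::max(E.py.n, 1);
      msum = 0; for (int i = 0; i < E.inn.n; ++i) msum += E.inn.vd[i];
      pop_mean(r, 1) = msum / std::max(E.inn.n, 1);
      msum = 0; for (int i = 0; i < E.tc.n; ++i) msum += E.tc.v[i];
      pop_mean(r, 2) = msum / std::max(E.tc.n, 1);
      msum = 0; for (int i = 0; i < E.re.n; ++i) msum += E.re.v[i];
      pop_mean(r, 3) = msum / std::max(E.re.n, 1);
      exemplar(r, 0) = E.py.vs[exi[0]];
      exemplar(r, 1) = E.inn.vs[exi[1]];
      exemplar(r, 2) = E.tc.v[exi[2]];
      exemplar(r, 3) = E.re.v[exi[3]];
      for (int j = 0; j < 9; ++j) scal_trace(r, j) = sc[j];

      // invariant tracking + stability guard on recorded frames
      for (int i = 0; i < E.py.n; ++i) {
        E.gr.upd(E.py.m_nad[i]); E.gr.upd(E.py.h_nad[i]); E.gr.upd(E.py.n_ks[i]);
        E.gr.upd(E.py.m_kca[i]); E.gr.upd(E.py.m_km[i]);
        if (!std::isfinite(E.py.vd[i]) || std::fabs(E.py.vd[i]) > 150.0)
          stop("PY cell %d diverged at t = %.2f ms (Vd = %f)", i + 1, t, E.py.vd[i]);
      }
      for (int i = 0; i < E.tc.n; ++i) {
        E.gr.upd(E.tc.m_it[i]); E.gr.upd(E.tc.h_it[i]);
        E.gr.upd(E.tc.o_h[i]); E.gr.upd(E.tc.p1_h[i]); E.gr.upd(E.tc.ol_h[i]);
        if (!std::isfinite(E.tc.v[i]) || std::fabs(E.tc.v[i]) > 150.0)
          stop("TC cell %d diverged at t = %.2f ms (V = %f)", i + 1, t, E.tc.v[i]);
      }
      for (int i = 0; i < E.re.n; ++i) {
        E.gr.upd(E.re.m_it[i]); E.gr.upd(E.re.h_it[i]);
        if (!std::isfinite(E.re.v[i]) || std::fabs(E.re.v[i]) > 150.0)
          stop("RE cell %d diverged at t = %.2f ms (V = %f)", i + 1, t, E.re.v[i]);
      }
      for (int i = 0; i < E.inn.n; ++i)
        if (!std::isfinite(E.inn.vd[i]) || std::fabs(E.inn.vd[i]) > 150.0)
          stop("IN cell %d diverged at t = %.2f ms (Vd = %f)", i + 1, t, E.inn.vd[i]);
    }
  }

  auto spikes_df = [&](int pp) {
    return DataFrame::create(_["cell"] = IntegerVector(spk_c[pp].begin(), spk_c[pp].end()),
                             _["t_ms"] = NumericVector(spk_t[pp].begin(), spk_t[pp].end()));
  };

  return List::create(
    _["time_s"] = rec_time,
    _["py_vd"] = py_vd,
    _["pop_mean"] = pop_mean,
    _["exemplar"] = exemplar,
    _["scalars"] = scal_trace,
    _["spikes_py"] = spikes_df(0),
    _["spikes_in"] = spikes_df(1),
    _["spikes_tc"] = spikes_df(2),
    _["spikes_re"] = spikes_df(3),
    _["gate_min"] = E.gr.lo,
    _["gate_max"] = E.gr.hi
  );
}

// [[Rcpp::export]]
List sim_single_cell_cpp(std::string kind, NumericVector consts_flat,
                         double duration_ms, double dt, double v0,
                         double ach_scale, double shift_ha,
                         double i_inj_nA, double inj_from_ms, double inj_to_ms,
                         double record_every_ms) {
  Engine E;
  E.C = make_consts(consts_flat);
  E.dt = dt;
  E.T = make_tables(E.C, dt);
  E.cache_consts();
  E.rng.seed(1);

  bool cortical = (kind == "PY" || kind == "IN");
  if (cortical) {
    init_cx(E, E.py, kind == "PY", 1);
    seed_cx_state(E, E.py, v0, 0.0);
  } else {
    init_th(E, E.tc, kind == "TC", 1);
    seed_th_state(E, E.tc, v0, 0.0, shift_ha);
  }

  int nsteps = (int)std::round(duration_ms / dt);
  int stride = std::max(1, (int)std::round(record_every_ms / dt));
  int nrec = nsteps / stride;
  NumericVector rt(nrec), rv(nrec), rvd(nrec), rca(nrec);
  std::vector<double> spikes;
  GateRange gr;

  for (int step = 0; step < nsteps; ++step) {
    double t = step * dt;
    double inj = (t >= inj_from_ms && t < inj_to_ms) ? i_inj_nA : 0.0;
    bool spk;
    if (cortical) {
      spk = step_cx_cell(E, E.py, 0, t, ach_scale, 0.0, 0.0, 0.0, inj);
      gr.upd(E.py.m_nad[0]); gr.upd(E.py.h_nad[0]); gr.upd(E.py.m_nas[0]);
      gr.upd(E.py.h_nas[0]); gr.upd(E.py.n_ks[0]); gr.upd(E.py.m_km[0]);
      gr.upd(E.py.m_kca[0]); gr.upd(E.py.m_ca[0]); gr.upd(E.py.h_ca[0]);
    } else {
      spk = step_th_cell(E, E.tc, 0, t, ach_scale, shift_ha, 0.0, 0.0, 0.0, inj);
      gr.upd(E.tc.m_na[0]); gr.upd(E.tc.h_na[0]); gr.upd(E.tc.n_k[0]);
      gr.upd(E.tc.m_it[0]); gr.upd(E.tc.h_it[0]);
      if (E.tc.is_tc) { gr.upd(E.tc.o_h[0]); gr.upd(E.tc.p1_h[0]); gr.upd(E.tc.ol_h[0]); }
    }
    if (spk) spikes.push_back(t);
    if ((step + 1) % stride == 0) {
      int r = (step + 1) / stride - 1;
      if (r < nrec) {
        rt[r] = t + dt;
        if (cortical) {
          rv[r] = E.py.vs[0]; rvd[r] = E.py.vd[0]; rca[r] = E.py.cai[0];
        } else {
          rv[r] = E.tc.v[0]; rvd[r] = E.tc.v[0]; rca[r] = E.tc.cai[0];
        }
        if (!std::isfinite(rv[r]) || std::fabs(rvd[r]) > 150.0)
          stop("cell diverged at t = %.3f ms", t);
      }
    }
  }
  return List::create(
    _["time"] = rt, _["v"] = rv, _["vd"] = rvd, _["ca"] = rca,
    _["spikes"] = NumericVector(spikes.begin(), spikes.end()),
    _["gate_range"] = NumericVector::create(_["min"] = gr.lo, _["max"] = gr.hi)
  );
}
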