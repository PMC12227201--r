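// Simulation core: current-based LIF network with delta-jump synapses,
// per-neuron Poisson drive, calcium traces, structural plasticity of the
// E-E block (element growth/retraction, random matching of free elements)
// and multiplicative homeostatic scaling of E-E weights.
//
// Conventions (shared with the R reference implementation in R/structural.R;
// do not change one side without the other):
//  * all randomness is drawn from R's RNG via unif_rand();
//  * per-neuron synapse lists are insertion-ordered and removals are
//    swap-with-last;
//  * uniform index picks are floor(unif_rand() * n);
//  * shuffles are Fisher-Yates from the top: for i = n-1 .. 1,
//    j = floor(unif_rand() * (i+1)), swap(v[i], v[j]).

#include <Rcpp.h>
#include <vector>
#include <cmath>
#include <algorithm>

using namespace Rcpp;

// ---------------------------------------------------------------- growth rules

struct GrowthRuleC {
  int variant;               // 0 linear, 1 gaussian
  double nu, eps, eta, xi, zeta;
  void init(const List& g, double mult) {
    std::string v = as<std::string>(g["variant"]);
    variant = (v == "linear") ? 0 : 1;
    nu  = as<double>(g["nu"]) * mult;
    eps = as<double>(g["epsilon"]);
    eta = as<double>(g["eta"]);
    xi   = 0.5 * (eta + eps);
    zeta = (eps - eta) / (2.0 * std::sqrt(std::log(2.0)));
  }
};

static inline double growth_rate_c(double C, const GrowthRuleC& g) {
  if (g.variant == 0) return g.nu * (1.0 - C / g.eps);
  double x = (C - g.xi) / g.zeta;
  return g.nu * (2.0 * std::exp(-x * x) - 1.0);
}

// ---------------------------------------------------------------- synapse store

struct SynStore {
  std::vector<int> pre, post;          // pre == -1 marks a dead slot
  std::vector<double> w;
  std::vector<int> apos, dpos;         // position within pre's axon / post's dend list
  std::vector<std::vector<int> > axon, dend;  // synapse ids per excitatory neuron
  std::vector<int> freelist;
  int nlive;

  void init(int NE, const IntegerVector& p, const IntegerVector& q,
            const NumericVector& ww) {
    axon.assign(NE, std::vector<int>());
    dend.assign(NE, std::vector<int>());
    int n = p.size();
    pre.resize(n); post.resize(n); w.resize(n); apos.resize(n); dpos.resize(n);
    nlive = n;
    for (int k = 0; k < n; ++k) {
      pre[k] = p[k]; post[k] = q[k]; w[k] = ww[k];
      apos[k] = (int)axon[p[k]].size(); axon[p[k]].push_back(k);
      dpos[k] = (int)dend[q[k]].size(); dend[q[k]].push_back(k);
    }
  }

  int add(int i, int j, double ww) {
    int id;
    if (!freelist.empty()) {
      id = freelist.back(); freelist.pop_back();
      pre[id] = i; post[id] = j; w[id] = ww;
    } else {
      id = (int)pre.size();
      pre.push_back(i); post.push_back(j); w.push_back(ww);
      apos.push_back(0); dpos.push_back(0);
    }
    apos[id] = (int)axon[i].size(); axon[i].push_back(id);
    dpos[id] = (int)dend[j].size(); dend[j].push_back(id);
    ++nlive;
    return id;
  }

  void remove(int id) {
    {
      std::vector<int>& L = axon[pre[id]];
      int p0 = apos[id]; int last = L.back();
      L[p0] = last; apos[last] = p0; L.pop_back();
    }
    {
      std::vector<int>& L = dend[post[id]];
      int p0 = dpos[id]; int last = L.back();
      L[p0] = last; dpos[last] = p0; L.pop_back();
    }
    pre[id] = -1; freelist.push_back(id); --nlive;
  }
};

static inline int pick_index(int n) {
  int k = (int)(unif_rand() * n);
  if (k >= n) k = n - 1;
  return k;
}

static void shuffle_vec(std::vector<int>& v) {
  for (int i = (int)v.size() - 1; i > 0; --i) {
    int j = (int)(unif_rand() * (i + 1));
    if (j > i) j = i;
    std::swap(v[i], v[j]);
  }
}

// one structural cycle: Euler step on element counts, surplus deletion
// (axonal pass then dendritic pass), then random matching of free elements
// with a single re-draw round for autapse collisions
static void structural_cycle(SynStore& S,
                             std::vector<double>& zA, std::vector<double>& zD,
                             const std::vector<double>& Ca,
                             const GrowthRuleC& gA, const GrowthRuleC& gD,
                             double dt_s, double J_new, int NE,
                             bool do_integrate, bool do_delete, bool do_form,
                             int& n_form, int& n_del,
                             double tnow,
                             std::vector<double>* ev_t, std::vector<int>* ev_type,
                             std::vector<int>* ev_pre, std::vector<int>* ev_post) {
  if (do_integrate) {
    for (int i = 0; i < NE; ++i) {
      zA[i] = std::max(0.0, zA[i] + dt_s * growth_rate_c(Ca[i], gA));
      zD[i] = std::max(0.0, zD[i] + dt_s * growth_rate_c(Ca[i], gD));
    }
  }
  if (do_delete) {
    for (int i = 0; i < NE; ++i) {
      int surplus = (int)S.axon[i].size() - (int)std::floor(zA[i]);
      for (int s = 0; s < surplus; ++s) {
        int id = S.axon[i][pick_index((int)S.axon[i].size())];
        if (ev_t) {
          ev_t->push_back(tnow); ev_type->push_back(1);
          ev_pre->push_back(S.pre[id]); ev_post->push_back(S.post[id]);
        }
        S.remove(id); ++n_del;
      }
    }
    for (int i = 0; i < NE; ++i) {
      int surplus = (int)S.dend[i].size() - (int)std::floor(zD[i]);
      for (int s = 0; s < surplus; ++s) {
        int id = S.dend[i][pick_index((int)S.dend[i].size())];
        if (ev_t) {
          ev_t->push_back(tnow); ev_type->push_back(1);
          ev_pre->push_back(S.pre[id]); ev_post->push_back(S.post[id]);
        }
        S.remove(id); ++n_del;
      }
    }
  }
  if (do_form) {
    std::vector<int> pa, pd;
    for (int i = 0; i < NE; ++i) {
      int f = (int)std::floor(zA[i]) - (int)S.axon[i].size();
      for (int k = 0; k < f; ++k) pa.push_back(i);
    }
    for (int i = 0; i < NE; ++i) {
      int f = (int)std::floor(zD[i]) - (int)S.dend[i].size();
      for (int k = 0; k < f; ++k) pd.push_back(i);
    }
    shuffle_vec(pa); shuffle_vec(pd);
    std::vector<int> ra, rd;
    int np = (int)std::min(pa.size(), pd.size());
    for (int k = 0; k < np; ++k) {
      if (pa[k] == pd[k]) { ra.push_back(pa[k]); rd.push_back(pd[k]); continue; }
      S.add(pa[k], pd[k], J_new); ++n_form;
      if (ev_t) {
        ev_t->push_back(tnow); ev_type->push_back(0);
        ev_pre->push_back(pa[k]); ev_post->push_back(pd[k]);
      }
    }
    if (!ra.empty()) {
      shuffle_vec(ra); shuffle_vec(rd);
      for (size_t k = 0; k < ra.size(); ++k) {
        if (ra[k] == rd[k]) continue;
        S.add(ra[k], rd[k], J_new); ++n_form;
        if (ev_t) {
          ev_t->push_back(tnow); ev_type->push_back(0);
          ev_pre->push_back(ra[k]); ev_post->push_back(rd[k]);
        }
      }
    }
  }
}

// multiplicative, cell-autonomous weight scaling driven by postsynaptic calcium
static void scale_weights_c(SynStore& S, const std::vector<double>& Ca,
                            double rho, double eps, double sign,
                            double dt_s, double w_min) {
  int n = (int)S.pre.size();
  for (int id = 0; id < n; ++id) {
    if (S.pre[id] < 0) continue;
    double f = 1.0 + rho * dt_s * sign * (eps - Ca[S.post[id]]);
    if (f < 0.0) f = 0.0;
    double ww = S.w[id] * f;
    S.w[id] = (ww < w_min) ? w_min : ww;
  }
}

// flatten live synapses in ascending slot order
static void flatten_store(const SynStore& S, IntegerVector& p, IntegerVector& q,
                          NumericVector& ww) {
  p = IntegerVector(S.nlive); q = IntegerVector(S.nlive); ww = NumericVector(S.nlive);
  int k = 0;
  for (size_t id = 0; id < S.pre.size(); ++id) {
    if (S.pre[id] < 0) continue;
    p[k] = S.pre[id]; q[k] = S.post[id]; ww[k] = S.w[id]; ++k;
  }
}

// [[Rcpp::export]]
List structural_run_cpp(NumericVector zA0, NumericVector zD0,
                        IntegerVector pre0, IntegerVector post0, NumericVector w0,
                        NumericMatrix Ca, List ruleA, List ruleD,
                        double dt_s, double J_new, double nu_mult,
                        bool do_integrate, bool do_delete, bool do_form,
                        bool do_scale, double rho, double scale_eps,
                        double scale_sign, double w_min,
                        bool snapshots, bool record_events) {
  int NE = zA0.size();
  int ncyc = Ca.ncol();
  GrowthRuleC gA, gD;
  gA.init(ruleA, nu_mult); gD.init(ruleD, nu_mult);
  SynStore S;
  S.init(NE, pre0, post0, w0);
  std::vector<double> zA(zA0.begin(), zA0.end()), zD(zD0.begin(), zD0.end());
  std::vector<double> cac(NE);
  IntegerVector nf(ncyc), nd(ncyc);
  List snaps(snapshots ? ncyc : 0);
  std::vector<double> ev_t; std::vector<int> ev_type, ev_pre, ev_post;

  for (int c = 0; c < ncyc; ++c) {
    for (int i = 0; i < NE; ++i) cac[i] = Ca(i, c);
    int f = 0, d = 0;
    structural_cycle(S, zA, zD, cac, gA, gD, dt_s, J_new, NE,
                     do_integrate, do_delete, do_form, f, d, (c + 1) * dt_s,
                     record_events ? &ev_t : (std::vector<double>*)0,
                     &ev_type, &ev_pre, &ev_post);
    if (do_scale) scale_weights_c(S, cac, rho, scale_eps, scale_sign, dt_s, w_min);
    nf[c] = f; nd[c] = d;
    if (snapshots) {
      IntegerVector p, q; NumericVector ww;
      flatten_store(S, p, q, ww);
      snaps[c] = List::create(_["z_A"] = NumericVector(zA.begin(), zA.end()),
                              _["z_D"] = NumericVector(zD.begin(), zD.end()),
                              _["pre"] = p, _["post"] = q, _["w"] = ww);
    }
  }
  IntegerVector p, q; NumericVector ww;
  flatten_store(S, p, q, ww);
  return List::create(
    _["z_A"] = NumericVector(zA.begin(), zA.end()),
    _["z_D"] = NumericVector(zD.begin(), zD.end()),
    _["pre"] = p, _["post"] = q, _["w"] = ww,
    _["n_form"] = nf, _["n_del"] = nd,
    _["snapshots"] = snaps,
    _["ev_t"] = NumericVector(ev_t.begin(), ev_t.end()),
    _["ev_type"] = IntegerVector(ev_type.begin(), ev_type.end()),
    _["ev_pre"] = IntegerVector(ev_pre.begin(), ev_pre.end()),
    _["ev_post"] = IntegerVector(ev_post.begin(), ev_post.end()));
}

// ------------------------------------------------------------- Poisson sampling
// Exact inversion of the Poisson CDF through a precomputed table; the table
// spans the distribution up to cumulative mass 1 - 1e-14.
//
// The external-drive path is the hot loop of the simulation (one draw per
// neuron per 0.1 ms step), so the engine feeds the inversion from a fast
// internal xorshift128+ stream that is itself seeded from R's RNG: runs
// remain fully reproducible from set.seed() while avoiding the per-call
// overhead of unif_rand().

struct FastRng {
  uint64_t s0, s1;
  void seed_from_R() {
    s0 = ((uint64_t)(unif_rand() * 4294967296.0) << 32) |
         (uint64_t)(unif_rand() * 4294967296.0);
    s1 = ((uint64_t)(unif_rand() * 4294967296.0) << 32) |
         (uint64_t)(unif_rand() * 4294967296.0);
    if (!(s0 | s1)) s1 = 0x9E3779B97F4A7C15ULL;
  }
  inline uint64_t next() {
    uint64_t x = s0, y = s1;
    s0 = y;
    x ^= x << 23;
    s1 = x ^ y ^ (x >> 17) ^ (y >> 26);
    return s1 + y;
  }
  inline double unif() { return (next() >> 11) * (1.0 / 9007199254740992.0); }
};

struct PoisTab {
  std::vector<double> cdf;
  void init(double lam) {
    cdf.clear();
    double p = std::exp(-lam), c = p;
    int k = 0;
    cdf.push_back(c);
    while (c < 1.0 - 1e-14 && k < 400) {
      ++k;
      p *= lam / k;
      c += p;
      cdf.push_back(c);
    }
  }
  inline int draw_u(double u) const {
    int n = (int)cdf.size(), k = 0;
    while (k < n && u > cdf[k]) ++k;
    return k;
  }
  inline int draw() const { return draw_u(unif_rand()); }
};

// Walker alias table over the truncated Poisson pmf: one uniform, two table
// lookups and one comparison per draw (the engine's hot path).
struct AliasTab {
  std::vector<double> prob;
  std::vector<int> alias;
  int K;
  void init(double lam) {
    std::vector<double> p;
    double q = std::exp(-lam), c = q;
    p.push_back(q);
    int k = 0;
    while (c < 1.0 - 1e-14 && k < 400) {
      ++k;
      q *= lam / k;
      c += q;
      p.push_back(q);
    }
    K = (int)p.size();
    for (int i = 0; i < K; ++i) p[i] /= c;
    prob.assign(K, 1.0);
    alias.assign(K, 0);
    std::vector<int> small, large;
    std::vector<double> sp(K);
    for (int i = 0; i < K; ++i) {
      sp[i] = p[i] * K;
      if (sp[i] < 1.0) small.push_back(i); else large.push_back(i);
    }
    while (!small.empty() && !large.empty()) {
      int s = small.back(); small.pop_back();
      int l = large.back(); large.pop_back();
      prob[s] = sp[s]; alias[s] = l;
      sp[l] -= (1.0 - sp[s]);
      if (sp[l] < 1.0) small.push_back(l); else large.push_back(l);
    }
    // leftovers get probability 1 (already initialized)
  }
  inline int draw(FastRng& r) const {
    double u = r.unif() * K;
    int j = (int)u;
    if (j >= K) j = K - 1;
    return (u - j) < prob[j] ? j : alias[j];
  }
};

// [[Rcpp::export]]
IntegerVector rpois_inv_cpp(int n, double lambda) {
  IntegerVector out(n);
  if (lambda <= 0) return out;
  PoisTab t; t.init(lambda);
  for (int i = 0; i < n; ++i) out[i] = t.draw();
  return out;
}

// ------------------------------------------------------------------- main engine

// [[Rcpp::export]]
List run_phase_cpp(List st, List prm, List ph) {
  // model constants
  const int NE = as<int>(prm["NE"]);
  const int NI = as<int>(prm["NI"]);
  const int N = NE + NI;
  const double dt_ms = as<double>(prm["dt_ms"]);
  const double dt_s = dt_ms * 1e-3;
  const double tau_m = as<double>(prm["tau_m"]);
  const double C_mem = as<double>(prm["C_mem"]);
  const double V_rest = as<double>(prm["V_rest"]);
  const double V_reset = as<double>(prm["V_reset"]);
  const double V_th = as<double>(prm["V_th"]);
  const int ref_steps = (int)std::lround(as<double>(prm["t_ref"]) / dt_ms);
  const double tau_ca = as<double>(prm["tau_ca_s"]);
  const double beta_ca = as<double>(prm["beta_ca"]);
  const int delay_steps = std::max(1, (int)std::lround(as<double>(prm["delay_ms"]) / dt_ms));
  const double J_new = as<double>(prm["J_new"]);
  const double unit_w = as<double>(prm["unit_w"]);
  const int struct_every = (int)std::lround(as<double>(prm["struct_interval_ms"]) / dt_ms);
  const int rec_every = (int)std::lround(as<double>(prm["record_interval_s"]) * 1000.0 / dt_ms);
  IntegerVector adj_ptr = prm["adj_ptr"];
  IntegerVector adj_tgt = prm["adj_tgt"];
  NumericVector adj_w = prm["adj_w"];
  IntegerVector subv = prm["sub"];

  // phase settings
  const double duration_s = as<double>(ph["duration_s"]);
  NumericVector ext_lambda = ph["ext_lambda"];
  const double ext_w = as<double>(ph["ext_w"]);
  IntegerVector ext_group = ph["ext_group"];
  const bool has_groups = as<bool>(ph["has_groups"]);
  const double fac_I0 = as<double>(ph["fac_I0"]);
  const double fac_t_end = as<double>(ph["fac_t_end"]);
  const double fac_t0 = as<double>(ph["fac_t0"]);
  const bool struct_on = as<bool>(ph["struct_on"]);
  const double nu_mult = as<double>(ph["nu_mult"]);
  const bool scaling_on = as<bool>(ph["scaling_on"]);
  const double rho = as<double>(ph["rho"]);
  const double scale_sign = as<double>(ph["scale_sign"]);
  const double w_min = as<double>(ph["w_min"]);
  const double scale_eps = as<double>(ph["scale_eps"]);
  const bool record_spikes = as<bool>(ph["record_spikes"]);
  const bool record_events = as<bool>(ph["record_events"]);
  IntegerVector record_V_ids = ph["record_V_ids"];

  GrowthRuleC gA, gD;
  gA.init(as<List>(ph["rule_A"]), nu_mult);
  gD.init(as<List>(ph["rule_D"]), nu_mult);

  // state
  std::vector<double> V(as<NumericVector>(st["V"]).begin(),
                        as<NumericVector>(st["V"]).end());
  std::vector<int> refc(as<IntegerVector>(st["ref"]).begin(),
                        as<IntegerVector>(st["ref"]).end());
  std::vector<double> Ca(as<NumericVector>(st["Ca"]).begin(),
                         as<NumericVector>(st["Ca"]).end());
  std::vector<double> zA(as<NumericVector>(st["z_A"]).begin(),
                         as<NumericVector>(st["z_A"]).end());
  std::vector<double> zD(as<NumericVector>(st["z_D"]).begin(),
                         as<NumericVector>(st["z_D"]).end());
  const double t0 = as<double>(st["t_now_s"]);
  SynStore S;
  S.init(NE, st["syn_pre"], st["syn_post"], st["syn_w"]);

  const int n_steps = (int)std::lround(duration_s * 1000.0 / dt_ms);
  const double alpha = std::exp(-dt_ms / tau_m);
  const double one_m_alpha = 1.0 - alpha;
  const double ca_dec = std::exp(-dt_s / tau_ca);
  const double fac_gain = tau_m / C_mem;   // pA -> mV of steady-state drive

  FastRng frng;
  frng.seed_from_R();

  // Poisson tables per distinct positive lambda
  std::vector<AliasTab> tabs;
  std::vector<int> tab_idx(N, -1);
  {
    std::vector<double> lams;
    for (int i = 0; i < N; ++i) {
      double lam = ext_lambda[i];
      if (lam <= 0) continue;
      int found = -1;
      for (size_t k = 0; k < lams.size(); ++k)
        if (lams[k] == lam) { found = (int)k; break; }
      if (found < 0) { lams.push_back(lam); found = (int)lams.size() - 1; }
      tab_idx[i] = found;
    }
    tabs.resize(lams.size());
    for (size_t k = 0; k < lams.size(); ++k) tabs[k].init(lams[k]);
  }
  int n_groups = 0;
  if (has_groups) for (int i = 0; i < N; ++i) n_groups = std::max(n_groups, ext_group[i] + 1);
  std::vector<int> group_count(n_groups, 0);
  std::vector<int> group_tab(n_groups, -1);
  if (has_groups)
    for (int i = 0; i < N; ++i)
      if (ext_group[i] >= 0) group_tab[ext_group[i]] = tab_idx[i];

  // ring buffer for delayed recurrent input
  const int ringD = delay_steps + 1;
  std::vector<double> ring((size_t)ringD * N, 0.0);

  // subpopulation membership
  std::vector<char> is_sub(NE, 0);
  for (int k = 0; k < subv.size(); ++k) is_sub[subv[k]] = 1;
  const int nS = subv.size();
  const int nEn = NE - nS;   // non-sub excitatory

  // recording
  const int n_rec = n_steps / rec_every;
  NumericVector tr_t(n_rec), tr_rE(n_rec), tr_rEsd(n_rec), tr_rI(n_rec),
      tr_rIsd(n_rec), tr_rS(n_rec), tr_rSsd(n_rec), tr_rEns(n_rec),
      tr_gEE(n_rec), tr_gSS(n_rec), tr_gSE(n_rec), tr_gES(n_rec),
      tr_geEE(n_rec), tr_geSS(n_rec), tr_geSE(n_rec), tr_geES(n_rec),
      tr_nsyn(n_rec), tr_form(n_rec), tr_del(n_rec);
  std::vector<int> sc(N, 0);
  int win_form = 0, win_del = 0;
  std::vector<double> rast_t; std::vector<int> rast_id;
  std::vector<double> ev_t; std::vector<int> ev_type, ev_pre, ev_post;
  const int nV = record_V_ids.size();
  NumericMatrix Vtrace(nV > 0 ? n_steps : 0, nV);

  std::vector<int> spikes;
  spikes.reserve(256);
  int rec_i = 0;

  for (int step = 0; step < n_steps; ++step) {
    const int slot = step % ringD;
    const int dslot = (step + delay_steps) % ringD;
    const double t_in = step * dt_s;

    double fac_mV = 0.0;
    if (fac_I0 > 0.0) {
      double ts = fac_t0 + t_in;
      if (ts < fac_t_end) fac_mV = fac_I0 * (1.0 - ts / fac_t_end) * fac_gain;
    }
    const double muE = V_rest + fac_mV;
    const double muI = V_rest;

    if (has_groups)
      for (int g = 0; g < n_groups; ++g)
        group_count[g] = (group_tab[g] >= 0) ? tabs[group_tab[g]].draw(frng) : 0;

    double* rg = &ring[(size_t)slot * N];
    double* Vp = V.data();
    double* Cp = Ca.data();
    int* rp = refc.data();
    // vectorizable relaxation and calcium-decay passes (refractory neurons
    // are overwritten with V_reset in the scalar pass below)
    for (int i = 0; i < NE; ++i) Vp[i] = muE + (Vp[i] - muE) * alpha;
    for (int i = NE; i < N; ++i) Vp[i] = muI + (Vp[i] - muI) * alpha;
    for (int i = 0; i < NE; ++i) Cp[i] *= ca_dec;

    for (int i = 0; i < N; ++i) {
      if (rp[i] > 0) {
        --rp[i];
        Vp[i] = V_reset;
        rg[i] = 0.0;        // inputs during refractoriness are discarded
        continue;
      }
      double inp = rg[i];
      rg[i] = 0.0;
      if (has_groups && ext_group[i] >= 0) {
        inp += ext_w * group_count[ext_group[i]];
      } else if (tab_idx[i] >= 0) {
        int c = tabs[tab_idx[i]].draw(frng);
        if (c) inp += ext_w * c;
      }
      Vp[i] += inp;
      if (Vp[i] >= V_th) {
        Vp[i] = V_reset;
        rp[i] = ref_steps;
        ++sc[i];
        if (i < NE) Cp[i] += beta_ca;
        spikes.push_back(i);
        if (record_spikes) {
          rast_t.push_back((t0 + t_in) * 1000.0 + dt_ms);
          rast_id.push_back(i);
        }
      }
    }

    if (nV > 0)
      for (int k = 0; k < nV; ++k) Vtrace(step, k) = V[record_V_ids[k]];

    // deliver emitted spikes after the transmission delay
    if (!spikes.empty()) {
      double* rd = &ring[(size_t)dslot * N];
      for (size_t s = 0; s < spikes.size(); ++s) {
        const int i = spikes[s];
        for (int k = adj_ptr[i]; k < adj_ptr[i + 1]; ++k) rd[adj_tgt[k]] += adj_w[k];
        if (i < NE) {
          const std::vector<int>& L = S.axon[i];
          for (size_t q = 0; q < L.size(); ++q) rd[S.post[L[q]]] += S.w[L[q]];
        }
      }
      spikes.clear();
    }

    // structural / scaling boundary
    if ((struct_on || scaling_on) && (step + 1) % struct_every == 0) {
      const double dts = struct_every * dt_s;
      if (struct_on) {
        structural_cycle(S, zA, zD, Ca, gA, gD, dts, J_new, NE,
                         true, true, true, win_form, win_del,
                         t0 + t_in + dt_s,
                         record_events ? &ev_t : (std::vector<double>*)0,
                         &ev_type, &ev_pre, &ev_post);
      }
      if (scaling_on && rho != 0.0)
        scale_weights_c(S, Ca, rho, scale_eps, scale_sign, dts, w_min);
    }

    // recording boundary
    if ((step + 1) % rec_every == 0) {
      const double win_s = rec_every * dt_s;
      double sE = 0, s2E = 0, sI = 0, s2I = 0, sS = 0, s2S = 0, sEns = 0;
      for (int i = 0; i < N; ++i) {
        const double r = sc[i] / win_s;
        if (i < NE) {
          sE += r; s2E += r * r;
          if (is_sub[i]) { sS += r; s2S += r * r; } else sEns += r;
        } else { sI += r; s2I += r * r; }
        sc[i] = 0;
      }
      const double mE = sE / NE;
      const double mI = NI > 0 ? sI / NI : NA_REAL;
      tr_t[rec_i] = t0 + (step + 1) * dt_s;
      tr_rE[rec_i] = mE;
      tr_rEsd[rec_i] = NE > 1 ? std::sqrt(std::max(0.0, s2E / NE - mE * mE)) : 0.0;
      tr_rI[rec_i] = mI;
      tr_rIsd[rec_i] = NI > 1 ? std::sqrt(std::max(0.0, s2I / NI - mI * mI)) : 0.0;
      if (nS > 0) {
        const double mS = sS / nS;
        tr_rS[rec_i] = mS;
        tr_rSsd[rec_i] = std::sqrt(std::max(0.0, s2S / nS - mS * mS));
        tr_rEns[rec_i] = nEn > 0 ? sEns / nEn : NA_REAL;
      } else {
        tr_rS[rec_i] = NA_REAL; tr_rSsd[rec_i] = NA_REAL; tr_rEns[rec_i] = mE;
      }
      // block connectivity from the live store
      double cEE = 0, cSS = 0, cSE = 0, cES = 0;
      double wEE = 0, wSS = 0, wSE = 0, wES = 0;
      for (size_t id = 0; id < S.pre.size(); ++id) {
        if (S.pre[id] < 0) continue;
        cEE += 1.0; wEE += S.w[id];
        if (nS > 0) {
          const bool ps = is_sub[S.pre[id]], qs = is_sub[S.post[id]];
          if (ps && qs) { cSS += 1.0; wSS += S.w[id]; }
          else if (ps) { cSE += 1.0; wSE += S.w[id]; }
          else if (qs) { cES += 1.0; wES += S.w[id]; }
        }
      }
      const double dEE = (double)NE * (NE - 1);
      tr_gEE[rec_i] = cEE / dEE;
      tr_geEE[rec_i] = wEE / unit_w / dEE;
      if (nS > 0) {
        const double dSS = (double)nS * (nS - 1);
        const double dX = (double)nS * nEn;
        tr_gSS[rec_i] = dSS > 0 ? cSS / dSS : NA_REAL;
        tr_geSS[rec_i] = dSS > 0 ? wSS / unit_w / dSS : NA_REAL;
        tr_gSE[rec_i] = dX > 0 ? cSE / dX : NA_REAL;
        tr_geSE[rec_i] = dX > 0 ? wSE / unit_w / dX : NA_REAL;
        tr_gES[rec_i] = dX > 0 ? cES / dX : NA_REAL;
        tr_geES[rec_i] = dX > 0 ? wES / unit_w / dX : NA_REAL;
      } else {
        tr_gSS[rec_i] = NA_REAL; tr_geSS[rec_i] = NA_REAL;
        tr_gSE[rec_i] = NA_REAL; tr_geSE[rec_i] = NA_REAL;
        tr_gES[rec_i] = NA_REAL; tr_geES[rec_i] = NA_REAL;
      }
      tr_nsyn[rec_i] = S.nlive;
      tr_form[rec_i] = win_form; tr_del[rec_i] = win_del;
      win_form = 0; win_del = 0;
      ++rec_i;

      for (int i = 0; i < N; ++i)
        if (!R_finite(V[i]))
          stop("non-finite membrane potential (neuron %d at t = %.3f s)",
               i + 1, t0 + (step + 1) * dt_s);
    }
  }

  IntegerVector p, q; NumericVector ww;
  flatten_store(S, p, q, ww);
  List trace = List::create(
    _["t"] = tr_t, _["rate_E"] = tr_rE, _["rate_E_sd"] = tr_rEsd,
    _["rate_I"] = tr_rI, _["rate_I_sd"] = tr_rIsd,
    _["rate_S"] = tr_rS, _["rate_S_sd"] = tr_rSsd, _["rate_Ens"] = tr_rEns,
    _["gamma_EE"] = tr_gEE, _["gamma_SS"] = tr_gSS,
    _["gamma_SE"] = tr_gSE, _["gamma_ES"] = tr_gES,
    _["geff_EE"] = tr_geEE, _["geff_SS"] = tr_geSS,
    _["geff_SE"] = tr_geSE, _["geff_ES"] = tr_geES,
    _["n_syn"] = tr_nsyn, _["n_form"] = tr_form, _["n_del"] = tr_del);

  return List::create(
    _["V"] = NumericVector(V.begin(), V.end()),
    _["ref"] = IntegerVector(refc.begin(), refc.end()),
    _["Ca"] = NumericVector(Ca.begin(), Ca.end()),
    _["z_A"] = NumericVector(zA.begin(), zA.end()),
    _["z_D"] = NumericVector(zD.begin(), zD.end()),
    _["syn_pre"] = p, _["syn_post"] = q, _["syn_w"] = ww,
    _["t_now_s"] = t0 + n_steps * dt_s,
    _["trace"] = trace,
    _["raster_t_ms"] = NumericVector(rast_t.begin(), rast_t.end()),
    _["raster_id"] = IntegerVector(rast_id.begin(), rast_id.end()),
    _["ev_t"] = NumericVector(ev_t.begin(), ev_t.end()),
    _["ev_type"] = IntegerVector(ev_type.begin(), ev_type.end()),
    _["ev_pre"] = IntegerVector(ev_pre.begin(), ev_pre.end()),
    _["ev_post"] = IntegerVector(ev_post.begin(), ev_post.end()),
    _["V_trace"] = Vtrace);
}
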