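// Multicompartment cable integrator.
//
// Crank-Nicolson on voltage with an exact O(n) Hines solve of the
// tree-structured linear system; gating states advanced by exact
// exponential relaxation at the midpoint voltage (staggered, NEURON-style);
// calcium pool advanced implicitly. Nonlinear exchanger current is treated
// as a constant source over each step (its conductance is orders of
// magnitude below the channel conductances).
//
// Units: mV, ms, mM, um; density conductance S/cm2; density current
// mA/cm2; absolute conductance uS; absolute current nA; capacitance nF.

#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

static const double FARADAY = 96485.33212;   // C/mol
static const double GASCONST = 8.314462618;  // J/(mol K)

// ---- gate kinetics (reduced HH complement) --------------------------------

static inline double vtrap(double x, double y) {
  // x/(1-exp(-x/y)) with the removable singularity handled
  if (std::fabs(x / y) < 1e-6) return y + 0.5 * x;
  return x / (1.0 - std::exp(-x / y));
}

struct GateLU { double inf, tau; };

static inline GateLU na_m(double v) {
  double a = 0.1 * vtrap(v + 40.0, 10.0);
  double b = 4.0 * std::exp(-(v + 65.0) / 18.0);
  GateLU g; g.tau = 1.0 / (a + b); g.inf = a * g.tau; return g;
}
static inline GateLU na_h(double v) {
  double a = 0.07 * std::exp(-(v + 65.0) / 20.0);
  double b = 1.0 / (1.0 + std::exp(-(v + 35.0) / 10.0));
  GateLU g; g.tau = 1.0 / (a + b); g.inf = a * g.tau; return g;
}
static inline GateLU kdr_n(double v) {
  double a = 0.01 * vtrap(v + 55.0, 10.0);
  double b = 0.125 * std::exp(-(v + 65.0) / 80.0);
  GateLU g; g.tau = 1.0 / (a + b); g.inf = a * g.tau; return g;
}
static inline GateLU ka_a(double v) {
  GateLU g; g.inf = 1.0 / (1.0 + std::exp(-(v + 30.0) / 15.0)); g.tau = 1.0; return g;
}
static inline GateLU ka_b(double v) {
  GateLU g; g.inf = 1.0 / (1.0 + std::exp((v + 70.0) / 6.0)); g.tau = 15.0; return g;
}
static inline GateLU cal_m(double v) {
  GateLU g; g.inf = 1.0 / (1.0 + std::exp(-(v + 15.0) / 6.0)); g.tau = 1.5; return g;
}

// ---- NCX (electrochemical x allosteric) -----------------------------------

struct NCXPars {
  double gamma, ksat, km_na, km_ca, km_ca_act, n_hill;
  double na_i, na_o, ca_o, tempK;
};

static inline double ncx_delta_e_c(double v, double ca_i, double vmax,
                                   const NCXPars& p) {
  double vfrt = v * 1e-3 * FARADAY / (GASCONST * p.tempK);
  double na_i3 = p.na_i * p.na_i * p.na_i;
  double na_o3 = p.na_o * p.na_o * p.na_o;
  double num = na_i3 * p.ca_o * std::exp(p.gamma * vfrt)
             - na_o3 * ca_i * std::exp((p.gamma - 1.0) * vfrt);
  double den = (p.km_na * p.km_na * p.km_na + na_o3) * (p.km_ca + p.ca_o)
             * (1.0 + p.ksat * std::exp((p.gamma - 1.0) * vfrt));
  return vmax * num / den;   // mA/cm2, outward positive (reverse mode)
}

static inline double ncx_allo_c(double ca_i, double km_ca_act, double n_hill,
                                double scale) {
  double a = 1.0 / (1.0 + std::pow(km_ca_act / ca_i, n_hill));
  a *= scale;
  return a > 1.0 ? 1.0 : a;
}

// ---- exported single-point evaluators (parity oracles for the R layer) ----

// [[Rcpp::export(name = ".engine_gate_rates")]]
List engine_gate_rates(double v) {
  GateLU m = na_m(v), h = na_h(v), n = kdr_n(v), a = ka_a(v), b = ka_b(v),
         cl = cal_m(v);
  return List::create(
    _["na_m_inf"] = m.inf, _["na_m_tau"] = m.tau,
    _["na_h_inf"] = h.inf, _["na_h_tau"] = h.tau,
    _["kdr_n_inf"] = n.inf, _["kdr_n_tau"] = n.tau,
    _["ka_a_inf"] = a.inf, _["ka_a_tau"] = a.tau,
    _["ka_b_inf"] = b.inf, _["ka_b_tau"] = b.tau,
    _["cal_m_inf"] = cl.inf, _["cal_m_tau"] = cl.tau);
}

// [[Rcpp::export(name = ".engine_ncx_eval")]]
List engine_ncx_eval(double v, double ca_i, double vmax, double allo_scale,
                     List pars) {
  NCXPars p;
  p.gamma = pars["gamma"]; p.ksat = pars["ksat"];
  p.km_na = pars["km_na"]; p.km_ca = pars["km_ca"];
  p.km_ca_act = pars["km_ca_act"]; p.n_hill = pars["n_hill"];
  p.na_i = pars["na_i"]; p.na_o = pars["na_o"]; p.ca_o = pars["ca_o"];
  p.tempK = pars["temperature_K"];
  double de = ncx_delta_e_c(v, ca_i, vmax, p);
  double allo = ncx_allo_c(ca_i, p.km_ca_act, p.n_hill, allo_scale);
  double phi = allo * de;
  return List::create(_["delta_e"] = de, _["allo"] = allo,
                      _["i_total"] = phi, _["i_ca"] = -2.0 * phi,
                      _["i_na"] = 3.0 * phi);
}

// ---- Hines solve ----------------------------------------------------------

// Solves the symmetric tree system: A[i][i] = d[i], A[i][parent[i]] =
// A[parent[i]][i] = off[i]. parent[i] < i (Hines order), parent = -1 at root.
// [[Rcpp::export(name = ".hines_solve_cpp")]]
NumericVector hines_solve_cpp(IntegerVector parent, NumericVector d,
                              NumericVector off, NumericVector rhs) {
  int n = d.size();
  NumericVector dd = clone(d), b = clone(rhs), x(n);
  for (int i = n - 1; i > 0; --i) {           // eliminate leaves upward
    int p = parent[i];
    if (p < 0) continue;
    if (dd[i] == 0.0) stop("numerical error: singular diagonal in tree solve");
    double f = off[i] / dd[i];
    dd[p] -= f * off[i];
    b[p] -= f * b[i];
  }
  if (dd[0] == 0.0) stop("numerical error: singular diagonal in tree solve");
  x[0] = b[0] / dd[0];
  for (int i = 1; i < n; ++i) {
    int p = parent[i];
    x[i] = (p < 0) ? b[i] / dd[i] : (b[i] - off[i] * x[p]) / dd[i];
  }
  return x;
}

// ---- the integrator -------------------------------------------------------

// [[Rcpp::export(name = ".run_engine_cpp")]]
List run_engine_cpp(List grid, List dens, List pars, List syns, List events,
                    List iclamps, List rec, double dt, double tstop,
                    double t0, double v_init, Nullable<List> init_state,
                    int sample_every) {
  IntegerVector parent = grid["parent"];      // -1 root, Hines order
  NumericVector area = grid["area_cm2"];
  NumericVector g_ax = grid["g_axial_uS"];    // to parent; root entry unused
  int n = parent.size();

  NumericVector g_pas = dens["g_pas"], e_pas = dens["e_pas"],
                gna = dens["gna"], gkdr = dens["gkdr"], gka = dens["gka"],
                gcal = dens["gcal"], gkca = dens["gkca"],
                ncx_vmax = dens["ncx_vmax"],
                ncx_scale = dens["ncx_alloscale"];
  NumericVector cm_v = pars["cm"];            // uF/cm2 per compartment

  double ena = pars["ena"], ek = pars["ek"], eca = pars["eca"];
  NCXPars np;
  List ncxp = pars["ncx"];
  np.gamma = ncxp["gamma"]; np.ksat = ncxp["ksat"];
  np.km_na = ncxp["km_na"]; np.km_ca = ncxp["km_ca"];
  np.km_ca_act = ncxp["km_ca_act"]; np.n_hill = ncxp["n_hill"];
  np.na_i = ncxp["na_i"]; np.na_o = ncxp["na_o"]; np.ca_o = ncxp["ca_o"];
  np.tempK = ncxp["temperature_K"];
  List kcap = pars["kca"];
  double kca_alpha = kcap["alpha"], kca_beta = kcap["beta"],
         kca_n = kcap["n"], kca_taumin = kcap["tau_min"];
  List poolp = pars["capool"];
  double pool_depth = poolp["shell_depth_um"], pool_tau = poolp["tau_decay_ms"],
         ca_rest = poolp["ca_rest"], ca_min = poolp["ca_min"];
  double pool_fac = 1.0 / (2.0 * FARADAY * pool_depth * 1e-4); // mA/cm2 -> mM/ms

  // synapses
  IntegerVector syn_comp = syns["comp"], syn_kind = syns["kind"];
  NumericVector syn_tau1 = syns["tau1"], syn_tau2 = syns["tau2"],
                syn_e = syns["e"], syn_w = syns["weight"];
  int nsyn = syn_comp.size();
  std::vector<double> syn_decay1(nsyn), syn_decay2(nsyn), syn_factor(nsyn);
  for (int s = 0; s < nsyn; ++s) {
    syn_decay1[s] = std::exp(-dt / syn_tau1[s]);
    syn_decay2[s] = std::exp(-dt / syn_tau2[s]);
    if (syn_kind[s] == 2) {
      double tp = syn_tau1[s] * syn_tau2[s] / (syn_tau2[s] - syn_tau1[s])
                * std::log(syn_tau2[s] / syn_tau1[s]);
      syn_factor[s] = 1.0 / (-std::exp(-tp / syn_tau1[s])
                             + std::exp(-tp / syn_tau2[s]));
    } else syn_factor[s] = 1.0;
  }
  IntegerVector ev_syn = events["syn"];
  NumericVector ev_t = events["time"];
  int nev = ev_syn.size(), ev_ptr = 0;

  IntegerVector ic_comp = iclamps["comp"];
  NumericVector ic_amp = iclamps["amp"], ic_start = iclamps["start"],
                ic_dur = iclamps["dur"];
  int nic = ic_comp.size();

  // state
  std::vector<double> v(n, v_init), ca(n, ca_rest);
  std::vector<double> m(n), h(n), ng(n), kaa(n), kab(n), clm(n), kcam(n);
  std::vector<double> syn_a(nsyn, 0.0), syn_b(nsyn, 0.0);
  for (int i = 0; i < n; ++i) {
    m[i] = na_m(v_init).inf; h[i] = na_h(v_init).inf;
    ng[i] = kdr_n(v_init).inf; kaa[i] = ka_a(v_init).inf;
    kab[i] = ka_b(v_init).inf; clm[i] = cal_m(v_init).inf;
    double ac = kca_alpha * std::pow(ca_rest, kca_n);
    kcam[i] = ac / (ac + kca_beta);
  }
  if (init_state.isNotNull()) {
    List st(init_state);
    NumericVector sv = st["v"], sca = st["ca"], sm = st["m"], sh = st["h"],
                  sn = st["n"], sa = st["ka_a"], sb = st["ka_b"],
                  scl = st["cal_m"], sk = st["kca_m"];
    for (int i = 0; i < n; ++i) {
      v[i] = sv[i]; ca[i] = sca[i]; m[i] = sm[i]; h[i] = sh[i]; ng[i] = sn[i];
      kaa[i] = sa[i]; kab[i] = sb[i]; clm[i] = scl[i]; kcam[i] = sk[i];
    }
    if (st.containsElementNamed("syn_a") && nsyn > 0) {
      NumericVector sA = st["syn_a"], sB = st["syn_b"];
      for (int s = 0; s < nsyn; ++s) { syn_a[s] = sA[s]; syn_b[s] = sB[s]; }
    }
  }

  // per-compartment unit conversions
  std::vector<double> cm_nF(n), a6(n);
  for (int i = 0; i < n; ++i) { a6[i] = area[i] * 1e6; cm_nF[i] = cm_v[i] * area[i] * 1e3; }

  int n_steps = (int)std::llround((tstop - t0) / dt);
  int n_samp = n_steps / sample_every + 1;

  // recordings
  IntegerVector rec_comps = rec["comps"];
  CharacterVector rec_vars = rec["vars"];
  int nrc = rec_comps.size(), nrv = rec_vars.size();
  std::vector<NumericMatrix> out_mats;
  std::vector<std::string> var_names;
  for (int k = 0; k < nrv; ++k) {
    out_mats.push_back(NumericMatrix(n_samp, nrc));
    var_names.push_back(as<std::string>(rec_vars[k]));
  }
  NumericVector out_t(n_samp);

  // scratch per-step density currents needed for recordings
  std::vector<double> cur_ikca(n), cur_ik(n), cur_ina(n), cur_ica(n),
                      cur_incx(n), cur_incx_ca(n), cur_incx_na(n), cur_ical(n);

  std::vector<double> diag(n), off(n), rhs(n), vmid(n);
  double max_dv = 0.0;

  auto record_row = [&](int row, double tnow) {
    out_t[row] = tnow;
    for (int k = 0; k < nrv; ++k) {
      for (int c = 0; c < nrc; ++c) {
        int i = rec_comps[c];
        double val = NA_REAL;
        const std::string& nm = var_names[k];
        if (nm == "v") val = v[i];
        else if (nm == "ca") val = ca[i];
        else if (nm == "i_ncx") val = cur_incx[i];
        else if (nm == "i_ncx_ca") val = cur_incx_ca[i];
        else if (nm == "i_ncx_na") val = cur_incx_na[i];
        else if (nm == "i_kca") val = cur_ikca[i];
        else if (nm == "i_k_total") val = cur_ik[i];
        else if (nm == "i_na_total") val = cur_ina[i];
        else if (nm == "i_cal") val = cur_ical[i];
        else if (nm == "i_ca_total") val = cur_ica[i];
        out_mats[k](row, c) = val;
      }
    }
  };

  // initial currents for the t0 sample
  for (int i = 0; i < n; ++i) {
    double phi = ncx_allo_c(ca[i], np.km_ca_act, np.n_hill, ncx_scale[i])
               * ncx_delta_e_c(v[i], ca[i], ncx_vmax[i], np);
    cur_incx[i] = phi; cur_incx_ca[i] = -2.0 * phi; cur_incx_na[i] = 3.0 * phi;
    cur_ikca[i] = gkca[i] * kcam[i] * kcam[i] * (v[i] - ek);
    cur_ik[i] = cur_ikca[i] + gkdr[i] * std::pow(ng[i], 4) * (v[i] - ek)
              + gka[i] * kaa[i] * kab[i] * (v[i] - ek);
    cur_ina[i] = gna[i] * m[i] * m[i] * m[i] * h[i] * (v[i] - ena);
    cur_ical[i] = gcal[i] * clm[i] * clm[i] * (v[i] - eca);
    cur_ica[i] = cur_ical[i] + cur_incx_ca[i];
  }
  record_row(0, t0);
  int samp_row = 1;

  for (int step = 0; step < n_steps; ++step) {
    double tnow = t0 + step * dt;
    double tmid = tnow + 0.5 * dt;

    // deliver events falling in [tnow, tnow+dt)
    while (ev_ptr < nev && ev_t[ev_ptr] < tnow + dt) {
      int s = ev_syn[ev_ptr];
      if (syn_kind[s] == 1) syn_b[s] += syn_w[s];
      else { syn_a[s] += syn_w[s] * syn_factor[s]; syn_b[s] += syn_w[s] * syn_factor[s]; }
      ++ev_ptr;
    }

    // assemble CN system
    for (int i = 0; i < n; ++i) {
      double G = 0.0, B = 0.0;   // uS, nA

      double g;
      g = g_pas[i] * a6[i];                       G += g; B += g * e_pas[i];
      g = gna[i] * m[i] * m[i] * m[i] * h[i] * a6[i];   G += g; B += g * ena;
      g = gkdr[i] * std::pow(ng[i], 4) * a6[i];   G += g; B += g * ek;
      g = gka[i] * kaa[i] * kab[i] * a6[i];       G += g; B += g * ek;
      g = gcal[i] * clm[i] * clm[i] * a6[i];      G += g; B += g * eca;
      g = gkca[i] * kcam[i] * kcam[i] * a6[i];    G += g; B += g * ek;

      double phi = ncx_allo_c(ca[i], np.km_ca_act, np.n_hill, ncx_scale[i])
                 * ncx_delta_e_c(v[i], ca[i], ncx_vmax[i], np);
      B -= phi * a6[i];                           // constant source this step
      cur_incx[i] = phi; cur_incx_ca[i] = -2.0 * phi; cur_incx_na[i] = 3.0 * phi;

      diag[i] = cm_nF[i] / dt + 0.5 * G;
      rhs[i] = (cm_nF[i] / dt - 0.5 * G) * v[i] + B;
    }
    for (int s = 0; s < nsyn; ++s) {
      double gs = (syn_kind[s] == 1) ? syn_b[s] : (syn_b[s] - syn_a[s]);
      if (gs <= 0.0) continue;
      int i = syn_comp[s];
      diag[i] += 0.5 * gs;
      rhs[i] += gs * syn_e[s] - 0.5 * gs * v[i];
    }
    for (int c = 0; c < nic; ++c) {
      if (tmid >= ic_start[c] && tmid < ic_start[c] + ic_dur[c]) {
        rhs[ic_comp[c]] += ic_amp[c];
      }
    }
    for (int i = 1; i < n; ++i) {
      int p = parent[i];
      if (p < 0) continue;
      diag[i] += 0.5 * g_ax[i];
      diag[p] += 0.5 * g_ax[i];
      off[i] = -0.5 * g_ax[i];
      double ax0 = g_ax[i] * (v[p] - v[i]);      // explicit half
      rhs[i] += 0.5 * ax0;
      rhs[p] -= 0.5 * ax0;
    }

    NumericVector vn = hines_solve_cpp(parent, NumericVector(diag.begin(), diag.end()),
                                       NumericVector(off.begin(), off.end()),
                                       NumericVector(rhs.begin(), rhs.end()));
    for (int i = 0; i < n; ++i) {
      if (!std::isfinite(vn[i])) {
        stop("divergence error: non-finite voltage at compartment %d, t = %g ms",
             i + 1, tnow + dt);
      }
      vmid[i] = 0.5 * (v[i] + vn[i]);
      double dvi = std::fabs(vn[i] - v[i]);
      if (dvi > max_dv) max_dv = dvi;
      v[i] = vn[i];
    }

    // gates at the midpoint voltage, exact exponential relaxation
    for (int i = 0; i < n; ++i) {
      GateLU gm = na_m(vmid[i]);  m[i]   += (1.0 - std::exp(-dt / gm.tau)) * (gm.inf - m[i]);
      GateLU gh = na_h(vmid[i]);  h[i]   += (1.0 - std::exp(-dt / gh.tau)) * (gh.inf - h[i]);
      GateLU gn = kdr_n(vmid[i]); ng[i]  += (1.0 - std::exp(-dt / gn.tau)) * (gn.inf - ng[i]);
      GateLU ga = ka_a(vmid[i]);  kaa[i] += (1.0 - std::exp(-dt / ga.tau)) * (ga.inf - kaa[i]);
      GateLU gb = ka_b(vmid[i]);  kab[i] += (1.0 - std::exp(-dt / gb.tau)) * (gb.inf - kab[i]);
      GateLU gc = cal_m(vmid[i]); clm[i] += (1.0 - std::exp(-dt / gc.tau)) * (gc.inf - clm[i]);
    }

    // calcium pool (implicit decay, channel + exchanger sources)
    for (int i = 0; i < n; ++i) {
      cur_ical[i] = gcal[i] * clm[i] * clm[i] * (v[i] - eca);
      cur_ica[i] = cur_ical[i] + cur_incx_ca[i];
      double canew = (ca[i] + dt * (-cur_ica[i] * pool_fac + ca_rest / pool_tau))
                   / (1.0 + dt / pool_tau);
      ca[i] = canew < ca_min ? ca_min : canew;
    }

    // K[Ca] activation from the updated calcium
    for (int i = 0; i < n; ++i) {
      double acn = kca_alpha * std::pow(ca[i], kca_n);
      double minf = acn / (acn + kca_beta);
      double tau = 1.0 / (acn + kca_beta);
      if (tau < kca_taumin) tau = kca_taumin;
      kcam[i] += (1.0 - std::exp(-dt / tau)) * (minf - kcam[i]);
      cur_ikca[i] = gkca[i] * kcam[i] * kcam[i] * (v[i] - ek);
      cur_ik[i] = cur_ikca[i] + gkdr[i] * std::pow(ng[i], 4) * (v[i] - ek)
                + gka[i] * kaa[i] * kab[i] * (v[i] - ek);
      cur_ina[i] = gna[i] * m[i] * m[i] * m[i] * h[i] * (v[i] - ena);
    }

    // synaptic conductance decay
    for (int s = 0; s < nsyn; ++s) {
      syn_a[s] *= syn_decay1[s];
      syn_b[s] *= (syn_kind[s] == 1) ? syn_decay1[s] : syn_decay2[s];
    }

    if ((step + 1) % sample_every == 0) {
      record_row(samp_row, tnow + dt);
      ++samp_row;
    }
  }

  List mats(nrv);
  CharacterVector mat_names(nrv);
  for (int k = 0; k < nrv; ++k) {
    mats[k] = out_mats[k];
    mat_names[k] = var_names[k];
  }
  mats.attr("names") = mat_names;

  List fin = List::create(
    _["v"] = NumericVector(v.begin(), v.end()),
    _["ca"] = NumericVector(ca.begin(), ca.end()),
    _["m"] = NumericVector(m.begin(), m.end()),
    _["h"] = NumericVector(h.begin(), h.end()),
    _["n"] = NumericVector(ng.begin(), ng.end()),
    _["ka_a"] = NumericVector(kaa.begin(), kaa.end()),
    _["ka_b"] = NumericVector(kab.begin(), kab.end()),
    _["cal_m"] = NumericVector(clm.begin(), clm.end()),
    _["kca_m"] = NumericVector(kcam.begin(), kcam.end()),
    _["syn_a"] = NumericVector(syn_a.begin(), syn_a.end()),
    _["syn_b"] = NumericVector(syn_b.begin(), syn_b.end()));

  return List::create(_["t"] = out_t, _["traces"] = mats,
                      _["final_state"] = fin,
                      _["stats"] = List::create(_["n_steps"] = n_steps,
                                                _["max_dv_per_step"] = max_dv));
}
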