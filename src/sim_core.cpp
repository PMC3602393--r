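// Compartmental Hodgkin-Huxley network integrator.
//
// Exponential-Euler update per compartment with neighbour voltages frozen
// within a step; voltage-gated rate functions are tabulated on a 0.05 mV
// grid over [-120, 60] mV (lookup, no interpolation: the grid error is far
// below the integrator error at dt = 0.025 ms).
//
// Synapses are aggregated per (postsynaptic compartment, kinetic class):
// each aggregate keeps two exponential states A (tau1) and B (tau2) so that
// g(t) = B - A superposes events exactly (dual-exponential kinetics are
// linear in the event history). NMDA aggregates are additionally multiplied
// by the Jahr-Stevens magnesium-block factor of the instantaneous
// postsynaptic voltage.
//
// Units: mV, ms, mS, uF, uA (g * V -> uA; uA / uF -> mV/ms).

#include <Rcpp.h>
#include <cmath>
#include <vector>
using namespace Rcpp;

static const double VMIN = -120.0, VMAX = 60.0, DV = 0.05;
static const int NT = 3601;
static const int NGATE_V = 7; // m h s n a b c (q is calcium-gated, analytic)

// x/(exp(x/y)-1) with the removable singularity at x = 0.
static inline double vtrap(double x, double y) {
  if (std::fabs(x) < 1e-7) return y * (1.0 - x / (2.0 * y));
  return x / std::expm1(x / y);
}

// Traub-lineage CA3 rate functions; u is membrane potential relative to
// rest (u = V + 60 for a -60 mV resting potential). Units 1/ms.
static void rate_ab(int gate, double u, double &a, double &b) {
  switch (gate) {
  case 0: // Na activation m
    a = 0.32 * vtrap(13.1 - u, 4.0);
    b = 0.28 * vtrap(u - 40.1, 5.0);
    break;
  case 1: // Na inactivation h
    a = 0.128 * std::exp((17.0 - u) / 18.0);
    b = 4.0 / (1.0 + std::exp((40.0 - u) / 5.0));
    break;
  case 2: // Ca activation s
    a = 1.6 / (1.0 + std::exp(-0.072 * (u - 65.0)));
    b = 0.02 * vtrap(u - 51.1, 5.0);
    break;
  case 3: // K delayed rectifier n
    a = 0.016 * vtrap(35.1 - u, 5.0);
    b = 0.25 * std::exp((20.0 - u) / 40.0);
    break;
  case 4: // K-A activation a
    a = 0.02 * vtrap(13.1 - u, 10.0);
    b = 0.0175 * vtrap(u - 40.1, 10.0);
    break;
  case 5: // K-A inactivation b
    a = 0.0016 * std::exp((-13.0 - u) / 18.0);
    b = 0.05 / (1.0 + std::exp((10.1 - u) / 5.0));
    break;
  case 6: // K-C voltage gate c
    if (u <= 50.0) {
      a = std::exp((u - 10.0) / 11.0 - (u - 6.5) / 27.0) / 18.975;
      b = 2.0 * std::exp((6.5 - u) / 27.0) - a;
    } else {
      a = 2.0 * std::exp((6.5 - u) / 27.0);
      b = 0.0;
    }
    break;
  default:
    stop("unknown gate index");
  }
  if (a < 0) a = 0;
  if (b < 0) b = 0;
}

struct GateTable {
  std::vector<double> xinf, dfac; // steady state, exp(-dt*(a+b))
};

static void build_tables(double dt, std::vector<GateTable> &tabs) {
  tabs.resize(NGATE_V);
  for (int g = 0; g < NGATE_V; ++g) {
    tabs[g].xinf.resize(NT);
    tabs[g].dfac.resize(NT);
    for (int i = 0; i < NT; ++i) {
      double v = VMIN + i * DV;
      double a, b;
      rate_ab(g, v + 60.0, a, b);
      double s = a + b;
      tabs[g].xinf[i] = s > 0 ? a / s : 0.0;
      tabs[g].dfac[i] = std::exp(-dt * s);
    }
  }
}

static inline int vindex(double v) {
  int i = (int)((v - VMIN) / DV + 0.5);
  if (i < 0) i = 0;
  if (i >= NT) i = NT - 1;
  return i;
}

static List sim_core(List net, List opts) {
  // --- compartments ---
  IntegerVector parent = net["parent"];       // 0-based, -1 = root
  NumericVector g_ax = net["g_ax"];           // mS, to parent
  NumericVector cm = net["cm"];               // uF
  NumericVector g_leak = net["g_leak"];       // mS
  NumericVector e_leak = net["e_leak"];       // mV
  NumericMatrix gchan = net["gchan"];         // ncomp x 6: Na Ca KDR KA KAHP KC
  NumericVector ca_phi = net["ca_phi"];
  NumericVector ca_tau = net["ca_tau"];
  IntegerVector soma = net["soma"];           // per cell, comp index
  const int ncomp = parent.size(), ncell = soma.size();

  double e_na = as<double>(net["e_na"]);
  double e_ca = as<double>(net["e_ca"]);
  double e_k = as<double>(net["e_k"]);

  // --- synaptic aggregates ---
  IntegerVector st_comp = net["st_comp"];
  NumericVector st_e = net["st_e"], st_tau1 = net["st_tau1"], st_tau2 = net["st_tau2"];
  IntegerVector st_nmda = net["st_nmda"], st_eeg = net["st_eeg"];
  const int nst = st_comp.size();

  // outgoing synapse lists (CSR over cells)
  IntegerVector out_ptr = net["out_ptr"];
  IntegerVector out_state = net["out_state"], out_delay = net["out_delay"];
  NumericVector out_amt = net["out_amt"];

  // external events (drive volleys)
  IntegerVector ev_state = net["ev_state"], ev_step = net["ev_step"];
  NumericVector ev_amt = net["ev_amt"];

  // current injections: constant steps
  IntegerVector inj_comp = net["inj_comp"], inj_on = net["inj_on"], inj_off = net["inj_off"];
  NumericVector inj_amp = net["inj_amp"];

  // --- options ---
  const double dt = as<double>(opts["dt"]);
  const int n_steps = as<int>(opts["n_steps"]);
  const double thresh = as<double>(opts["spike_threshold"]);
  const double refrac = as<double>(opts["refractory_ms"]);
  const double mg = as<double>(opts["mg_mM"]);
  IntegerVector rec_comps = opts["record_comps"];
  const int rec_every = as<int>(opts["record_every"]);
  const bool want_eeg = as<bool>(opts["eeg"]);
  const double t0 = as<double>(opts["t_start"]);

  if (dt <= 0) stop("dt must be positive");
  if (n_steps < 1) stop("n_steps must be >= 1");

  // --- state ---
  NumericVector v(ncomp);
  NumericMatrix gates(ncomp, 8); // m h s n a b c q
  NumericVector chi(ncomp);
  NumericVector stA(nst), stB(nst);
  NumericVector tlast(ncell);

  std::vector<GateTable> tabs;
  build_tables(dt, tabs);

  List init = opts["init_state"];
  if (init.size() > 0) {
    v = clone(as<NumericVector>(init["v"]));
    gates = clone(as<NumericMatrix>(init["gates"]));
    chi = clone(as<NumericVector>(init["chi"]));
    if (init.containsElementNamed("syn_a")) {
      stA = clone(as<NumericVector>(init["syn_a"]));
      stB = clone(as<NumericVector>(init["syn_b"]));
    }
    tlast = clone(as<NumericVector>(init["t_last_spike"]));
  } else {
    double v0 = as<double>(opts["v_init"]);
    for (int i = 0; i < ncomp; ++i) {
      v[i] = v0;
      int iv = vindex(v0);
      for (int g = 0; g < NGATE_V; ++g) gates(i, g) = tabs[g].xinf[iv];
      gates(i, 7) = 0.0; // q
      chi[i] = 0.0;
    }
    std::fill(tlast.begin(), tlast.end(), -1e9);
  }

  // precompute per-state decay factors and axial bookkeeping
  std::vector<double> dA(nst), dB(nst);
  for (int s = 0; s < nst; ++s) {
    if (st_tau2[s] <= st_tau1[s]) stop("synaptic tau2 must exceed tau1");
    dA[s] = std::exp(-dt / st_tau1[s]);
    dB[s] = std::exp(-dt / st_tau2[s]);
  }

  // event buckets by step
  std::vector<std::vector<std::pair<int, double> > > bucket(n_steps);
  for (int e = 0; e < ev_state.size(); ++e) {
    int stp = ev_step[e];
    if (stp >= 0 && stp < n_steps)
      bucket[stp].push_back(std::make_pair(ev_state[e], ev_amt[e]));
  }

  const int nrec = rec_comps.size();
  const int nrow_rec = (n_steps + rec_every - 1) / rec_every;
  NumericMatrix vtrace(nrec > 0 ? nrow_rec : 0, nrec);
  NumericVector eeg(want_eeg ? n_steps : 0);

  std::vector<double> gsyn(ncomp), gesyn(ncomp), sax(ncomp), iinj(ncomp);
  std::vector<double> vnew(ncomp);

  // total axial conductance touching each compartment (constant in time)
  std::vector<double> gax_sum(ncomp, 0.0);
  for (int i = 0; i < ncomp; ++i) {
    int p = parent[i];
    if (p >= 0) { gax_sum[i] += g_ax[i]; gax_sum[p] += g_ax[i]; }
  }

  std::vector<int> spike_cell;
  std::vector<double> spike_time;

  for (int t = 0; t < n_steps; ++t) {
    const double tnow = t0 + t * dt;

    // synaptic aggregate decay + event arrivals
    for (int s = 0; s < nst; ++s) { stA[s] *= dA[s]; stB[s] *= dB[s]; }
    const std::vector<std::pair<int, double> > &evs = bucket[t];
    for (size_t e = 0; e < evs.size(); ++e) {
      stA[evs[e].first] += evs[e].second;
      stB[evs[e].first] += evs[e].second;
    }

    std::fill(gsyn.begin(), gsyn.end(), 0.0);
    std::fill(gesyn.begin(), gesyn.end(), 0.0);
    std::fill(sax.begin(), sax.end(), 0.0);
    std::fill(iinj.begin(), iinj.end(), 0.0);

    double eeg_t = 0.0;
    for (int s = 0; s < nst; ++s) {
      double g = stB[s] - stA[s];
      if (g < 0) g = 0;
      const int c = st_comp[s];
      if (st_nmda[s])
        g /= 1.0 + (mg / 3.57) * std::exp(-0.062 * v[c]);
      gsyn[c] += g;
      gesyn[c] += g * st_e[s];
      if (st_eeg[s]) eeg_t += std::fabs(g * (v[c] - st_e[s]));
    }
    if (want_eeg) eeg[t] = eeg_t;

    // axial neighbour terms (old voltages)
    for (int i = 0; i < ncomp; ++i) {
      int p = parent[i];
      if (p >= 0) {
        sax[i] += g_ax[i] * v[p];
        sax[p] += g_ax[i] * v[i];
      }
    }
    for (int k = 0; k < inj_comp.size(); ++k)
      if (t >= inj_on[k] && t < inj_off[k]) iinj[inj_comp[k]] += inj_amp[k];

    // membrane update
    for (int i = 0; i < ncomp; ++i) {
      const double m = gates(i, 0), h = gates(i, 1), s2 = gates(i, 2),
                   n = gates(i, 3), aa = gates(i, 4), bb = gates(i, 5),
                   cc = gates(i, 6), q = gates(i, 7);
      const double gna = gchan(i, 0) * m * m * h;
      const double gca = gchan(i, 1) * s2 * s2;
      const double gkdr = gchan(i, 2) * n;
      const double gka = gchan(i, 3) * aa * bb;
      const double gkahp = gchan(i, 4) * q;
      double cgate = chi[i] / 250.0; if (cgate > 1.0) cgate = 1.0;
      const double gkc = gchan(i, 5) * cc * cgate;

      const double G = g_leak[i] + gna + gca + gkdr + gka + gkahp + gkc +
                       gsyn[i] + gax_sum[i];
      const double S = g_leak[i] * e_leak[i] + gna * e_na + gca * e_ca +
                       (gkdr + gka + gkahp + gkc) * e_k + gesyn[i] + sax[i] +
                       iinj[i];
      const double vinf = S / G;
      vnew[i] = vinf + (v[i] - vinf) * std::exp(-dt * G / cm[i]);
      if (!std::isfinite(vnew[i]))
        stop("integration failure: non-finite voltage in compartment %d at t = %.3f ms",
             i + 1, tnow);

      // calcium influx from the pre-step voltage
      const double ica = gca * (v[i] - e_ca);
      chi[i] += dt * (-ca_phi[i] * ica - chi[i] / ca_tau[i]);
      if (chi[i] < 0) chi[i] = 0;
    }

    // gates at the new voltage
    for (int i = 0; i < ncomp; ++i) {
      const int iv = vindex(vnew[i]);
      for (int g = 0; g < NGATE_V; ++g) {
        double x = tabs[g].xinf[iv] + (gates(i, g) - tabs[g].xinf[iv]) * tabs[g].dfac[iv];
        if (x < 0) x = 0; if (x > 1) x = 1;
        gates(i, g) = x;
      }
      double aq = 2e-5 * chi[i]; if (aq > 0.01) aq = 0.01;
      double q = gates(i, 7);
      q += dt * (aq * (1.0 - q) - 0.001 * q);
      if (q < 0) q = 0; if (q > 1) q = 1;
      gates(i, 7) = q;
    }

    // spikes: upward threshold crossing at the soma with refractory lockout
    for (int c = 0; c < ncell; ++c) {
      const int sc = soma[c];
      const double tsp = tnow + dt;
      if (vnew[sc] >= thresh && v[sc] < thresh && (tsp - tlast[c]) >= refrac) {
        tlast[c] = tsp;
        spike_cell.push_back(c + 1);
        spike_time.push_back(tsp);
        for (int k = out_ptr[c]; k < out_ptr[c + 1]; ++k) {
          const int stp = t + out_delay[k];
          if (stp < n_steps)
            bucket[stp].push_back(std::make_pair(out_state[k], out_amt[k]));
        }
      }
    }

    for (int i = 0; i < ncomp; ++i) v[i] = vnew[i];

    if (nrec > 0 && (t % rec_every) == 0) {
      const int r = t / rec_every;
      for (int j = 0; j < nrec; ++j) vtrace(r, j) = v[rec_comps[j]];
    }
    if ((t & 2047) == 0) Rcpp::checkUserInterrupt();
  }

  return List::create(
    _["eeg"] = eeg,
    _["spike_cell"] = wrap(spike_cell),
    _["spike_time"] = wrap(spike_time),
    _["vtrace"] = vtrace,
    _["state"] = List::create(
      _["v"] = v, _["gates"] = gates, _["chi"] = chi,
      _["syn_a"] = stA, _["syn_b"] = stB, _["t_last_spike"] = tlast));
}

// Entry point and registration. The wrapper lives in this translation
// unit (rather than a generated RcppExports.cpp) so the integrator and
// its Rcpp accessors are optimised together.
RcppExport SEXP hg_sim_core(SEXP netSEXP, SEXP optsSEXP) {
BEGIN_RCPP
  Rcpp::RObject out;
  {
    List net(netSEXP), opts(optsSEXP);
    out = sim_core(net, opts);
  }
  return out;
END_RCPP
}

static const R_CallMethodDef CallEntries[] = {
  {"hg_sim_core", (DL_FUNC)&hg_sim_core, 2},
  {NULL, NULL, 0}
};

RcppExport void R_init_hippogamma(DllInfo *dll) {
  R_registerRoutines(dll, NULL, CallEntries, NULL, NULL);
  R_useDynamicSymbols(dll, FALSE);
}
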