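#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// Reduced sinoatrial pacemaker cell: two-variable conductance oscillator in a
// Class-I (SNIC) regime so firing slows gracefully to quiescence as an
// ACh-gated potassium conductance grows.  Units: mV, ms, nS, pF, pA; ACh mM.
//
// Each cell carries a two-pool ACh kinetics pair (neuroeffector junction J and
// extra-junctional space E): events inject a fixed quantum into J; J and E
// exchange first-order and both are hydrolysed at k_H.

struct CellPar {
  double gca, eca, gk, ek, gl, el;
  double v1, v2, v3, v4, phi, cap, iapp;
};

static inline double minf(const CellPar &p, double v) {
  return 0.5 * (1.0 + std::tanh((v - p.v1) / p.v2));
}
static inline double winf(const CellPar &p, double v) {
  return 0.5 * (1.0 + std::tanh((v - p.v3) / p.v4));
}
static inline double tauw(const CellPar &p, double v) {
  return 1.0 / (p.phi * std::cosh((v - p.v3) / (2.0 * p.v4)));
}

// [[Rcpp::export(name = ".san_network_c")]]
List san_network_c(double duration, double dt,
                   NumericVector v_init, NumericVector w_init,
                   NumericVector event_times, IntegerVector event_offsets,
                   IntegerMatrix neighbors, IntegerVector n_neighbors,
                   List cell_par, List ach_par,
                   double g_gap, double g_kach,
                   int record_cell, double record_dt) {
  const int n = v_init.size();
  CellPar p;
  p.gca = cell_par["gca"]; p.eca = cell_par["eca"];
  p.gk  = cell_par["gk"];  p.ek  = cell_par["ek"];
  p.gl  = cell_par["gl"];  p.el  = cell_par["el"];
  p.v1  = cell_par["v1"];  p.v2  = cell_par["v2"];
  p.v3  = cell_par["v3"];  p.v4  = cell_par["v4"];
  p.phi = cell_par["phi"]; p.cap = cell_par["cap"];
  p.iapp = cell_par["iapp"];

  const double quantum = ach_par["quantum"];   // mM added to J per event
  const double k_ex = as<double>(ach_par["k_exchange"]) / 1000.0; // 1/ms
  const double k_h  = as<double>(ach_par["k_hydrolysis"]) / 1000.0;
  const double hill_k = ach_par["hill_k"];
  const double hill_n = ach_par["hill_n"];
  const double tau_b = ach_par["tau_bound_ms"]; // receptor/G-protein kinetics

  std::vector<double> v(v_init.begin(), v_init.end());
  std::vector<double> w(w_init.begin(), w_init.end());
  std::vector<double> J(n, 0.0), E(n, 0.0), B(n, 0.0), s(n, 0.0);
  std::vector<int> evptr(n);
  for (int i = 0; i < n; ++i) evptr[i] = event_offsets[i];

  std::vector< std::vector<double> > spikes(n);
  std::vector<double> vprev(v);

  const double spike_thr = -10.0;
  const long nsteps = (long)std::ceil(duration / dt);
  const int rec_every = record_dt > 0 ? std::max(1, (int)std::round(record_dt / dt)) : 0;
  std::vector<double> rec_t, rec_v, rec_j;

  std::vector<double> vnew(n), wnew(n);

  for (long step = 0; step < nsteps; ++step) {
    double t = step * dt;

    // inject ACh quanta due at or before t
    for (int i = 0; i < n; ++i) {
      int end = event_offsets[i + 1];
      while (evptr[i] < end && event_times[evptr[i]] <= t) {
        J[i] += quantum;
        ++evptr[i];
      }
      // ACh kinetics (forward Euler; rates are slow relative to dt)
      double dJ = -k_h * J[i] - k_ex * (J[i] - E[i]);
      double dE = -k_h * E[i] + k_ex * (J[i] - E[i]);
      J[i] += dt * dJ; E[i] += dt * dE;
      if (J[i] < 0) J[i] = 0; if (E[i] < 0) E[i] = 0;
      // slow receptor-bound pool: the ACh-gated K channel activates with
      // G-protein-coupled kinetics, not instantaneously with junctional ACh
      B[i] += dt * (J[i] - B[i]) / tau_b;
      double jn = std::pow(B[i], hill_n);
      s[i] = jn / (jn + std::pow(hill_k, hill_n));
    }

    for (int i = 0; i < n; ++i) {
      double vi = v[i];
      double igap = 0.0;
      for (int k = 0; k < n_neighbors[i]; ++k)
        igap += g_gap * (v[neighbors(i, k)] - vi);
      double iion = p.gca * minf(p, vi) * (vi - p.eca)
                  + p.gk * w[i] * (vi - p.ek)
                  + p.gl * (vi - p.el)
                  + g_kach * s[i] * (vi - p.ek);
      vnew[i] = vi + dt * (p.iapp - iion + igap) / p.cap;
      wnew[i] = w[i] + dt * (winf(p, vi) - w[i]) / tauw(p, vi);
    }
    for (int i = 0; i < n; ++i) {
      if (vprev[i] < spike_thr && vnew[i] >= spike_thr) {
        double frac = (spike_thr - vprev[i]) / (vnew[i] - vprev[i]);
        spikes[i].push_back(t + frac * dt);
      }
      vprev[i] = vnew[i];
      v[i] = vnew[i];
      w[i] = wnew[i];
    }

    if (rec_every && record_cell >= 0 && step % rec_every == 0) {
      rec_t.push_back(t);
      rec_v.push_back(v[record_cell]);
      rec_j.push_back(J[record_cell]);
    }
  }

  List spk(n);
  for (int i = 0; i < n; ++i) spk[i] = NumericVector(spikes[i].begin(), spikes[i].end());
  List out = List::create(_["spikes"] = spk);
  if (rec_every && record_cell >= 0)
    out["trace"] = DataFrame::create(_["time"] = rec_t, _["v"] = rec_v, _["junction_ach"] = rec_j);
  return out;
}
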