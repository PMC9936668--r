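#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// Ding force-fatigue model of electrically stimulated muscle.
//
// CN (normalized Ca-troponin driver) obeys
//   tau_c * dCN/dt = sum_i R_i exp(-(t - t_i)/tau_c) - CN
// with doublet enhancement R_i = 1 + (R0 - 1) exp(-(t_i - t_{i-1})/tau_c).
// Writing E(t) = sum_i R_i exp(-(t - t_i)/tau_c), E decays with tau_c and
// jumps by R_i at each pulse, and CN has the exact resonant-case update
//   CN(t+h) = (CN + E * h/tau_c) * exp(-h/tau_c)
// between pulses, which this integrator uses (no aliasing of the driver).
//
// Force: dF/dt = A * CN/(Km + CN) - F / (tau1 + tau2 * CN/(Km + CN))
// Fatigue: dX/dt = -(X - X_rest)/tau_fat + alpha_X * F  for X in {A, Km, tau1};
// integrated with RK4 using the analytic CN at the half steps.
//
// Units: ms for time (tau_fat supplied in s, converted), force nominal.

struct DingState { double F, A, Km, tau1; };

static inline void deriv(const DingState &st, double cn,
                         double A0, double Km0, double tau10,
                         double tau2, double aA, double aKm, double at1,
                         double taufat, DingState &d) {
  double A = st.A > 0 ? st.A : 0.0;
  double Km = st.Km > 1e-6 ? st.Km : 1e-6;
  double tau1 = st.tau1 > 1e-3 ? st.tau1 : 1e-3;
  double occ = cn / (Km + cn);
  d.F = A * occ - st.F / (tau1 + tau2 * occ);
  d.A = -(st.A - A0) / taufat + aA * st.F;
  d.Km = -(st.Km - Km0) / taufat + aKm * st.F;
  d.tau1 = -(st.tau1 - tau10) / taufat + at1 * st.F;
}

// [[Rcpp::export(name = ".ding_simulate_c")]]
List ding_simulate_c(NumericVector pulse_times, NumericVector params,
                     double dt, double duration, bool keep_trace) {
  // params: A, Km, tau1, tau2, alpha_A, alpha_Km, alpha_tau1, tau_fat_s, tau_c, R0
  const double A0 = params[0], Km0 = params[1], tau10 = params[2], tau2 = params[3];
  const double aA = params[4], aKm = params[5], at1 = params[6];
  const double taufat = params[7] * 1000.0;  // s -> ms
  const double tauc = params[8], R0 = params[9];

  const long nsteps = (long)std::ceil(duration / dt);
  DingState st = {0.0, A0, Km0, tau10};
  double E = 0.0, CN = 0.0, fti = 0.0;
  double last_pulse = -1e12;
  int np = pulse_times.size(), ip = 0;
  const double edec = std::exp(-dt / tauc);

  NumericVector tr_t, tr_f, tr_cn, tr_a, tr_km, tr_tau1;
  int keep_every = keep_trace ? std::max(1, (int)std::round(0.5 / dt)) : 0;

  for (long step = 0; step < nsteps; ++step) {
    double t = step * dt;
    while (ip < np && pulse_times[ip] <= t) {
      double ipi = pulse_times[ip] - last_pulse;
      E += 1.0 + (R0 - 1.0) * std::exp(-ipi / tauc);
      last_pulse = pulse_times[ip];
      ++ip;
    }
    if (keep_every && step % keep_every == 0) {
      tr_t.push_back(t); tr_f.push_back(st.F); tr_cn.push_back(CN);
      tr_a.push_back(st.A); tr_km.push_back(st.Km); tr_tau1.push_back(st.tau1);
    }

    // analytic CN at substages of the step
    double cn0 = CN;
    double cn_half = (cn0 + E * (0.5 * dt) / tauc) * std::exp(-0.5 * dt / tauc);
    double cn_full = (cn0 + E * dt / tauc) * edec;

    DingState k1, k2, k3, k4, tmp;
    deriv(st, cn0, A0, Km0, tau10, tau2, aA, aKm, at1, taufat, k1);
    tmp.F = st.F + 0.5 * dt * k1.F; tmp.A = st.A + 0.5 * dt * k1.A;
    tmp.Km = st.Km + 0.5 * dt * k1.Km; tmp.tau1 = st.tau1 + 0.5 * dt * k1.tau1;
    deriv(tmp, cn_half, A0, Km0, tau10, tau2, aA, aKm, at1, taufat, k2);
    tmp.F = st.F + 0.5 * dt * k2.F; tmp.A = st.A + 0.5 * dt * k2.A;
    tmp.Km = st.Km + 0.5 * dt * k2.Km; tmp.tau1 = st.tau1 + 0.5 * dt * k2.tau1;
    deriv(tmp, cn_half, A0, Km0, tau10, tau2, aA, aKm, at1, taufat, k3);
    tmp.F = st.F + dt * k3.F; tmp.A = st.A + dt * k3.A;
    tmp.Km = st.Km + dt * k3.Km; tmp.tau1 = st.tau1 + dt * k3.tau1;
    deriv(tmp, cn_full, A0, Km0, tau10, tau2, aA, aKm, at1, taufat, k4);

    st.F += dt / 6.0 * (k1.F + 2 * k2.F + 2 * k3.F + k4.F);
    st.A += dt / 6.0 * (k1.A + 2 * k2.A + 2 * k3.A + k4.A);
    st.Km += dt / 6.0 * (k1.Km + 2 * k2.Km + 2 * k3.Km + k4.Km);
    st.tau1 += dt / 6.0 * (k1.tau1 + 2 * k2.tau1 + 2 * k3.tau1 + k4.tau1);
    if (st.F < 0) st.F = 0;

    E *= edec;
    CN = cn_full;
    fti += st.F * dt;  // force-time integral, left Riemann
  }

  List out = List::create(_["fti"] = fti,
                          _["final"] = NumericVector::create(
                            _["F"] = st.F, _["A"] = st.A,
                            _["Km"] = st.Km, _["tau1"] = st.tau1));
  if (keep_trace)
    out["trace"] = DataFrame::create(_["time"] = tr_t, _["cn"] = tr_cn,
                                     _["force"] = tr_f, _["A"] = tr_a,
                                     _["Km"] = tr_km, _["tau1"] = tr_tau1);
  return out;
}
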