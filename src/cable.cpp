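#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// Reduced myelinated fiber: Hodgkin-Huxley-style active nodes of Ranvier
// joined by passive internodal resistances (myelin treated as a perfect
// insulator).  Extracellular node potentials from the bipolar point-source
// field enter through the activating-function term of the cable equation.
//
// Units: mV, ms; membrane patches in mS / uF (areas in cm^2).

static inline double am(double v) { double x = -(v + 40.0) / 10.0; return std::fabs(x) < 1e-7 ? 1.0 : 0.1 * (v + 40.0) / (1.0 - std::exp(x)); }
static inline double bm(double v) { return 4.0 * std::exp(-(v + 65.0) / 18.0); }
static inline double ah(double v) { return 0.07 * std::exp(-(v + 65.0) / 20.0); }
static inline double bh(double v) { return 1.0 / (1.0 + std::exp(-(v + 35.0) / 10.0)); }
static inline double an(double v) { double x = -(v + 55.0) / 10.0; return std::fabs(x) < 1e-7 ? 0.1 : 0.01 * (v + 55.0) / (1.0 - std::exp(x)); }
static inline double bn(double v) { return 0.125 * std::exp(-(v + 65.0) / 80.0); }

// Simulate one fiber at a given stimulus amplitude; return true if an action
// potential (rising crossing of -30 mV) reaches the detection node.
// ve_unit: extracellular potential (mV) at each node per unit (1 mA) cathodic
// first-phase current; phases flip its sign.
static bool fires(const std::vector<double> &ve_unit, double amp,
                  double phase_ms, double g_ax, double c_node, double area,
                  double dur_ms, double dt, int detect_node, double q_gate) {
  const int n = ve_unit.size();
  // nodal channel densities ~10x the squid values (mammalian nodes of
  // Ranvier are far denser), giving a conduction safety factor adequate for
  // internodes of 100 fiber diameters
  const double gna = 1200.0 * area, gk = 360.0 * area, gl = 3.0 * area;  // mS
  const double ena = 50.0, ek = -77.0, el = -54.4, vrest = -65.0;
  std::vector<double> v(n, vrest), m(n), h(n), nn(n), vnew(n);
  for (int i = 0; i < n; ++i) {
    m[i] = am(vrest) / (am(vrest) + bm(vrest));
    h[i] = ah(vrest) / (ah(vrest) + bh(vrest));
    nn[i] = an(vrest) / (an(vrest) + bn(vrest));
  }
  const long nsteps = (long)std::ceil(dur_ms / dt);
  double vdet_prev = vrest;
  for (long step = 0; step < nsteps; ++step) {
    double t = step * dt;
    double sgn = t < phase_ms ? -1.0 : (t < 2.0 * phase_ms ? 1.0 : 0.0);
    for (int i = 0; i < n; ++i) {
      double vi = v[i];
      double iion = gna * m[i] * m[i] * m[i] * h[i] * (vi - ena)
                  + gk * nn[i] * nn[i] * nn[i] * nn[i] * (vi - ek)
                  + gl * (vi - el);
      double ax = 0.0;
      double vei = sgn * amp * ve_unit[i];
      if (i > 0)     ax += g_ax * ((v[i - 1] + sgn * amp * ve_unit[i - 1]) - (vi + vei));
      if (i < n - 1) ax += g_ax * ((v[i + 1] + sgn * amp * ve_unit[i + 1]) - (vi + vei));
      vnew[i] = vi + dt * (ax - iion) / c_node;  // c in uF, I in uA -> mV/ms
      m[i] += dt * q_gate * (am(vi) * (1 - m[i]) - bm(vi) * m[i]);
      h[i] += dt * q_gate * (ah(vi) * (1 - h[i]) - bh(vi) * h[i]);
      nn[i] += dt * q_gate * (an(vi) * (1 - nn[i]) - bn(vi) * nn[i]);
    }
    v.swap(vnew);
    if (vdet_prev < -30.0 && v[detect_node] >= -30.0) return true;
    vdet_prev = v[detect_node];
  }
  return false;
}

// [[Rcpp::export(name = ".fiber_threshold_c")]]
double fiber_threshold_c(NumericVector ve_unit, double phase_ms, double g_ax,
                         double c_node, double area, double dur_ms, double dt,
                         int detect_node, double q_gate,
                         double upper, double tol) {
  std::vector<double> ve(ve_unit.begin(), ve_unit.end());
  // very strong fields near the contacts can block conduction (the anodic
  // phase annihilates the spike), so activation need not be monotone up to
  // the bound: scan the whole geometric amplitude grid for the lowest
  // activating point, then bisect the lower edge of that activation range
  // (the smallest activating amplitude, i.e. the recruitment threshold;
  // windows narrower than the grid factor can be missed)
  double hi = -1.0, lo = 0.0;
  for (double a = upper; a > upper * 1e-5; a *= 0.6) {
    bool f = fires(ve, a, phase_ms, g_ax, c_node, area, dur_ms, dt, detect_node, q_gate);
    if (f) { hi = a; lo = 0.0; }
    else if (hi > 0 && lo == 0.0) lo = a;
  }
  if (hi < 0) return R_PosInf;
  while ((hi - lo) > tol * hi) {
    double mid = 0.5 * (lo + hi);
    if (fires(ve, mid, phase_ms, g_ax, c_node, area, dur_ms, dt, detect_node, q_gate))
      hi = mid;
    else
      lo = mid;
  }
  return hi;
}

// [[Rcpp::export(name = ".fiber_fires_c")]]
bool fiber_fires_c(NumericVector ve_unit, double amp, double phase_ms,
                   double g_ax, double c_node, double area, double dur_ms,
                   double dt, int detect_node, double q_gate) {
  std::vector<double> ve(ve_unit.begin(), ve_unit.end());
  return fires(ve, amp, phase_ms, g_ax, c_node, area, dur_ms, dt,
               detect_node, q_gate);
}

// van Herk / Gil-Werman sliding maximum with centered window (odd width).
// [[Rcpp::export(name = ".running_max_c")]]
NumericVector running_max_c(NumericVector x, int w) {
  int n = x.size();
  if (w < 1) w = 1;
  if (w % 2 == 0) w += 1;
  int half = w / 2;
  NumericVector out(n);
  std::vector<double> pref(n), suff(n);
  for (int i = 0; i < n; ++i)
    pref[i] = (i % w == 0) ? x[i] : std::max(pref[i - 1], x[i]);
  for (int i = n - 1; i >= 0; --i)
    suff[i] = (i == n - 1 || (i + 1) % w == 0) ? x[i] : std::max(suff[i + 1], x[i]);
  for (int i = 0; i < n; ++i) {
    int lo = i - half, hi = i + half;
    if (lo < 0) lo = 0;
    if (hi > n - 1) hi = n - 1;
    out[i] = std::max(suff[lo], pref[hi]);
  }
  return out;
}
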