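// Implicit (backward-Euler) solver for the multi-compartment cable equation
// on a tree, with Hodgkin-Huxley-style active conductances.
//
// Units: mV, ms, nA, nF, uS, MOhm (so that nA/nF = mV/ms and mV/MOhm = nA).
//
// Channel kinetics: Traub-Miles-type rat cortical pyramidal rate functions
// (the standard set of minimal cortical Hodgkin-Huxley models), with
// threshold parameter vT = -55 mV. Rate constants in 1/ms, voltages in mV,
// u = v - vT:
//   Na  (transient, m^3 h):
//     alpha_m = 0.32 (u-13) / (1 - exp(-(u-13)/4))
//     beta_m  = 0.28 (u-40) / (exp((u-40)/5) - 1)
//     alpha_h = 0.128 exp(-(u-17)/18)
//     beta_h  = 4 / (1 + exp(-(u-40)/5))
//   K   (delayed rectifier, n^4):
//     alpha_n = 0.032 (u-15) / (1 - exp(-(u-15)/5))
//     beta_n  = 0.5 exp(-(u-10)/40)
//   Kv7 (M-type, slow non-inactivating, first-order gate q):
//     alpha_q = 0.0033 exp( 0.1 (v+35))   beta_q = 0.0033 exp(-0.1 (v+35))
// The set is parameterized at ~36 degC; all rates are scaled by
// phi = Q10^((T-36)/10) with Q10 = 3. Gates are advanced by exact
// exponential relaxation towards their voltage-dependent steady state; the
// voltage update then treats the resulting conductances as constant over
// the step (standard staggered scheme).

#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

static inline double vtrap(double x, double y) {
  // x / (exp(x/y) - 1), stable near x = 0
  if (std::fabs(x / y) < 1e-6) return y * (1.0 - x / (2.0 * y));
  return x / (std::exp(x / y) - 1.0);
}

static const double VT = -55.0;

static inline double alpha_m(double v) { return 0.32 * vtrap(-(v - VT - 13.0), 4.0); }
static inline double beta_m(double v)  { return 0.28 * vtrap(v - VT - 40.0, 5.0); }
static inline double alpha_h(double v) { return 0.128 * std::exp(-(v - VT - 17.0) / 18.0); }
static inline double beta_h(double v)  { return 4.0 / (1.0 + std::exp(-(v - VT - 40.0) / 5.0)); }
static inline double alpha_n(double v) { return 0.032 * vtrap(-(v - VT - 15.0), 5.0); }
static inline double beta_n(double v)  { return 0.5 * std::exp(-(v - VT - 10.0) / 40.0); }
static inline double alpha_q(double v) { return 0.0033 * std::exp( 0.1 * (v + 35.0)); }
static inline double beta_q(double v)  { return 0.0033 * std::exp(-0.1 * (v + 35.0)); }

// [[Rcpp::export]]
List cable_solve_cpp(IntegerVector parent,      // 0-based parent index, -1 for root
                     NumericVector cm_nF,
                     NumericVector g_na_uS,
                     NumericVector g_k_uS,
                     NumericVector g_kv7_uS,
                     NumericVector g_leak_uS,
                     double e_na, double e_k, double e_leak,
                     NumericVector r_axial_MOhm, // comp <-> parent, NA/0 unused for root
                     double v_init,
                     int stim_comp,              // 0-based
                     double stim_amp_nA,
                     double stim_start_ms,
                     double stim_dur_ms,
                     double dt_ms,
                     int n_steps,
                     double phi) {
  const int n = parent.size();
  if (n < 1) stop("empty compartment set");
  for (int i = 1; i < n; ++i)
    if (parent[i] >= i) stop("compartments must be ordered with parent < child");

  NumericMatrix v_out(n, n_steps), im_out(n, n_steps);

  std::vector<double> v(n, v_init), m(n), h(n), gn(n), q(n);
  for (int i = 0; i < n; ++i) {
    double vv = v_init;
    m[i]  = alpha_m(vv) / (alpha_m(vv) + beta_m(vv));
    h[i]  = alpha_h(vv) / (alpha_h(vv) + beta_h(vv));
    gn[i] = alpha_n(vv) / (alpha_n(vv) + beta_n(vv));
    q[i]  = alpha_q(vv) / (alpha_q(vv) + beta_q(vv));
  }

  std::vector<double> axg(n, 0.0); // axial conductance to parent, uS
  for (int i = 1; i < n; ++i) {
    double r = r_axial_MOhm[i];
    if (!(r > 0)) stop("axial resistance must be positive for non-root compartments");
    axg[i] = 1.0 / r;
  }

  std::vector<double> diag(n), rhs(n), vm_new(n);

  for (int step = 0; step < n_steps; ++step) {
    double t = step * dt_ms;
    double istim = (t >= stim_start_ms && t < stim_start_ms + stim_dur_ms) ? stim_amp_nA : 0.0;

    // gate update (exponential relaxation, rates scaled by phi)
    for (int i = 0; i < n; ++i) {
      double vv = v[i];
      double am = alpha_m(vv), bm = beta_m(vv);
      double ah = alpha_h(vv), bh = beta_h(vv);
      double an = alpha_n(vv), bn = beta_n(vv);
      double aq = alpha_q(vv), bq = beta_q(vv);
      double tm = 1.0 / (phi * (am + bm)), minf = am / (am + bm);
      double th = 1.0 / (phi * (ah + bh)), hinf = ah / (ah + bh);
      double tn = 1.0 / (phi * (an + bn)), ninf = an / (an + bn);
      double tq = 1.0 / (phi * (aq + bq)), qinf = aq / (aq + bq);
      m[i]  = minf + (m[i]  - minf) * std::exp(-dt_ms / tm);
      h[i]  = hinf + (h[i]  - hinf) * std::exp(-dt_ms / th);
      gn[i] = ninf + (gn[i] - ninf) * std::exp(-dt_ms / tn);
      q[i]  = qinf + (q[i]  - qinf) * std::exp(-dt_ms / tq);
    }

    // assemble backward-Euler system  A v' = b
    for (int i = 0; i < n; ++i) {
      double gna = g_na_uS[i] * m[i] * m[i] * m[i] * h[i];
      double gk  = g_k_uS[i] * gn[i] * gn[i] * gn[i] * gn[i];
      double gq  = g_kv7_uS[i] * q[i];
      double gl  = g_leak_uS[i];
      diag[i] = cm_nF[i] / dt_ms + gna + gk + gq + gl;
      rhs[i]  = cm_nF[i] / dt_ms * v[i] + gna * e_na + gk * e_k + gq * e_k + gl * e_leak;
      if (i == stim_comp) rhs[i] += istim;
    }
    for (int i = 1; i < n; ++i) {
      diag[i] += axg[i];
      diag[parent[i]] += axg[i];
    }
    // Hines elimination: leaves -> root, then back-substitution
    for (int i = n - 1; i >= 1; --i) {
      int p = parent[i];
      double f = axg[i] / diag[i];
      diag[p] -= axg[i] * f;
      rhs[p]  += rhs[i] * f;
    }
    vm_new[0] = rhs[0] / diag[0];
    for (int i = 1; i < n; ++i)
      vm_new[i] = (rhs[i] + axg[i] * vm_new[parent[i]]) / diag[i];

    for (int i = 0; i < n; ++i) v[i] = vm_new[i];

    // Membrane current for the forward model: KCL at each compartment
    // reads C dv/dt + I_ion - I_stim = net axial inflow, so the outward
    // transmembrane current (capacitive + ionic, with the electrode
    // current accounted at the injected compartment) equals the axial
    // inflow.  Axial currents cancel pairwise, hence the total over the
    // closed cell is exactly zero at every step.
    for (int i = 0; i < n; ++i) im_out(i, step) = 0.0;
    for (int i = 1; i < n; ++i) {
      int p = parent[i];
      double f = (v[p] - v[i]) * axg[i]; // nA flowing parent -> i
      im_out(i, step) += f;
      im_out(p, step) -= f;
    }
    for (int i = 0; i < n; ++i) v_out(i, step) = v[i];
  }

  return List::create(_["v"] = v_out, _["imem"] = im_out);
}
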