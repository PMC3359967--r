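#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// Fixed-step Euler / Euler-Maruyama core shared by all model variants.
//
// Parameter vector layout (kept in sync with .par_vec() on the R side):
//  0 C      1 g_fast  2 g_slow  3 g_leak  4 E_Na   5 E_K    6 E_leak
//  7 bm     8 gm
//  9 bw    10 gw     11 phiw
// 12 bh    13 gh     14 tauh   15 phih   16 h_fixed_tau (0/1)
// 17 bz    18 gz     19 tauz   20 g_adapt
// 21 g_kdr 22 bws    23 gws    24 phiws
// 25 g_sub 26 E_sub  27 by     28 gy     29 phiy
// 30 h_clamp (ml2d only)       31 z_clamp (ml2d only)
//
// Variant codes: 1 ml2d, 2 ml2d_nainact_fast, 3 ml3d_nainact_slow,
//                4 ml3d_ahp, 5 ml3d_ungrouped.

static inline double xinf(double V, double beta, double gamma) {
  return 0.5 * (1.0 + std::tanh((V - beta) / gamma));
}

static inline void rhs_core(int variant, const double *p, const double *y,
                            double Istim, double *dy) {
  const double V = y[0];
  const double minf = xinf(V, p[7], p[8]);
  switch (variant) {
  case 1: { // ml2d (+ optional h clamp on I_fast, z clamp on an AHP term)
    const double w = y[1];
    const double I_ion = p[1] * p[30] * minf * (V - p[4]) +
                         p[2] * w * (V - p[5]) +
                         p[20] * p[31] * (V - p[5]) +
                         p[3] * (V - p[6]);
    dy[0] = (Istim - I_ion) / p[0];
    dy[1] = p[11] * std::cosh((V - p[9]) / (2.0 * p[10])) *
            (xinf(V, p[9], p[10]) - w);
    break;
  }
  case 2: { // ml2d_nainact_fast: (V, h), inactivation is the slow feedback
    const double h = y[1];
    const double I_ion = p[1] * minf * h * (V - p[4]) + p[3] * (V - p[6]);
    dy[0] = (Istim - I_ion) / p[0];
    dy[1] = p[15] * std::cosh((V - p[12]) / (2.0 * p[13])) *
            (xinf(V, p[12], p[13]) - h);
    break;
  }
  case 3: { // ml3d_nainact_slow: (V, w, h), fixed tau_h
    const double w = y[1], h = y[2];
    const double I_ion = p[1] * minf * h * (V - p[4]) +
                         p[2] * w * (V - p[5]) + p[3] * (V - p[6]);
    dy[0] = (Istim - I_ion) / p[0];
    dy[1] = p[11] * std::cosh((V - p[9]) / (2.0 * p[10])) *
            (xinf(V, p[9], p[10]) - w);
    dy[2] = (xinf(V, p[12], p[13]) - h) / p[14];
    break;
  }
  case 4: { // ml3d_ahp: (V, w, z), fixed tau_z
    const double w = y[1], z = y[2];
    const double I_ion = p[1] * minf * (V - p[4]) + p[2] * w * (V - p[5]) +
                         p[20] * z * (V - p[5]) + p[3] * (V - p[6]);
    dy[0] = (Istim - I_ion) / p[0];
    dy[1] = p[11] * std::cosh((V - p[9]) / (2.0 * p[10])) *
            (xinf(V, p[9], p[10]) - w);
    dy[2] = (xinf(V, p[17], p[18]) - z) / p[19];
    break;
  }
  case 5: { // ml3d_ungrouped: (V, ws, y) with I_Kdr + I_sub
    const double ws = y[1], yy = y[2];
    const double I_ion = p[1] * minf * (V - p[4]) +
                         p[21] * ws * (V - p[5]) +
                         p[25] * yy * (V - p[26]) + p[3] * (V - p[6]);
    dy[0] = (Istim - I_ion) / p[0];
    dy[1] = p[24] * std::cosh((V - p[22]) / (2.0 * p[23])) *
            (xinf(V, p[22], p[23]) - ws);
    dy[2] = p[29] * std::cosh((V - p[27]) / (2.0 * p[28])) *
            (xinf(V, p[27], p[28]) - yy);
    break;
  }
  default:
    stop("unknown variant code");
  }
}

// [[Rcpp::export(name = ".euler_core")]]
List euler_core(int variant, NumericVector par, NumericVector y0, double dt,
                int n_steps, double i_base, double i_amp, double t_on,
                double t_off, double noise_sd_step, int thin,
                bool strict_gates) {
  const int ns = y0.size();
  if (ns < 2 || ns > 3) stop("state must have 2 or 3 components");
  const double *p = REAL(par);
  double y[3] = {0, 0, 0}, dy[3] = {0, 0, 0};
  for (int k = 0; k < ns; ++k) y[k] = y0[k];

  const int n_rec = n_steps / thin + 1;
  NumericMatrix out(n_rec, ns);
  NumericVector istim_rec(n_rec);
  int irec = 0;
  for (int k = 0; k < ns; ++k) out(0, k) = y[k];
  istim_rec[0] = i_base + ((0.0 >= t_on && 0.0 < t_off) ? i_amp : 0.0);
  irec = 1;

  RNGScope scope; // only used when noise_sd_step > 0

  int step_failed = -1;
  for (int i = 0; i < n_steps; ++i) {
    const double t = i * dt;
    const double Istim = i_base + ((t >= t_on && t < t_off) ? i_amp : 0.0);
    rhs_core(variant, p, y, Istim, dy);
    for (int k = 0; k < ns; ++k) y[k] += dt * dy[k];
    if (noise_sd_step > 0.0) y[0] += noise_sd_step * norm_rand();
    for (int k = 1; k < ns; ++k) { // gates live in [0,1]
      if (y[k] < 0.0 || y[k] > 1.0) {
        if (strict_gates) stop("gate %d left [0,1] at step %d (value %g)",
                               k, i + 1, y[k]);
        y[k] = y[k] < 0.0 ? 0.0 : 1.0;
      }
    }
    bool finite = true;
    for (int k = 0; k < ns; ++k) finite = finite && R_finite(y[k]);
    if (!finite) { step_failed = i + 1; break; }
    if ((i + 1) % thin == 0) {
      for (int k = 0; k < ns; ++k) out(irec, k) = y[k];
      const double tn = (i + 1) * dt;
      istim_rec[irec] = i_base + ((tn >= t_on && tn < t_off) ? i_amp : 0.0);
      ++irec;
    }
  }

  NumericVector yend(ns);
  for (int k = 0; k < ns; ++k) yend[k] = y[k];
  return List::create(_["states"] = out, _["istim"] = istim_rec,
                      _["n_recorded"] = irec, _["y_end"] = yend,
                      _["step_failed"] = step_failed);
}

// Backward-time Euler trace (quasi-separatrix plotting, 2-D variants only).
// Integrates dy/dt' = -f(y) and stops cleanly when the trajectory leaves
// a stated phase-plane window or becomes non-finite.
// [[Rcpp::export(name = ".euler_backward_core")]]
List euler_backward_core(int variant, NumericVector par, NumericVector y0,
                         double dt, int n_steps, double i_stim,
                         NumericVector v_window, int thin) {
  const int ns = y0.size();
  if (ns != 2) stop("backward integration supports 2-D variants only");
  const double *p = REAL(par);
  double y[2] = {y0[0], y0[1]}, dy[2];
  const int n_rec = n_steps / thin + 1;
  NumericMatrix out(n_rec, 2);
  out(0, 0) = y[0]; out(0, 1) = y[1];
  int irec = 1;
  for (int i = 0; i < n_steps; ++i) {
    rhs_core(variant, p, y, i_stim, dy);
    y[0] -= dt * dy[0];
    y[1] -= dt * dy[1];
    if (!R_finite(y[0]) || !R_finite(y[1])) break;
    if (y[0] < v_window[0] || y[0] > v_window[1] || y[1] < -0.5 || y[1] > 1.5)
      break;
    if ((i + 1) % thin == 0) { out(irec, 0) = y[0]; out(irec, 1) = y[1]; ++irec; }
  }
  return List::create(_["states"] = out, _["n_recorded"] = irec);
}

// One right-hand-side evaluation (cross-checked against the R-level rhs).
// [[Rcpp::export(name = ".rhs_core")]]
NumericVector rhs_eval(int variant, NumericVector par, NumericVector y,
                       double i_stim) {
  const int ns = y.size();
  double dy[3] = {0, 0, 0};
  rhs_core(variant, REAL(par), REAL(y), i_stim, dy);
  NumericVector out(ns);
  for (int k = 0; k < ns; ++k) out[k] = dy[k];
  return out;
}
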