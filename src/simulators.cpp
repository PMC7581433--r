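// Time-stepped mechanistic simulators.  These inner loops are the only
// performance-critical code in the package: gating variables use
// exponential-Euler updates, the membrane potential forward Euler, and
// all stochastic terms draw from R's RNG so set.seed() in R makes every
// trace reproducible.

#include <Rcpp.h>
using namespace Rcpp;

// x / (exp(x/a) - 1), stable near x = 0 (limit a - x/2)
static inline double expdiv(double x, double a) {
  double r = x / a;
  if (std::fabs(r) < 1e-6) return a - x / 2.0;
  return x / (std::expm1(r));
}

static inline double clampd(double x, double lo, double hi) {
  return x < lo ? lo : (x > hi ? hi : x);
}

// ---------------------------------------------------------------------
// Non-inactivating K+ channel family ("Omnimodel") under voltage clamp.
// theta = (th1..th8): steady-state slope/offset; time-constant center,
// amplitude and four shape parameters.  Returns the raw (unnormalized)
// K current at stored time points; command-voltage noise is added here.
// [[Rcpp::export]]
NumericVector omnimodel_trace_cpp(NumericVector theta, NumericVector vcmd,
                                  double dt, double e_k, double noise_sd,
                                  int store_every) {
  const double th1 = theta[0], th2 = theta[1], th3 = theta[2], th4 = theta[3];
  const double th5 = theta[4], th6 = theta[5], th7 = theta[6], th8 = theta[7];
  const int n = vcmd.size();
  const int n_store = (n + store_every - 1) / store_every;
  NumericVector out(n_store);
  double v0 = vcmd[0];
  double m = 1.0 / (1.0 + std::exp(-th1 * v0 + th2));
  int si = 0;
  for (int t = 0; t < n; t++) {
    double v = vcmd[t] + (noise_sd > 0 ? noise_sd * R::norm_rand() : 0.0);
    double minf = 1.0 / (1.0 + std::exp(clampd(-th1 * v + th2, -60.0, 60.0)));
    double d = v - th3;
    double e1 = clampd(-(th5 * d + th6 * d * d), -60.0, 60.0);
    double e2 = clampd(th7 * d + th8 * d * d, -60.0, 60.0);
    double tau = th4 / (std::exp(e1) + std::exp(e2));
    tau = clampd(tau, 1e-3, 1e7);
    m = minf + (m - minf) * std::exp(-dt / tau);
    if (t % store_every == 0) out[si++] = m * (v - e_k);
  }
  return out;
}

// ---------------------------------------------------------------------
// Stochastic single-compartment Hodgkin-Huxley neuron with Na, delayed-
// rectifier K, slow (M-type) K and leak currents.  Gating kinetics follow
// the cortical-neuron rate functions with a spike-threshold shift VT and
// an adaptation time scale tau_max.  params = (gNa, gK, gl, gM, tau_max,
// VT_mag, sigma, El_mag); VT and El enter with negative sign.
// [[Rcpp::export]]
NumericVector hh_trace_cpp(NumericVector params, double dt, double t_total,
                           double t_on, double t_off, double i_amp,
                           int store_every, double e_na, double e_k) {
  const double g_na = params[0], g_k = params[1], g_l = params[2];
  const double g_m = params[3], tau_max = params[4];
  const double vt = -params[5];          // threshold shift (magnitude sampled)
  const double sigma = params[6];
  const double e_l = -params[7];         // leak reversal (magnitude sampled)
  const double cm = 1.0;                 // uF/cm^2
  const int n = (int)std::round(t_total / dt);
  const int n_store = (n + store_every - 1) / store_every;
  NumericVector out(n_store);

  double v = e_l;
  // gating steady states at rest
  double am = 0.32 * expdiv(-(v - vt - 13.0), 4.0);
  double bm = 0.28 * expdiv(v - vt - 40.0, 5.0);
  double ah = 0.128 * std::exp(-(v - vt - 17.0) / 18.0);
  double bh = 4.0 / (1.0 + std::exp(-(v - vt - 40.0) / 5.0));
  double an = 0.032 * expdiv(-(v - vt - 15.0), 5.0);
  double bn = 0.5 * std::exp(-(v - vt - 10.0) / 40.0);
  double m = am / (am + bm), h = ah / (ah + bh), nn = an / (an + bn);
  double p = 1.0 / (1.0 + std::exp(-(v + 35.0) / 10.0));

  const double noise_scale = sigma * std::sqrt(dt) / cm;
  int si = 0;
  bool blew_up = false;
  for (int t = 0; t < n; t++) {
    double tt = t * dt;
    if (t % store_every == 0) out[si++] = blew_up ? NA_REAL : v;
    if (blew_up) continue;
    am = 0.32 * expdiv(-(v - vt - 13.0), 4.0);
    bm = 0.28 * expdiv(v - vt - 40.0, 5.0);
    ah = 0.128 * std::exp(-(v - vt - 17.0) / 18.0);
    bh = 4.0 / (1.0 + std::exp(-(v - vt - 40.0) / 5.0));
    an = 0.032 * expdiv(-(v - vt - 15.0), 5.0);
    bn = 0.5 * std::exp(-(v - vt - 10.0) / 40.0);
    double pinf = 1.0 / (1.0 + std::exp(-(v + 35.0) / 10.0));
    double taup = tau_max / (3.3 * std::exp((v + 35.0) / 20.0) +
                             std::exp(-(v + 35.0) / 20.0));
    double sm = am + bm, sh = ah + bh, sn = an + bn;
    m = am / sm + (m - am / sm) * std::exp(-dt * sm);
    h = ah / sh + (h - ah / sh) * std::exp(-dt * sh);
    nn = an / sn + (nn - an / sn) * std::exp(-dt * sn);
    p = pinf + (p - pinf) * std::exp(-dt / taup);
    double i_inj = (tt >= t_on && tt < t_off) ? i_amp : 0.0;
    double i_ion = g_l * (e_l - v) + g_na * m * m * m * h * (e_na - v) +
                   g_k * nn * nn * nn * nn * (e_k - v) + g_m * p * (e_k - v);
    v += dt * (i_ion + i_inj) / cm;
    if (sigma > 0) v += noise_scale * R::norm_rand();
    if (!std::isfinite(v) || std::fabs(v) > 1000.0) blew_up = true;
  }
  return out;
}

// ---------------------------------------------------------------------
// Three-neuron pyloric circuit (AB/PD, LP, PY).  Eight membrane currents
// per neuron (Na, CaT, CaS, A, KCa, Kd, H, leak) with intracellular Ca
// dynamics and a Nernstian Ca reversal, plus seven graded chemical
// synapses (glutamatergic fast / cholinergic slow).

struct Gate { double m, h; };

static inline double sigm(double v, double v0, double k) {
  // 1 / (1 + exp((v0 + v)/k)); k < 0 gives rising curves
  return 1.0 / (1.0 + std::exp((v + v0) / k));
}

// [[Rcpp::export]]
NumericMatrix stg_trace_cpp(NumericMatrix gmem, NumericVector gsyn_ns,
                            double dt, double t_total, double noise_sd,
                            int store_every) {
  const double area = 0.628e-3;          // cm^2
  const double cm = 1.0;                 // uF/cm^2
  const double e_na = 50.0, e_k = -80.0, e_h = -20.0, e_leak = -50.0;
  const double ca0 = 0.05, ca_ext = 3000.0, tau_ca = 200.0, f_ca = 14.96;
  const int n = (int)std::round(t_total / dt);
  const int n_store = (n + store_every - 1) / store_every;
  NumericMatrix out(3, n_store);

  // synapse wiring: pre, post, glutamatergic flag
  const int s_pre[7]  = {0, 0, 0, 0, 1, 1, 2};
  const int s_post[7] = {1, 1, 2, 2, 0, 2, 1};
  const bool s_glut[7] = {true, false, true, false, true, true, true};
  const double v_th = -35.0, delta = 5.0;

  double v[3], ca[3], s[7];
  Gate na[3], cat[3], cas[3], ia[3], kca[3], kd[3], ih[3];
  for (int i = 0; i < 3; i++) {
    v[i] = -65.0;
    ca[i] = ca0;
    double vv = v[i];
    na[i].m = sigm(vv, 25.5, -5.29); na[i].h = sigm(vv, 48.9, 5.18);
    cat[i].m = sigm(vv, 27.1, -7.2); cat[i].h = sigm(vv, 32.1, 5.5);
    cas[i].m = sigm(vv, 33.0, -8.1); cas[i].h = sigm(vv, 60.0, 6.2);
    ia[i].m = sigm(vv, 27.2, -8.7);  ia[i].h = sigm(vv, 56.9, 4.9);
    kca[i].m = (ca[i] / (ca[i] + 3.0)) * sigm(vv, 28.3, -12.6); kca[i].h = 1.0;
    kd[i].m = sigm(vv, 12.3, -11.8); kd[i].h = 1.0;
    ih[i].m = sigm(vv, 75.0, 5.5);   ih[i].h = 1.0;
  }
  for (int k = 0; k < 7; k++) {
    double vpre = v[s_pre[k]];
    s[k] = 1.0 / (1.0 + std::exp((v_th - vpre) / delta));
  }

  const double noise_scale = noise_sd * std::sqrt(dt);
  int si = 0;
  bool blew_up = false;
  for (int t = 0; t < n; t++) {
    if (t % store_every == 0) {
      for (int i = 0; i < 3; i++) out(i, si) = blew_up ? NA_REAL : v[i];
      si++;
    }
    if (blew_up) continue;

    double i_syn[3] = {0.0, 0.0, 0.0};
    for (int k = 0; k < 7; k++) {
      double e_s = s_glut[k] ? -70.0 : -80.0;
      // nS -> mS, divided by area: current density in uA/cm^2
      i_syn[s_post[k]] += gsyn_ns[k] * 1e-6 * s[k] * (v[s_post[k]] - e_s) / area;
    }

    double vnew[3];
    for (int i = 0; i < 3; i++) {
      double vv = v[i];
      double e_ca = 12.193 * std::log(ca_ext / ca[i]);

      double m3;
      m3 = na[i].m * na[i].m * na[i].m;
      double i_na  = gmem(i, 0) * m3 * na[i].h * (vv - e_na);
      m3 = cat[i].m * cat[i].m * cat[i].m;
      double i_cat = gmem(i, 1) * m3 * cat[i].h * (vv - e_ca);
      m3 = cas[i].m * cas[i].m * cas[i].m;
      double i_cas = gmem(i, 2) * m3 * cas[i].h * (vv - e_ca);
      m3 = ia[i].m * ia[i].m * ia[i].m;
      double i_a   = gmem(i, 3) * m3 * ia[i].h * (vv - e_k);
      double m4 = kca[i].m * kca[i].m * kca[i].m * kca[i].m;
      double i_kca = gmem(i, 4) * m4 * (vv - e_k);
      m4 = kd[i].m * kd[i].m * kd[i].m * kd[i].m;
      double i_kd  = gmem(i, 5) * m4 * (vv - e_k);
      double i_h   = gmem(i, 6) * ih[i].m * (vv - e_h);
      double i_leak = gmem(i, 7) * (vv - e_leak);

      double i_total = i_na + i_cat + i_cas + i_a + i_kca + i_kd + i_h +
                       i_leak + i_syn[i];
      vnew[i] = vv + dt * (-i_total) / cm +
                (noise_sd > 0 ? noise_scale * R::norm_rand() : 0.0);

      // intracellular calcium (exponential Euler; uA/cm^2 -> nA via area)
      double i_ca_na = (i_cat + i_cas) * area * 1e3;
      double ca_inf = ca0 - f_ca * i_ca_na;
      ca[i] = ca_inf + (ca[i] - ca_inf) * std::exp(-dt / tau_ca);
      if (ca[i] < 1e-6) ca[i] = 1e-6;

      // gating updates (exponential Euler with voltage-dependent tau, ms)
      double minf, tau;
      minf = sigm(vv, 25.5, -5.29);
      tau = 2.64 - 2.52 * sigm(vv, 120.0, -25.0);
      na[i].m = minf + (na[i].m - minf) * std::exp(-dt / tau);
      minf = sigm(vv, 48.9, 5.18);
      tau = (1.34 * sigm(vv, 62.9, -10.0)) * (1.5 + sigm(vv, 34.9, 3.6));
      na[i].h = minf + (na[i].h - minf) * std::exp(-dt / tau);

      minf = sigm(vv, 27.1, -7.2);
      tau = 43.4 - 42.6 * sigm(vv, 68.1, -20.5);
      cat[i].m = minf + (cat[i].m - minf) * std::exp(-dt / tau);
      minf = sigm(vv, 32.1, 5.5);
      tau = 210.0 - 179.6 * sigm(vv, 55.0, -16.9);
      cat[i].h = minf + (cat[i].h - minf) * std::exp(-dt / tau);

      minf = sigm(vv, 33.0, -8.1);
      tau = 2.8 + 14.0 / (std::exp((vv + 27.0) / 10.0) +
                          std::exp((vv + 70.0) / -13.0));
      cas[i].m = minf + (cas[i].m - minf) * std::exp(-dt / tau);
      minf = sigm(vv, 60.0, 6.2);
      tau = 120.0 + 300.0 / (std::exp((vv + 55.0) / 9.0) +
                             std::exp((vv + 65.0) / -16.0));
      cas[i].h = minf + (cas[i].h - minf) * std::exp(-dt / tau);

      minf = sigm(vv, 27.2, -8.7);
      tau = 23.2 - 20.8 * sigm(vv, 32.9, -15.2);
      ia[i].m = minf + (ia[i].m - minf) * std::exp(-dt / tau);
      minf = sigm(vv, 56.9, 4.9);
      tau = 77.2 - 58.4 * sigm(vv, 38.9, -26.5);
      ia[i].h = minf + (ia[i].h - minf) * std::exp(-dt / tau);

      minf = (ca[i] / (ca[i] + 3.0)) * sigm(vv, 28.3, -12.6);
      tau = 180.6 - 150.2 * sigm(vv, 46.0, -22.7);
      kca[i].m = minf + (kca[i].m - minf) * std::exp(-dt / tau);

      minf = sigm(vv, 12.3, -11.8);
      tau = 14.4 - 12.8 * sigm(vv, 28.3, -19.2);
      kd[i].m = minf + (kd[i].m - minf) * std::exp(-dt / tau);

      minf = sigm(vv, 75.0, 5.5);
      tau = 2.0 / (std::exp((vv + 169.7) / -11.6) +
                   std::exp((vv - 26.7) / 14.3));
      ih[i].m = minf + (ih[i].m - minf) * std::exp(-dt / tau);
    }

    // synapse activation (exponential Euler; tau_s = (1 - sbar)/k_minus)
    for (int k = 0; k < 7; k++) {
      double vpre = v[s_pre[k]];
      double sbar = 1.0 / (1.0 + std::exp((v_th - vpre) / delta));
      double k_minus = s_glut[k] ? (1.0 / 40.0) : (1.0 / 100.0);
      double tau_s = (1.0 - sbar) / k_minus;
      if (tau_s < 1e-3) tau_s = 1e-3;
      s[k] = sbar + (s[k] - sbar) * std::exp(-dt / tau_s);
    }

    for (int i = 0; i < 3; i++) {
      v[i] = vnew[i];
      if (!std::isfinite(v[i]) || std::fabs(v[i]) > 500.0) blew_up = true;
    }
  }
  return out;
}
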