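#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// Hodgkin-Huxley gating rates (ms^-1), V in mV. Removable singularities
// evaluated by their series limit.
static inline double vtrap_c(double x, double y) {
  if (std::fabs(x / y) < 1e-7) return y + x / 2.0;
  return x / (1.0 - std::exp(-x / y));
}
static inline double f_alpha_m(double v) { return 0.1 * vtrap_c(v + 40.0, 10.0); }
static inline double f_beta_m(double v)  { return 4.0 * std::exp(-(v + 65.0) / 18.0); }
static inline double f_alpha_h(double v) { return 0.07 * std::exp(-(v + 65.0) / 20.0); }
static inline double f_beta_h(double v)  { return 1.0 / (1.0 + std::exp(-(v + 35.0) / 10.0)); }
static inline double f_alpha_n(double v) { return 0.01 * vtrap_c(v + 55.0, 10.0); }
static inline double f_beta_n(double v)  { return 0.125 * std::exp(-(v + 65.0) / 80.0); }

// [[Rcpp::export]]
List gating_rates_cpp(double v) {
  return List::create(
    _["alpha_m"] = f_alpha_m(v), _["beta_m"] = f_beta_m(v),
    _["alpha_h"] = f_alpha_h(v), _["beta_h"] = f_beta_h(v),
    _["alpha_n"] = f_alpha_n(v), _["beta_n"] = f_beta_n(v));
}

// One exact Gillespie pass over an arbitrary transition list, with rates
// held fixed. counts0: state occupancies; transitions k move one channel
// from src[k] to dst[k] with per-channel rate rates[k] (ms^-1). Windows of
// length `window` ms are simulated back to back; the occupancy at the end
// of each window is recorded. Waiting times left over at a window boundary
// are discarded (rates would be refreshed there in the full simulator).
// [[Rcpp::export]]
IntegerMatrix gillespie_generic(IntegerVector counts0, IntegerVector src,
                                IntegerVector dst, NumericVector rates,
                                double window, int n_windows) {
  int ns = counts0.size(), nt = src.size();
  std::vector<double> cnt(ns);
  for (int i = 0; i < ns; ++i) cnt[i] = counts0[i];
  IntegerMatrix out(n_windows, ns);
  std::vector<double> a(nt);
  for (int w = 0; w < n_windows; ++w) {
    double rem = window;
    for (;;) {
      double lambda = 0.0;
      for (int k = 0; k < nt; ++k) {
        a[k] = rates[k] * cnt[src[k]];
        lambda += a[k];
      }
      if (lambda <= 0.0) break;
      double u1 = unif_rand();
      if (u1 <= 0.0) u1 = 1e-300;
      double tw = -std::log(u1) / lambda;
      if (tw >= rem) break;
      rem -= tw;
      double u2 = unif_rand() * lambda;
      double cum = 0.0;
      int j = nt - 1;
      for (int k = 0; k < nt; ++k) {
        cum += a[k];
        if (u2 <= cum) { j = k; break; }
      }
      cnt[src[j]] -= 1.0;
      cnt[dst[j]] += 1.0;
    }
    for (int i = 0; i < ns; ++i) out(w, i) = (int) cnt[i];
  }
  return out;
}

// Hybrid integrator of the membrane current-balance equation:
// forward Euler for V (and for deterministic gating variables), exact
// Gillespie within each dt window for stochastic channel populations,
// with transition rates frozen at the window's starting voltage.
//
// na_mode: 0 stochastic, 1 deterministic, 2 absent; k_mode: 0 or 1.
// Na states indexed i + 4*j (i = open m gates 0..3, j = h gate 0/1),
// conducting state 7 (m3h1); K states n0..n4, conducting 4 (n4).
// i_k returned is the total K+ current: delayed rectifier plus the
// K+-permeable leak branch g_leak_k * (V - E_K) (outward positive).
// [[Rcpp::export]]
List sim_core(NumericVector stim, double dt_ms, List par,
              int na_mode, int k_mode, double v0,
              IntegerVector na0, IntegerVector k0,
              double m0, double h0, double n0,
              double g_leak_k, bool record_extra) {
  const double cm  = as<double>(par["membrane_capacitance"]);
  const double gna = as<double>(par["g_na_max"]);
  const double gk  = as<double>(par["g_k_max"]);
  const double gl  = as<double>(par["g_leak"]);
  const double ena = as<double>(par["e_na"]);
  const double ek  = as<double>(par["e_k"]);
  const double el  = as<double>(par["e_leak"]);
  const int nna = as<int>(par["n_na"]);
  const int nk  = as<int>(par["n_k"]);

  const int n = stim.size();
  NumericVector v_out(n), ik_out(n);
  NumericVector open_na_out(record_extra ? n : 0),
    open_k_out(record_extra ? n : 0), ina_out(record_extra ? n : 0);

  // combined state vector: Na occupancies 0..7, K occupancies 8..12
  double cnt[13] = {0};
  const bool na_stoch = (na_mode == 0), na_det = (na_mode == 1);
  const bool k_stoch = (k_mode == 0);
  if (na_stoch) for (int i = 0; i < 8; ++i) cnt[i] = na0[i];
  if (k_stoch)  for (int i = 0; i < 5; ++i) cnt[8 + i] = k0[i];

  // transition table (built once; rates refilled every step)
  int src[28], dst[28];
  double rate[28];
  int nt = 0, na_nt = 0;
  if (na_stoch) {
    for (int j = 0; j <= 1; ++j) {
      for (int i = 0; i <= 2; ++i) { src[nt] = i + 4 * j; dst[nt] = i + 1 + 4 * j; ++nt; }
      for (int i = 1; i <= 3; ++i) { src[nt] = i + 4 * j; dst[nt] = i - 1 + 4 * j; ++nt; }
    }
    for (int i = 0; i <= 3; ++i) {
      src[nt] = i; dst[nt] = i + 4; ++nt;       // h0 -> h1 (alpha_h)
      src[nt] = i + 4; dst[nt] = i; ++nt;       // h1 -> h0 (beta_h)
    }
    na_nt = nt;  // 20
  }
  if (k_stoch) {
    for (int i = 0; i <= 3; ++i) { src[nt] = 8 + i; dst[nt] = 8 + i + 1; ++nt; }
    for (int i = 1; i <= 4; ++i) { src[nt] = 8 + i; dst[nt] = 8 + i - 1; ++nt; }
  }

  double v = v0, m = m0, h = h0, ngate = n0;
  double a[28];

  for (int t = 0; t < n; ++t) {
    const double am = f_alpha_m(v), bm = f_beta_m(v);
    const double ah = f_alpha_h(v), bh = f_beta_h(v);
    const double an = f_alpha_n(v), bn = f_beta_n(v);

    // conductances from the state at the start of the step
    double g_na_eff = 0.0;
    if (na_stoch) g_na_eff = gna * cnt[7] / nna;
    else if (na_det) g_na_eff = gna * m * m * m * h;
    double g_k_eff = k_stoch ? gk * cnt[12] / nk : gk * ngate * ngate * ngate * ngate;

    const double i_na = g_na_eff * (v - ena);
    const double i_k_dr = g_k_eff * (v - ek);
    const double i_leak = gl * (v - el);
    const double i_k_tot = i_k_dr + g_leak_k * (v - ek);

    v_out[t] = v;
    ik_out[t] = i_k_tot;
    if (record_extra) {
      open_na_out[t] = na_stoch ? cnt[7] / (double) nna : (na_det ? m * m * m * h : 0.0);
      open_k_out[t] = k_stoch ? cnt[12] / (double) nk : ngate * ngate * ngate * ngate;
      ina_out[t] = i_na;
    }

    // Euler voltage update
    v += dt_ms * (stim[t] - i_na - i_k_dr - i_leak) / cm;
    if (!std::isfinite(v) || v > 200.0 || v < -200.0) {
      stop("membrane potential diverged at step %d (V = %f mV)", t + 1, v);
    }

    // deterministic gating (Euler)
    if (na_det) {
      m += dt_ms * (am * (1.0 - m) - bm * m);
      h += dt_ms * (ah * (1.0 - h) - bh * h);
    }
    if (!k_stoch) ngate += dt_ms * (an * (1.0 - ngate) - bn * ngate);

    // stochastic gating: refill rates, exact Gillespie within the window
    if (nt > 0) {
      int k = 0;
      if (na_stoch) {
        for (int j = 0; j <= 1; ++j) {
          for (int i = 0; i <= 2; ++i) rate[k++] = (3 - i) * am;
          for (int i = 1; i <= 3; ++i) rate[k++] = i * bm;
        }
        for (int i = 0; i <= 3; ++i) { rate[k++] = ah; rate[k++] = bh; }
      }
      if (k_stoch) {
        for (int i = 0; i <= 3; ++i) rate[k++] = (4 - i) * an;
        for (int i = 1; i <= 4; ++i) rate[k++] = i * bn;
      }
      double rem = dt_ms;
      for (;;) {
        double lambda = 0.0;
        for (int kk = 0; kk < nt; ++kk) {
          a[kk] = rate[kk] * cnt[src[kk]];
          lambda += a[kk];
        }
        if (lambda <= 0.0) break;
        double u1 = unif_rand();
        if (u1 <= 0.0) u1 = 1e-300;
        double tw = -std::log(u1) / lambda;
        if (tw >= rem) break;
        rem -= tw;
        double u2 = unif_rand() * lambda;
        double cum = 0.0;
        int j = nt - 1;
        for (int kk = 0; kk < nt; ++kk) {
          cum += a[kk];
          if (u2 <= cum) { j = kk; break; }
        }
        cnt[src[j]] -= 1.0;
        cnt[dst[j]] += 1.0;
      }
    }
  }

  IntegerVector na_final(8), k_final(5);
  for (int i = 0; i < 8; ++i) na_final[i] = (int) cnt[i];
  for (int i = 0; i < 5; ++i) k_final[i] = (int) cnt[8 + i];

  List out = List::create(
    _["v"] = v_out, _["i_k"] = ik_out,
    _["na_final"] = na_final, _["k_final"] = k_final,
    _["gates_final"] = NumericVector::create(m, h, ngate));
  if (record_extra) {
    out["open_na"] = open_na_out;
    out["open_k"] = open_k_out;
    out["i_na"] = ina_out;
  }
  (void) na_nt;
  return out;
}
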