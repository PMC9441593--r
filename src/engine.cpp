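// Numerical core: implicit (theta-method) integration of the branched cable
// equation with Hodgkin-Huxley gates (Rush-Larsen update), six-state Markov
// calcium channels (backward Euler on the master equation) and double
// exponential synaptic conductances.  Units contract (package-wide): mV, ms,
// um, uS, nF, nA; membrane current inward-negative; permeability*area in
// cm^3/s; concentrations mM; temperature K.

#include <Rcpp.h>
#include <cmath>
#include <vector>
using namespace Rcpp;

struct Gate { double vh, k, tb, ta, tv, ts; };

static inline double gate_inf(const Gate& g, double v) {
  return 1.0 / (1.0 + std::exp(-(v - g.vh) / g.k));
}
static inline double gate_tau(const Gate& g, double v) {
  double z = (v - g.tv) / g.ts;
  return g.tb + g.ta * std::exp(-z * z);
}
static Gate as_gate(const NumericMatrix& gm, int row) {
  Gate g;
  g.vh = gm(row, 0); g.k = gm(row, 1); g.tb = gm(row, 2);
  g.ta = gm(row, 3); g.tv = gm(row, 4); g.ts = gm(row, 5);
  return g;
}

// GHK flux factor for a divalent ion: mA/cm^2 per unit permeability (cm/s),
// with concentrations in mM and temperature in K.
static inline double ghk2_factor(double v_mv, double ci, double co,
                                 double temp) {
  const double F = 96485.33212, R = 8.31446262;
  double u = 2.0 * F * (v_mv * 1e-3) / (R * temp);
  double num;
  if (std::fabs(u) < 1e-5) {
    num = (ci - co) + 0.5 * u * (ci + co);
  } else {
    num = u * (ci - co * std::exp(-u)) / (1.0 - std::exp(-u));
  }
  return 2.0 * F * 1e-3 * num;
}

// Chain transition rates for the six-state scheme C0<->C1<->C2<->C3<->C4<->O.
// fwd[k]: state k -> k+1 (k = 0..4), bwd[k]: state k+1 -> k.
static inline void chain_rates(const double* p, double v, double* fwd,
                               double* bwd) {
  // p: a, kf, b, kb, kon, koff
  double ef = std::exp(v / p[1]), eb = std::exp(-v / p[3]);
  for (int k = 0; k < 4; ++k) {
    fwd[k] = (4.0 - k) * p[0] * ef;
    bwd[k] = (k + 1.0) * p[2] * eb;
  }
  fwd[4] = p[4];
  bwd[4] = p[5];
}

// Stationary distribution of the birth-death chain (detailed balance).
static void chain_stationary(const double* p, double v, double* pi) {
  double fwd[5], bwd[5];
  chain_rates(p, v, fwd, bwd);
  double r[6];
  r[0] = 1.0;
  for (int k = 0; k < 5; ++k) r[k + 1] = r[k] * fwd[k] / bwd[k];
  double s = 0.0;
  for (int k = 0; k < 6; ++k) s += r[k];
  for (int k = 0; k < 6; ++k) pi[k] = r[k] / s;
}

// One backward-Euler step of the master equation dp/dt = Q^T p for the
// six-state chain.  The system (I - dt Q^T) p' = p is tridiagonal.
static void chain_be_step(const double* p, double v, double dt, double* occ) {
  double fwd[5], bwd[5];
  chain_rates(p, v, fwd, bwd);
  double diag[6], lo[6], up[6];
  for (int i = 0; i < 6; ++i) {
    double out = 0.0;
    if (i < 5) out += fwd[i];
    if (i > 0) out += bwd[i - 1];
    diag[i] = 1.0 + dt * out;
    lo[i] = (i > 0) ? -dt * fwd[i - 1] : 0.0;  // coeff of p_{i-1}
    up[i] = (i < 5) ? -dt * bwd[i] : 0.0;      // coeff of p_{i+1}
  }
  // Thomas algorithm
  double c[6], d[6];
  c[0] = up[0] / diag[0];
  d[0] = occ[0] / diag[0];
  for (int i = 1; i < 6; ++i) {
    double m = diag[i] - lo[i] * c[i - 1];
    c[i] = up[i] / m;
    d[i] = (occ[i] - lo[i] * d[i - 1]) / m;
  }
  occ[5] = d[5];
  for (int i = 4; i >= 0; --i) occ[i] = d[i] - c[i] * occ[i + 1];
}

// [[Rcpp::export]]
List engine_run_cpp(IntegerVector parent, NumericVector ga_us,
                    NumericVector cm_nf,
                    NumericVector g_leak_us, double e_leak,
                    NumericVector g_na_us, double e_na,
                    NumericVector g_k_us, double e_k,
                    NumericMatrix gates,
                    IntegerVector ca_comp, NumericMatrix ca_pa,
                    NumericMatrix ca_rates,
                    double cao, double cai, double temp,
                    NumericMatrix inj, NumericMatrix syn,
                    double dt, int nstep, double v_init, double theta,
                    LogicalVector clamped, NumericVector clamp_v,
                    IntegerVector rec_idx, IntegerVector rec_ca_rows,
                    int settle_steps = 0) {
  const int n = parent.size();
  const int nsub = ca_rates.ncol();
  const int nca = ca_comp.size();
  const int nrec = rec_idx.size();
  const int nrecca = rec_ca_rows.size();
  const bool has_clamp = clamp_v.size() > 0;

  Gate gm = as_gate(gates, 0), gh = as_gate(gates, 1);
  Gate gn = as_gate(gates, 2), ghk = as_gate(gates, 3);

  std::vector<double> rates(6 * nsub);
  for (int s = 0; s < nsub; ++s)
    for (int r = 0; r < 6; ++r) rates[6 * s + r] = ca_rates(r, s);

  // state
  std::vector<double> v(n), m(n), h(n), ng(n), hk(n);
  std::vector<double> occ(nca * nsub * 6, 0.0);
  double v0 = has_clamp ? clamp_v[0] : v_init;
  for (int i = 0; i < n; ++i) {
    v[i] = (has_clamp && clamped[i]) ? clamp_v[0] : v_init;
    double vi = v[i];
    m[i] = gate_inf(gm, vi); h[i] = gate_inf(gh, vi);
    ng[i] = gate_inf(gn, vi); hk[i] = gate_inf(ghk, vi);
  }
  (void)v0;
  for (int c = 0; c < nca; ++c) {
    double vi = v[ca_comp[c]];
    for (int s = 0; s < nsub; ++s)
      chain_stationary(&rates[6 * s], vi, &occ[(c * nsub + s) * 6]);
  }

  // recordings
  NumericVector tvec(nstep + 1);
  NumericMatrix vrec(nstep + 1, nrec), inarec(nstep + 1, nrec),
      ikrec(nstep + 1, nrec);
  List icarec(nrecca);
  std::vector<NumericMatrix> icam;
  for (int r = 0; r < nrecca; ++r) {
    NumericMatrix mm(nstep + 1, nsub + 1);
    icarec[r] = mm;
    icam.push_back(mm);
  }
  NumericMatrix occrec =
      (nrecca > 0) ? NumericMatrix(nstep + 1, 6 * nsub) : NumericMatrix(0, 0);

  double occ_err_max = 0.0, resid_max = 0.0;

  // work arrays
  std::vector<double> diag(n), off(n), rhs(n), diag0(n), rhs0(n), gtot(n),
      be(n), iext(n), axial_old(n);

  // record helper (uses current state and voltages)
  auto record = [&](int row) {
    tvec[row] = row * dt;
    for (int r = 0; r < nrec; ++r) {
      int i = rec_idx[r];
      vrec(row, r) = v[i];
      double m3h = m[i] * m[i] * m[i] * h[i];
      double n4 = ng[i] * ng[i]; n4 *= n4;
      inarec(row, r) = g_na_us[i] * m3h * (v[i] - e_na);
      ikrec(row, r) = g_k_us[i] * n4 * hk[i] * (v[i] - e_k);
    }
    for (int r = 0; r < nrecca; ++r) {
      int c = rec_ca_rows[r];
      int i = ca_comp[c];
      double fac = ghk2_factor(v[i], cai, cao, temp);
      double tot = 0.0;
      for (int s = 0; s < nsub; ++s) {
        double cur = ca_pa(c, s) * occ[(c * nsub + s) * 6 + 5] * fac * 1e6;
        icam[r](row, s) = cur;
        tot += cur;
      }
      icam[r](row, nsub) = tot;
    }
    if (nrecca > 0) {
      int c = rec_ca_rows[0];
      for (int s = 0; s < nsub; ++s)
        for (int k = 0; k < 6; ++k)
          occrec(row, 6 * s + k) = occ[(c * nsub + s) * 6 + k];
    }
  };
  record(0);

  // settle phase runs with negative clock so no stimulus is active yet
  for (int step = -settle_steps; step < nstep; ++step) {
    double t = step * dt;
    double tsrc = t + theta * dt;
    double cmd = has_clamp ? clamp_v[std::max(step + 1, 0)] : 0.0;

    // 1. gate update (Rush-Larsen) at the present voltage (for a clamped
    // compartment the command is imposed over the coming step)
    for (int i = 0; i < n; ++i) {
      double vi = (has_clamp && clamped[i]) ? cmd : v[i];
      if (g_na_us[i] > 0.0) {
        double inf = gate_inf(gm, vi);
        m[i] = inf + (m[i] - inf) * std::exp(-dt / gate_tau(gm, vi));
        inf = gate_inf(gh, vi);
        h[i] = inf + (h[i] - inf) * std::exp(-dt / gate_tau(gh, vi));
      }
      if (g_k_us[i] > 0.0) {
        double inf = gate_inf(gn, vi);
        ng[i] = inf + (ng[i] - inf) * std::exp(-dt / gate_tau(gn, vi));
        inf = gate_inf(ghk, vi);
        hk[i] = inf + (hk[i] - inf) * std::exp(-dt / gate_tau(ghk, vi));
      }
    }

    // 2. Markov update (backward Euler) at the present voltage
    for (int c = 0; c < nca; ++c) {
      int i = ca_comp[c];
      double vi = (has_clamp && clamped[i]) ? cmd : v[i];
      for (int s = 0; s < nsub; ++s) {
        double* p = &occ[(c * nsub + s) * 6];
        chain_be_step(&rates[6 * s], vi, dt, p);
        double sum = 0.0;
        for (int k = 0; k < 6; ++k) sum += p[k];
        double err = std::fabs(sum - 1.0);
        if (err > occ_err_max) occ_err_max = err;
        if (err > 1e-10)
          for (int k = 0; k < 6; ++k) p[k] /= sum;
      }
    }

    // 3. linearized ionic terms and external currents
    for (int i = 0; i < n; ++i) {
      double m3h = m[i] * m[i] * m[i] * h[i];
      double n4 = ng[i] * ng[i]; n4 *= n4;
      double gna = g_na_us[i] * m3h, gk = g_k_us[i] * n4 * hk[i];
      gtot[i] = g_leak_us[i] + gna + gk;
      be[i] = g_leak_us[i] * e_leak + gna * e_na + gk * e_k;
      iext[i] = 0.0;
    }
    for (int s = 0; s < syn.nrow(); ++s) {
      double onset = syn(s, 4);
      if (tsrc < onset) continue;
      double tr = syn(s, 2), td = syn(s, 3);
      double tp = tr * td / (td - tr) * std::log(td / tr);
      double norm = 1.0 / (std::exp(-tp / td) - std::exp(-tp / tr));
      double g = syn(s, 1) * norm *
                 (std::exp(-(tsrc - onset) / td) - std::exp(-(tsrc - onset) / tr));
      int i = (int)syn(s, 0);
      gtot[i] += g;
      be[i] += g * syn(s, 5);
    }
    for (int s = 0; s < inj.nrow(); ++s) {
      if (tsrc >= inj(s, 1) && tsrc < inj(s, 1) + inj(s, 2))
        iext[(int)inj(s, 0)] += inj(s, 3);
    }
    // explicit calcium current at the present voltage (negligible feedback)
    for (int c = 0; c < nca; ++c) {
      int i = ca_comp[c];
      double fac = ghk2_factor(v[i], cai, cao, temp);
      for (int s = 0; s < nsub; ++s)
        iext[i] -= ca_pa(c, s) * occ[(c * nsub + s) * 6 + 5] * fac * 1e6;
    }

    // 4. assemble theta-system
    for (int i = 0; i < n; ++i) {
      axial_old[i] = 0.0;
      off[i] = 0.0;
    }
    for (int i = 1; i < n; ++i) {
      int p = parent[i];
      double a = ga_us[i];
      axial_old[i] += a * (v[i] - v[p]);
      axial_old[p] += a * (v[p] - v[i]);
    }
    for (int i = 0; i < n; ++i) {
      diag[i] = cm_nf[i] / dt + theta * gtot[i];
      rhs[i] = cm_nf[i] / dt * v[i] + be[i] - (1.0 - theta) * gtot[i] * v[i] -
               (1.0 - theta) * axial_old[i] + iext[i];
    }
    for (int i = 1; i < n; ++i) {
      int p = parent[i];
      double a = ga_us[i];
      bool ci = clamped[i], cp = clamped[p];
      if (!ci && !cp) {
        diag[i] += theta * a;
        diag[p] += theta * a;
        off[i] = -theta * a;
      } else if (ci && !cp) {
        diag[p] += theta * a;
        rhs[p] += theta * a * cmd;
      } else if (!ci && cp) {
        diag[i] += theta * a;
        rhs[i] += theta * a * cmd;
      }
    }
    for (int i = 0; i < n; ++i) {
      if (clamped[i]) {
        diag[i] = 1.0;
        rhs[i] = cmd;
        off[i] = 0.0;
      }
    }
    for (int i = 0; i < n; ++i) { diag0[i] = diag[i]; rhs0[i] = rhs[i]; }

    // 5. Hines solve (parent index < child index by construction)
    for (int i = n - 1; i >= 1; --i) {
      if (off[i] == 0.0) continue;
      int p = parent[i];
      double f = off[i] / diag[i];
      diag[p] -= f * off[i];
      rhs[p] -= f * rhs[i];
    }
    v[0] = rhs[0] / diag[0];
    for (int i = 1; i < n; ++i)
      v[i] = (off[i] == 0.0) ? rhs[i] / diag[i]
                             : (rhs[i] - off[i] * v[parent[i]]) / diag[i];

    if (!std::isfinite(v[0]))
      stop("integration failure (non-finite state) at t = %f ms", t + dt);

    // residual of the linear system (audit)
    {
      std::vector<double> r(n);
      for (int i = 0; i < n; ++i) r[i] = diag0[i] * v[i] - rhs0[i];
      for (int i = 1; i < n; ++i) {
        if (off[i] == 0.0) continue;
        int p = parent[i];
        r[i] += off[i] * v[p];
        r[p] += off[i] * v[i];
      }
      for (int i = 0; i < n; ++i)
        if (std::fabs(r[i]) > resid_max) resid_max = std::fabs(r[i]);
    }

    if (step >= -1) record(step + 1 < 0 ? 0 : step + 1);
  }

  NumericVector vfin(n);
  for (int i = 0; i < n; ++i) vfin[i] = v[i];

  return List::create(_["t"] = tvec, _["v"] = vrec, _["ina"] = inarec,
                      _["ik"] = ikrec, _["ica"] = icarec, _["occ"] = occrec,
                      _["occ_err_max"] = occ_err_max,
                      _["resid_max"] = resid_max, _["v_final"] = vfin);
}

// [[Rcpp::export]]
NumericVector chain_stationary_cpp(NumericVector rates, double v) {
  NumericVector out(6);
  double p[6];
  chain_stationary(REAL(rates), v, p);
  for (int k = 0; k < 6; ++k) out[k] = p[k];
  return out;
}

// [[Rcpp::export]]
double ghk2_factor_cpp(double v_mv, double ci, double co, double temp) {
  return ghk2_factor(v_mv, ci, co, temp);
}
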