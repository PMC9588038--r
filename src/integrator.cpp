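// Fast fixed-step RK4 integrator for the two-layer box-model ecosystem.
// Mirrors the R reference implementation in R/core.R (rhs_core) exactly;
// the two routes are cross-checked in the test suite.
#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

namespace {

struct Model {
  int n;                       // number of columns
  // parameters
  double J_O_max, J_D_max, k_N, k_P, k_P_d, mu_max;
  double theta_o, theta_d, theta_det, T_min_diaz;
  double r_NP, r_CN, chl_per_N;
  double mortality, remin_surface, remin_deep;
  double z_assim, z_excrete, z_mort, det_sink, f_denit, fix_pow;
  bool holling_saturating;
  double k_graze;
  // geometry
  std::vector<double> area, temp0, w_mix, iron, J0, Jamp, phase, denit_flag;
  std::vector<double> V_s, V_d;
  std::vector<int> e_from, e_to;
  std::vector<double> e_qs, e_qd;
  // configuration / forcing
  bool warming, denit_enabled;
  double year0, ys, ye, dT, mixred;

  inline double ramp(double t) const {
    if (!warming) return 0.0;
    double x = (year0 + t / 365.0 - ys) / (ye - ys);
    if (x < 0.0) x = 0.0;
    if (x > 1.0) x = 1.0;
    return x * x;
  }

  // y layout: idx = i + n*tracer + 6n*layer, tracers NO3 PO4 PhyO PhyD Zoo Det
  void rhs(double t, const double* y, double* dy,
           double* fix, double* den) const {
    const int n6 = 6 * n;
    double w = ramp(t);
    double season = t / 365.0;
    for (int i = 0; i < n; ++i) {
      const double NO3s = std::max(y[i], 0.0);
      const double PO4s = std::max(y[i + n], 0.0);
      const double PhyOs = std::max(y[i + 2 * n], 0.0);
      const double PhyDs = std::max(y[i + 3 * n], 0.0);
      const double Zoos = std::max(y[i + 4 * n], 0.0);
      const double Dets = std::max(y[i + 5 * n], 0.0);
      const double NO3d = std::max(y[i + n6], 0.0);
      const double PO4d = std::max(y[i + n6 + n], 0.0);
      const double PhyOd = std::max(y[i + n6 + 2 * n], 0.0);
      const double PhyDd = std::max(y[i + n6 + 3 * n], 0.0);
      const double Zood = std::max(y[i + n6 + 4 * n], 0.0);
      const double Detd = std::max(y[i + n6 + 5 * n], 0.0);
      (void)NO3d;

      const double temp_s = temp0[i] + dT * w;
      const double J_IO = std::max(
          J0[i] * (1.0 + Jamp[i] * std::sin(2.0 * M_PI * (season - phase[i]))),
          0.0);
      const double JmaxO = J_O_max * iron[i];
      const double JmaxD = J_D_max * iron[i];

      double J_O = std::min(J_IO, JmaxO * NO3s / (k_N + NO3s));
      J_O = std::min(J_O, JmaxO * PO4s / (k_P + PO4s));
      double J_D = std::min(J_IO, JmaxD * PO4s / (k_P_d + PO4s));
      if (temp_s < T_min_diaz) J_D = 0.0;

      const double G_O = J_O * PhyOs;
      const double G_D = J_D * PhyDs;
      const double f_fix = std::pow(k_N / (k_N + NO3s), fix_pow);
      const double fixation = G_D * f_fix;
      const double no3_uptake = G_O + G_D * (1.0 - f_fix);
      const double po4_uptake = (G_O + G_D) / r_NP;

      double denom = 1.0;
      if (holling_saturating)
        denom = 1.0 + (theta_o * PhyOs + theta_d * PhyDs +
                       theta_det * Dets) / k_graze;
      const double gr_O = mu_max * Zoos * theta_o * PhyOs / denom;
      const double gr_D = mu_max * Zoos * theta_d * PhyDs / denom;
      const double gr_Det = mu_max * Zoos * theta_det * Dets / denom;
      const double gr_tot = gr_O + gr_D + gr_Det;

      const double remin_s = remin_surface * Dets;
      const double excr_s = z_excrete * Zoos;
      const double sink = det_sink * Dets;

      dy[i] = -no3_uptake + remin_s + excr_s;
      dy[i + n] = -po4_uptake + (remin_s + excr_s) / r_NP;
      dy[i + 2 * n] = G_O - gr_O - mortality * PhyOs;
      dy[i + 3 * n] = G_D - gr_D - mortality * PhyDs;
      dy[i + 4 * n] = z_assim * gr_tot - (z_excrete + z_mort) * Zoos;
      dy[i + 5 * n] = mortality * (PhyOs + PhyDs) +
        (1.0 - z_assim) * gr_tot + z_mort * Zoos - gr_Det - remin_s - sink;

      const double remin_d = remin_deep * Detd;
      const double excr_d = z_excrete * Zood;
      const double denit = denit_enabled
        ? f_denit * remin_d * denit_flag[i] : 0.0;

      dy[i + n6] = remin_d - denit + excr_d;
      dy[i + n6 + n] = (remin_d + excr_d) / r_NP;
      dy[i + n6 + 2 * n] = -mortality * PhyOd;
      dy[i + n6 + 3 * n] = -mortality * PhyDd;
      dy[i + n6 + 4 * n] = -(z_excrete + z_mort) * Zood;
      dy[i + n6 + 5 * n] = sink * V_s[i] / V_d[i] +
        mortality * (PhyOd + PhyDd) + z_mort * Zood - remin_d;

      fix[i] = fixation;
      den[i] = denit;
    }
    // transport on raw (unclamped) state: vertical then lateral exchange
    for (int k = 0; k < 6; ++k) {
      const double* cs = y + k * n;
      const double* cd = y + n6 + k * n;
      double* ds = dy + k * n;
      double* dd = dy + n6 + k * n;
      for (int i = 0; i < n; ++i) {
        const double qv = w_mix[i] / 365.0 * area[i] * (1.0 - mixred * w);
        ds[i] += qv / V_s[i] * (cd[i] - cs[i]);
        dd[i] += qv / V_d[i] * (cs[i] - cd[i]);
      }
      for (size_t j = 0; j < e_from.size(); ++j) {
        const int i1 = e_from[j], i2 = e_to[j];
        ds[i1] += e_qs[j] / V_s[i1] * (cs[i2] - cs[i1]);
        ds[i2] += e_qs[j] / V_s[i2] * (cs[i1] - cs[i2]);
        dd[i1] += e_qd[j] / V_d[i1] * (cd[i2] - cd[i1]);
        dd[i2] += e_qd[j] / V_d[i2] * (cd[i1] - cd[i2]);
      }
    }
  }
};

Model build_model(List par, List geom, List cfg) {
  Model m;
  NumericVector area = geom["area"];
  m.n = area.size();
  m.J_O_max = par["J_O_max"]; m.J_D_max = par["J_D_max"];
  m.k_N = par["k_N"]; m.k_P = par["k_P"]; m.k_P_d = par["k_P_d"];
  m.mu_max = par["mu_max"]; m.theta_o = par["theta_o"];
  m.theta_d = par["theta_d"]; m.theta_det = par["theta_det"];
  m.T_min_diaz = par["T_min_diaz"]; m.r_NP = par["r_NP"];
  m.r_CN = par["r_CN"]; m.chl_per_N = par["chl_per_N"];
  m.mortality = par["mortality"]; m.remin_surface = par["remin_surface"];
  m.remin_deep = par["remin_deep"]; m.z_assim = par["z_assim"];
  m.z_excrete = par["z_excrete"]; m.z_mort = par["z_mort"];
  m.det_sink = par["det_sink"]; m.f_denit = par["f_denit"];
  m.fix_pow = par["fix_pow"];
  m.holling_saturating = as<bool>(par["holling_saturating"]);
  m.k_graze = par["k_graze"];

  m.area = as<std::vector<double> >(geom["area"]);
  m.temp0 = as<std::vector<double> >(geom["temp"]);
  m.w_mix = as<std::vector<double> >(geom["w_mix"]);
  m.iron = as<std::vector<double> >(geom["iron"]);
  m.J0 = as<std::vector<double> >(geom["J0"]);
  m.Jamp = as<std::vector<double> >(geom["J_amp"]);
  m.denit_flag = as<std::vector<double> >(geom["denit_flag"]);
  m.V_s = as<std::vector<double> >(geom["V_s"]);
  m.V_d = as<std::vector<double> >(geom["V_d"]);
  NumericVector lat = geom["lat"];
  m.phase.resize(m.n);
  for (int i = 0; i < m.n; ++i) m.phase[i] = lat[i] >= 0 ? 0.22 : 0.72;
  IntegerVector ef = geom["e_from"], et = geom["e_to"];
  NumericVector eqs = geom["e_qs"], eqd = geom["e_qd"];
  m.e_from = as<std::vector<int> >(ef);
  m.e_to = as<std::vector<int> >(et);
  m.e_qs = as<std::vector<double> >(eqs);
  m.e_qd = as<std::vector<double> >(eqd);

  m.warming = as<bool>(cfg["warming"]);
  m.denit_enabled = as<bool>(cfg["denit_enabled"]);
  m.year0 = cfg["year0"]; m.ys = cfg["start_year"]; m.ye = cfg["end_year"];
  m.dT = cfg["dT_surface"]; m.mixred = cfg["mix_reduction"];
  return m;
}

} // namespace

// [[Rcpp::export(name = ".cpp_run")]]
List cpp_run(NumericVector y0, List par, List geom, List cfg,
             int n_years, double dt, double clip_eps,
             bool record_snapshots) {
  Model m = build_model(par, geom, cfg);
  const int n = m.n, ny = 12 * n;
  if (y0.size() != ny) stop("state length does not match geometry");
  const int spy = (int)std::lround(365.0 / dt);
  if (std::fabs(spy * dt - 365.0) > 1e-9)
    stop("dt must divide the 365-day year exactly");

  std::vector<double> y(y0.begin(), y0.end());
  std::vector<double> k1(ny), k2(ny), k3(ny), k4(ny), tmp(ny);
  std::vector<double> f1(n), f2(n), f3(n), f4(n);
  std::vector<double> d1(n), d2(n), d3(n), d4(n);

  NumericMatrix annual(n_years, 8);
  colnames(annual) = CharacterVector::create(
      "year", "fixation_TgN_yr", "denit_TgN_yr", "biomass_diaz_TgC",
      "biomass_ord_TgC", "N_mol", "P_mol", "excessP_molN");
  NumericMatrix chl(n_years, n);
  NumericMatrix fix_box(n_years, n);
  NumericMatrix snaps(record_snapshots ? n_years : 1,
                      record_snapshots ? ny : 1);

  const double molN_to_TgN = 1e-3 * 14.0 * 1e-12 * 1e3; // mmol->Tg via mol
  // (mmol m^-3 d^-1 * m^3 = mmol d^-1; *1e-3 -> mol; *14 -> g; *1e-12 -> Tg)
  const double mmol_to_TgN = 1e-3 * 14.0 * 1e-12;
  const double mmol_to_TgC = 1e-3 * m.r_CN * 12.0 * 1e-12;
  (void)molN_to_TgN;

  double clipped_total = 0.0;
  double t = 0.0;

  for (int yr = 0; yr < n_years; ++yr) {
    double fix_year = 0.0, den_year = 0.0;   // Tg N per year
    std::vector<double> fixb(n, 0.0);
    std::vector<double> ymean(ny, 0.0);
    for (int s = 0; s < spy; ++s) {
      m.rhs(t, y.data(), k1.data(), f1.data(), d1.data());
      for (int i = 0; i < ny; ++i) tmp[i] = y[i] + 0.5 * dt * k1[i];
      m.rhs(t + 0.5 * dt, tmp.data(), k2.data(), f2.data(), d2.data());
      for (int i = 0; i < ny; ++i) tmp[i] = y[i] + 0.5 * dt * k2[i];
      m.rhs(t + 0.5 * dt, tmp.data(), k3.data(), f3.data(), d3.data());
      for (int i = 0; i < ny; ++i) tmp[i] = y[i] + dt * k3[i];
      m.rhs(t + dt, tmp.data(), k4.data(), f4.data(), d4.data());
      for (int i = 0; i < ny; ++i)
        y[i] += dt / 6.0 * (k1[i] + 2.0 * k2[i] + 2.0 * k3[i] + k4[i]);

      // clip small negatives; hard error on large excursions
      for (int i = 0; i < ny; ++i) {
        if (y[i] < 0.0) {
          if (y[i] < -clip_eps)
            stop("negative tracer excursion %g mmol/m3 exceeds clip_eps = %g "
                 "at t = %g d; reduce dt", y[i], clip_eps, t);
          const int col = i % n;
          const double V = (i / (6 * n) == 0) ? m.V_s[col] : m.V_d[col];
          clipped_total += -y[i] * V * 1e-3;
          y[i] = 0.0;
        }
      }

      for (int i = 0; i < n; ++i) {
        const double fx = dt / 6.0 *
          (f1[i] + 2.0 * f2[i] + 2.0 * f3[i] + f4[i]) * m.V_s[i];
        const double dn = dt / 6.0 *
          (d1[i] + 2.0 * d2[i] + 2.0 * d3[i] + d4[i]) * m.V_d[i];
        fix_year += fx * mmol_to_TgN;
        fixb[i] += fx * mmol_to_TgN;
        den_year += dn * mmol_to_TgN;
      }
      const double wgt = dt / 365.0;
      for (int i = 0; i < ny; ++i) ymean[i] += y[i] * wgt;
      t += dt;
    }

    double bD = 0.0, bO = 0.0, Nmol = 0.0, Pmol = 0.0, bio = 0.0;
    for (int i = 0; i < n; ++i) {
      bD += (ymean[i + 3 * n] * m.V_s[i] + ymean[i + 6 * n + 3 * n] * m.V_d[i]);
      bO += (ymean[i + 2 * n] * m.V_s[i] + ymean[i + 6 * n + 2 * n] * m.V_d[i]);
      chl(yr, i) = m.chl_per_N * (ymean[i + 2 * n] + ymean[i + 3 * n]);
      fix_box(yr, i) = fixb[i];
      for (int k = 0; k < 6; ++k) {
        const double vs = y[i + k * n] * m.V_s[i];
        const double vd = y[i + 6 * n + k * n] * m.V_d[i];
        if (k == 0) Nmol += vs + vd;
        else if (k == 1) Pmol += vs + vd;
        else { bio += vs + vd; }
      }
    }
    Nmol = (Nmol + bio) * 1e-3;
    Pmol = Pmol * 1e-3 + bio * 1e-3 / m.r_NP;
    annual(yr, 0) = m.year0 + (yr + 1);
    annual(yr, 1) = fix_year;
    annual(yr, 2) = den_year;
    annual(yr, 3) = bD * mmol_to_TgC;
    annual(yr, 4) = bO * mmol_to_TgC;
    annual(yr, 5) = Nmol;
    annual(yr, 6) = Pmol;
    annual(yr, 7) = m.r_NP * Pmol - Nmol;
    if (record_snapshots)
      for (int i = 0; i < ny; ++i) snaps(yr, i) = ymean[i];
  }

  return List::create(
    _["state_final"] = NumericVector(y.begin(), y.end()),
    _["annual"] = annual,
    _["chl"] = chl,
    _["fix_box"] = fix_box,
    _["snapshots"] = record_snapshots ? snaps : NumericMatrix(0, 0),
    _["clipped_mol"] = clipped_total);
}
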