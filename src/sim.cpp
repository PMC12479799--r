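#include <Rcpp.h>
using namespace Rcpp;

// Fixed-step RK4 integrator for the glucoregulatory model.
//
// State (7): S1, S2 (subcutaneous rapid insulin, mU), I (plasma insulin,
// mU/L), X (remote insulin action, 1/min), Q1, Q2 (gut glucose, mmol),
// G (plasma glucose, mmol/L).
//
// Parameters (11): SI (1/min per mU/L), SG (1/min), Gb (mmol/L),
// p2 (1/min), tauI (min), ke (1/min), VI (L), kb ((mU/L)/(U/day)),
// taum (min), VG (L), B (basal dose, U/day).
//
// Rapid boluses are impulses into S1 (dose U * 1000 -> mU); meals are
// impulses into Q1 (mmol, bioavailability already applied by the caller).
// The once-daily long-acting basal is modelled as the constant plasma
// contribution kb*B.
//
// An impulse at time t is applied at the first grid point >= t within
// [t0, t1); segment chaining relies on this convention.

static inline void deriv(const double *s, double *ds, const double *p) {
  const double SI = p[0], SG = p[1], Gb = p[2], p2 = p[3], tauI = p[4],
               ke = p[5], VI = p[6], kb = p[7], taum = p[8], VG = p[9],
               B = p[10];
  ds[0] = -s[0] / tauI;                       // S1
  ds[1] = (s[0] - s[1]) / tauI;               // S2
  ds[2] = s[1] / (tauI * VI) - ke * s[2];     // I
  ds[3] = -p2 * s[3] + p2 * SI * (s[2] + kb * B); // X
  ds[4] = -s[4] / taum;                       // Q1
  ds[5] = (s[4] - s[5]) / taum;               // Q2
  ds[6] = -(SG + s[3]) * s[6] + SG * Gb + s[5] / (taum * VG); // G
}

// [[Rcpp::export(name = ".sim_gluco_cpp")]]
NumericMatrix sim_gluco_cpp(double t0, double t1, double dt,
                            NumericVector state0, NumericVector params,
                            NumericMatrix boluses, NumericMatrix meals) {
  if (state0.size() != 7) stop("state0 must have 7 elements");
  if (params.size() != 11) stop("params must have 11 elements");
  if (dt <= 0 || t1 <= t0) stop("need dt > 0 and t1 > t0");

  const int n_steps = (int)std::round((t1 - t0) / dt);
  const double p[11] = {params[0], params[1], params[2], params[3], params[4],
                        params[5], params[6], params[7], params[8], params[9],
                        params[10]};
  double s[7];
  for (int i = 0; i < 7; ++i) s[i] = state0[i];

  // map impulses to grid indices (first grid point >= event time)
  std::vector<std::vector<double> > bolus_at(n_steps + 1), meal_at(n_steps + 1);
  for (int i = 0; i < boluses.nrow(); ++i) {
    double et = boluses(i, 0);
    if (et < t0 - 1e-9 || et >= t1 - 1e-9) continue;
    int idx = (int)std::ceil((et - t0) / dt - 1e-9);
    if (idx < 0) idx = 0;
    if (idx <= n_steps) bolus_at[idx].push_back(boluses(i, 1) * 1000.0);
  }
  for (int i = 0; i < meals.nrow(); ++i) {
    double et = meals(i, 0);
    if (et < t0 - 1e-9 || et >= t1 - 1e-9) continue;
    int idx = (int)std::ceil((et - t0) / dt - 1e-9);
    if (idx < 0) idx = 0;
    if (idx <= n_steps) meal_at[idx].push_back(meals(i, 1));
  }

  NumericMatrix out(n_steps + 1, 8);
  double k1[7], k2[7], k3[7], k4[7], tmp[7];

  for (int step = 0; step <= n_steps; ++step) {
    for (size_t j = 0; j < bolus_at[step].size(); ++j) s[0] += bolus_at[step][j];
    for (size_t j = 0; j < meal_at[step].size(); ++j) s[4] += meal_at[step][j];

    out(step, 0) = t0 + step * dt;
    for (int i = 0; i < 7; ++i) out(step, i + 1) = s[i];
    if (!R_finite(s[6]))
      stop("integration failure: non-finite glucose at t=%f", t0 + step * dt);
    if (step == n_steps) break;

    deriv(s, k1, p);
    for (int i = 0; i < 7; ++i) tmp[i] = s[i] + 0.5 * dt * k1[i];
    deriv(tmp, k2, p);
    for (int i = 0; i < 7; ++i) tmp[i] = s[i] + 0.5 * dt * k2[i];
    deriv(tmp, k3, p);
    for (int i = 0; i < 7; ++i) tmp[i] = s[i] + dt * k3[i];
    deriv(tmp, k4, p);
    for (int i = 0; i < 7; ++i)
      s[i] += dt / 6.0 * (k1[i] + 2 * k2[i] + 2 * k3[i] + k4[i]);
    if (s[6] < 0.1) s[6] = 0.1;  // physiological floor
  }

  colnames(out) = CharacterVector::create("time", "S1", "S2", "I", "X",
                                          "Q1", "Q2", "G");
  return out;
}
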