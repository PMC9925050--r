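// Monte-Carlo engines for the rectified urgency race and the DDM benchmark.
//
// Randomness is counter-based: every trial owns an independent splitmix64
// stream seeded from (seed, cell, trial index), so a fit using common random
// numbers re-uses exactly the same draws for every parameter proposal, and
// identical (params, seed) calls are byte-identical regardless of how many
// trials other cells consumed.

#include <Rcpp.h>
#include <cstdint>
#include <cmath>
using namespace Rcpp;

namespace {

struct Rng {
  uint64_t s;
};

inline uint64_t rng_next(Rng &r) {
  uint64_t z = (r.s += 0x9E3779B97F4A7C15ULL);
  z = (z ^ (z >> 30)) * 0xBF58476D1CE4E5B9ULL;
  z = (z ^ (z >> 27)) * 0x94D049BB133111EBULL;
  return z ^ (z >> 31);
}

inline uint64_t mix64(uint64_t z) {
  z = (z ^ (z >> 30)) * 0xBF58476D1CE4E5B9ULL;
  z = (z ^ (z >> 27)) * 0x94D049BB133111EBULL;
  return z ^ (z >> 31);
}

// One stream per (seed, cell, trial): scrambled so streams are uncorrelated.
inline Rng trial_rng(uint64_t seed, uint64_t cell, uint64_t trial) {
  uint64_t s = mix64(seed + 0x9E3779B97F4A7C15ULL * (cell + 1));
  s = mix64(s ^ (0xBF58476D1CE4E5B9ULL * (trial + 1)));
  Rng r;
  r.s = s;
  return r;
}

inline double runif01(Rng &r) {
  return (rng_next(r) >> 11) * (1.0 / 9007199254740992.0);
}

// Marsaglia-Tsang ziggurat for standard normals (128 layers).
static double zig_wn[128], zig_fn[128];
static uint32_t zig_kn[128];
static bool zig_ready = false;

void zig_init() {
  double dn = 3.442619855899, tn = dn, vn = 9.91256303526217e-3;
  const double m1 = 2147483648.0;
  double q = vn / std::exp(-0.5 * dn * dn);
  zig_kn[0] = (uint32_t)((dn / q) * m1);
  zig_kn[1] = 0;
  zig_wn[0] = q / m1;
  zig_wn[127] = dn / m1;
  zig_fn[0] = 1.0;
  zig_fn[127] = std::exp(-0.5 * dn * dn);
  for (int i = 126; i >= 1; i--) {
    dn = std::sqrt(-2.0 * std::log(vn / dn + std::exp(-0.5 * dn * dn)));
    zig_kn[i + 1] = (uint32_t)((dn / tn) * m1);
    tn = dn;
    zig_fn[i] = std::exp(-0.5 * dn * dn);
    zig_wn[i] = dn / m1;
  }
  zig_ready = true;
}

inline double rnorm_std(Rng &r) {
  const double zr = 3.442619855899;
  for (;;) {
    uint64_t u = rng_next(r);
    int32_t hz = (int32_t)(u >> 32);
    int i = (int)(u & 127);
    double x = hz * zig_wn[i];
    uint32_t iz = (hz < 0) ? (uint32_t)(-(int64_t)hz) : (uint32_t)hz;
    if (iz < zig_kn[i]) return x;
    if (i == 0) {  // tail
      double xx, yy;
      do {
        xx = -std::log(runif01(r)) / zr;
        yy = -std::log(runif01(r));
      } while (yy + yy < xx * xx);
      return hz > 0 ? zr + xx : -(zr + xx);
    }
    if (zig_fn[i] + runif01(r) * (zig_fn[i - 1] - zig_fn[i]) <
        std::exp(-0.5 * x * x))
      return x;
  }
}

struct TrialDraws {
  double u1, u2, z1, z2, burstT, motor, tev, tz;
  int soa_idx;
};

// integral of a unit indicator over the step (t - dt, t] intersected with
// [w0, w1]; used so piecewise-constant drifts are integrated exactly and the
// Euler drift has no O(dt) bias at window edges
inline double step_overlap(double t, double dt, double w0, double w1) {
  double lo = std::max(t - dt, w0);
  double hi = std::min(t, w1);
  return hi > lo ? hi - lo : 0.0;
}

// Fixed draw order (documented contract): u1, u2, [z1, z2 perturbations],
// [burstT], motor, [T_ev perturbation].  SOA alternates deterministically with
// trial parity so the 50/50 split is exact and stable under CRN.
inline TrialDraws draw_trial(Rng &r, int trial,
                             double z1m, double z2m, double u1m, double u2m,
                             double s_u, double s_Z, int bias_kind,
                             double b_range, double T_r, double s_t,
                             double T_ev, double sT_ev,
                             const NumericVector &tz_options) {
  TrialDraws d;
  d.u1 = u1m + s_u * rnorm_std(r);
  d.u2 = u2m + s_u * rnorm_std(r);
  d.z1 = z1m;
  d.z2 = z2m;
  if (s_Z > 0) {
    d.z1 += s_Z * (runif01(r) - 0.5);
    d.z2 += s_Z * (runif01(r) - 0.5);
  }
  d.burstT = (bias_kind == 2) ? b_range * runif01(r) : 0.0;
  d.motor = T_r + s_t * (runif01(r) - 0.5);
  if (d.motor < 0) d.motor = 0;  // clip, counted by caller
  d.tev = T_ev + ((sT_ev > 0) ? sT_ev * (runif01(r) - 0.5) : 0.0);
  d.soa_idx = (tz_options.size() > 1) ? (trial & 1) : 0;
  d.tz = tz_options[d.soa_idx];
  return d;
}

}  // namespace

// Race simulator for one condition-by-value cell.
//
// nu and nu_b are passed already signed toward the correct response (DV1):
// nu >= 0, nu_b positive on high-value trials and negative on low-value ones.
// evidence_kind: 0 = stationary (step at T_ev), 1 = increasing (mu_vec /
// sigma_vec are per-step lookups on the grid t = 0, dt, 2 dt, ...).
// bias_kind: 0 none, 1 sustained, 2 burst.
// Outcome codes: 0 nonresponse, 1 correct, 2 error.  rt is NA for
// nonresponses; fast-guess exclusion (rt < 50 ms) is applied by the R caller.
// [[Rcpp::export]]
List sim_race_cell_cpp(int n, double seed, int cell_id,
                       double z1m, double z2m, double u1m, double u2m,
                       double s_u,
                       double nu, double nu_b, int bias_kind, double b_range,
                       int evidence_kind, double s, double T_ev, double sT_ev,
                       NumericVector mu_vec, NumericVector sigma_vec,
                       double T_ac, double s_Z,
                       double T_r, double s_t,
                       NumericVector tz_options, IntegerVector soa_values,
                       double dt, double stim_dur, int noise_literal) {
  if (!zig_ready) zig_init();
  NumericVector rt(n, NA_REAL);
  IntegerVector outcome(n);
  IntegerVector soa(n);
  int n_clip = 0;
  const double sqrtdt = std::sqrt(dt);
  const int n_steps = (int)std::lround(stim_dur / dt);
  const int i0 = (int)std::ceil(T_ac / dt - 1e-9);
  const uint64_t useed = (uint64_t)(int64_t)seed;

  for (int tr = 0; tr < n; tr++) {
    Rng r = trial_rng(useed, (uint64_t)cell_id, (uint64_t)tr);
    TrialDraws d = draw_trial(r, tr, z1m, z2m, u1m, u2m, s_u, s_Z, bias_kind,
                              b_range, T_r, s_t, T_ev, sT_ev, tz_options);
    if (d.motor == 0 && s_t > 0) n_clip++;
    soa[tr] = soa_values[d.soa_idx];

    // Before T_ac both DVs are exact lines (x = 0): solve crossings in closed
    // form instead of stepping.
    double td = NA_REAL;
    int winner = 0;
    double c1 = (d.u1 > 0 && d.z1 < 1) ? d.tz + (1 - d.z1) / d.u1 : R_PosInf;
    double c2 = (d.u2 > 0 && d.z2 < 1) ? d.tz + (1 - d.z2) / d.u2 : R_PosInf;
    double cmin = std::min(c1, c2);
    if (cmin <= i0 * dt) {
      td = cmin;
      winner = (c1 < c2) ? 1 : ((c2 < c1) ? 2 : ((runif01(r) < 0.5) ? 1 : 2));
    } else {
      double x = 0.0;
      for (int i = i0; i <= n_steps; i++) {
        double t = i * dt;
        if (t + d.motor > stim_dur + 1e-12) break;  // response can no longer land
        double drift_int = 0.0;  // exact integral of B(t) + mu(t) over the step
        if (bias_kind == 1) {
          drift_int += nu_b * step_overlap(t, dt, T_ac, R_PosInf);
        } else if (bias_kind == 2) {
          drift_int += nu_b * step_overlap(t, dt, T_ac, T_ac + d.burstT);
        }
        double sg;
        if (evidence_kind == 0) {
          drift_int += nu * step_overlap(t, dt, d.tev, R_PosInf);
          sg = (t > d.tev + 1e-12) ? s : 0.0;
        } else {
          drift_int += mu_vec[i] * dt;
          sg = sigma_vec[i];
        }
        double incr = drift_int;
        if (sg > 0)
          incr += (noise_literal ? sg * dt : sg * sqrtdt) * rnorm_std(r);
        x += incr;
        double dv1 = d.z1 + d.u1 * (t - d.tz) + (x > 0 ? x : 0.0);
        double dv2 = d.z2 + d.u2 * (t - d.tz) + (x < 0 ? -x : 0.0);
        if (dv1 >= 1.0 || dv2 >= 1.0) {
          double o1 = dv1 - 1.0, o2 = dv2 - 1.0;
          winner = (o1 > o2) ? 1 : ((o2 > o1) ? 2 : ((runif01(r) < 0.5) ? 1 : 2));
          td = t;
          break;
        }
      }
    }
    if (winner != 0) {
      double rtt = td + d.motor;
      if (rtt > stim_dur + 1e-12) {
        winner = 0;  // decision too late to register a response
      } else {
        rt[tr] = rtt;
      }
    }
    outcome[tr] = winner;
  }
  return List::create(_["rt"] = rt, _["outcome"] = outcome, _["soa"] = soa,
                      _["n_motor_clipped"] = n_clip);
}

// Mean DV1 - DV2 trace for one cell, stimulus-locked grid t = 0..horizon.
// DVs keep evolving past the bound (no absorption).  Draw order matches
// sim_race_cell_cpp so the same seed describes the same trials.
// [[Rcpp::export]]
NumericVector sim_race_trace_cpp(int n, double seed, int cell_id,
                                 double z1m, double z2m, double u1m,
                                 double u2m, double s_u,
                                 double nu, double nu_b, int bias_kind,
                                 double b_range,
                                 int evidence_kind, double s, double T_ev,
                                 double sT_ev,
                                 NumericVector mu_vec, NumericVector sigma_vec,
                                 double T_ac, double s_Z,
                                 double T_r, double s_t,
                                 NumericVector tz_options,
                                 double dt, double horizon, int noise_literal) {
  if (!zig_ready) zig_init();
  const double sqrtdt = std::sqrt(dt);
  const int n_steps = (int)std::lround(horizon / dt);
  const int i0 = (int)std::ceil(T_ac / dt - 1e-9);
  const uint64_t useed = (uint64_t)(int64_t)seed;
  std::vector<double> acc(n_steps + 1, 0.0);

  for (int tr = 0; tr < n; tr++) {
    Rng r = trial_rng(useed, (uint64_t)cell_id, (uint64_t)tr);
    TrialDraws d = draw_trial(r, tr, z1m, z2m, u1m, u2m, s_u, s_Z, bias_kind,
                              b_range, T_r, s_t, T_ev, sT_ev, tz_options);
    double x = 0.0;
    for (int i = 0; i <= n_steps; i++) {
      double t = i * dt;
      if (i >= i0) {
        double drift_int = 0.0;  // exact integral of B(t) + mu(t) over the step
        if (bias_kind == 1) {
          drift_int += nu_b * step_overlap(t, dt, T_ac, R_PosInf);
        } else if (bias_kind == 2) {
          drift_int += nu_b * step_overlap(t, dt, T_ac, T_ac + d.burstT);
        }
        double sg;
        if (evidence_kind == 0) {
          drift_int += nu * step_overlap(t, dt, d.tev, R_PosInf);
          sg = (t > d.tev + 1e-12) ? s : 0.0;
        } else {
          drift_int += mu_vec[i] * dt;
          sg = sigma_vec[i];
        }
        double incr = drift_int;
        if (sg > 0)
          incr += (noise_literal ? sg * dt : sg * sqrtdt) * rnorm_std(r);
        x += incr;
      }
      double dv1 = d.z1 + d.u1 * (t - d.tz) + (x > 0 ? x : 0.0);
      double dv2 = d.z2 + d.u2 * (t - d.tz) + (x < 0 ? -x : 0.0);
      acc[i] += dv1 - dv2;
    }
  }
  NumericVector out(n_steps + 1);
  for (int i = 0; i <= n_steps; i++) out[i] = acc[i] / n;
  return out;
}

// DDM benchmark for one cell.  zb_signed carries the value-cue sign
// (+z_b high value, -z_b low value); the upper bound +a is the correct
// response.  Outcome codes as in the race simulator.
// [[Rcpp::export]]
List sim_ddm_cell_cpp(int n, double seed, int cell_id,
                      double nu, double eta, double a, double zb_signed,
                      double s_z, double T_er, double s_t, double sigma,
                      double dt, double stim_dur) {
  if (!zig_ready) zig_init();
  NumericVector rt(n, NA_REAL);
  IntegerVector outcome(n);
  const double sqrtdt = std::sqrt(dt);
  const int n_steps = (int)std::lround(stim_dur / dt);
  const uint64_t useed = (uint64_t)(int64_t)seed;

  for (int tr = 0; tr < n; tr++) {
    Rng r = trial_rng(useed, (uint64_t)cell_id, (uint64_t)tr);
    double drift = nu + eta * rnorm_std(r);
    double x = zb_signed + s_z * (runif01(r) - 0.5);
    double nondec = T_er + s_t * (runif01(r) - 0.5);
    if (nondec < 0) nondec = 0;
    int winner = 0;
    double td = NA_REAL;
    for (int i = 1; i <= n_steps; i++) {
      double t = i * dt;
      if (t + nondec > stim_dur + 1e-12) break;
      x += drift * dt + sigma * sqrtdt * rnorm_std(r);
      if (x >= a) {
        winner = 1;
        td = t;
        break;
      }
      if (x <= -a) {
        winner = 2;
        td = t;
        break;
      }
    }
    if (winner != 0) rt[tr] = td + nondec;
    outcome[tr] = winner;
  }
  return List::create(_["rt"] = rt, _["outcome"] = outcome);
}
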