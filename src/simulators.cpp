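// Inner loops for the reward-taxis simulators.
//
// Both simulators advance millions of small time steps, so the stepping is
// done here; everything else (parameter validation, field construction,
// statistics) lives in R. Randomness comes from R's RNG (unif_rand /
// norm_rand), so set.seed() in R makes runs reproducible end to end.

#include <Rcpp.h>
#include <cmath>
#include <vector>

using namespace Rcpp;

namespace {

// Parametric reward fields understood by the compiled loops.
// kind 0: uniform, pars = {R0}
// kind 1: two isotropic Gaussians, pars = {R1, R2, b1, b2, c1[m], c2[m]}
// kind 2: exponential decay exp(-gamma x^h) on x >= 0 (1D), pars = {gamma, h}
struct Field {
  int kind;
  int m;
  std::vector<double> p;

  // log R(x); if grad != nullptr also fills grad with d logR / dx
  double logR(const double* x, double* grad) const {
    switch (kind) {
      case 0: {
        if (grad) for (int j = 0; j < m; ++j) grad[j] = 0.0;
        return std::log(p[0]);
      }
      case 1: {
        const double R1 = p[0], R2 = p[1], b1 = p[2], b2 = p[3];
        const double* c1 = &p[4];
        const double* c2 = &p[4 + m];
        double q1 = 0.0, q2 = 0.0;
        for (int j = 0; j < m; ++j) {
          const double e1 = x[j] - c1[j], e2 = x[j] - c2[j];
          q1 += e1 * e1; q2 += e2 * e2;
        }
        const double t1 = R1 * std::exp(-q1 / (2.0 * b1 * b1));
        const double t2 = R2 * std::exp(-q2 / (2.0 * b2 * b2));
        const double R = t1 + t2;
        if (grad) {
          for (int j = 0; j < m; ++j) {
            const double num = -(x[j] - c1[j]) * t1 / (b1 * b1)
                               -(x[j] - c2[j]) * t2 / (b2 * b2);
            grad[j] = num / R;
          }
        }
        return std::log(R);
      }
      default: { // 2
        const double g = p[0], h = p[1];
        const double v = x[0] < 0.0 ? 0.0 : x[0];
        if (grad) grad[0] = (v <= 0.0) ? 0.0 : -g * h * std::pow(v, h - 1.0);
        return -g * std::pow(v, h);
      }
    }
  }
};

inline void reflect(double* x, const double* lo, const double* hi, int m,
                    bool bounded) {
  if (!bounded) return;
  for (int j = 0; j < m; ++j) {
    // fold until inside; box is always much wider than one step
    while (x[j] < lo[j] || x[j] > hi[j]) {
      if (x[j] < lo[j]) x[j] = 2.0 * lo[j] - x[j];
      if (x[j] > hi[j]) x[j] = 2.0 * hi[j] - x[j];
    }
  }
}

inline void fresh_heading(double* h, int m, double corr) {
  if (m == 1) {
    const double keep_p = 0.5 * (1.0 + corr);
    if (unif_rand() >= keep_p) h[0] = -h[0];
    return;
  }
  double u[3], n2 = 0.0;
  for (int j = 0; j < m; ++j) { u[j] = norm_rand(); n2 += u[j] * u[j]; }
  const double inv = 1.0 / std::sqrt(n2);
  double s2 = 0.0;
  for (int j = 0; j < m; ++j) {
    h[j] = corr * h[j] + (1.0 - corr) * u[j] * inv;
    s2 += h[j] * h[j];
  }
  const double invs = 1.0 / std::sqrt(s2);
  for (int j = 0; j < m; ++j) h[j] *= invs;
}

inline bool in_window(const double* x, const double* c, int m, double w) {
  for (int j = 0; j < m; ++j)
    if (std::fabs(x[j] - c[j]) > w) return false;
  return true;
}

} // namespace

// Run-and-tumble agent with the dopamine circuit carried along the path.
// modulation: 0 = speed (v = v0 * (max(d,0)/d0)^h_speed),
//             1 = tumble rate (tau^-1 * d0 / max(d, floor), speed v0).
// [[Rcpp::export(name = ".run_taxis_cpp")]]
List run_taxis_cpp(List field_desc, NumericVector circuit,
                   NumericVector agent, NumericVector x0,
                   double T, double dt,
                   NumericVector box_lo, NumericVector box_hi,
                   int record_every, NumericMatrix centers, double window,
                   double burn_frac) {
  Field fld;
  fld.kind = as<int>(field_desc["kind"]);
  fld.m = as<int>(field_desc["m"]);
  fld.p = as<std::vector<double> >(field_desc["pars"]);
  const int m = fld.m;

  const double omega_d = circuit[0], omega = circuit[1], C = circuit[2],
               mu = circuit[3], alpha = circuit[4], d0 = circuit[5];
  const bool quasi = circuit.size() > 6 && circuit[6] > 0.5;
  const double v0 = agent[0], tau = agent[1];
  const int modulation = (int)agent[2];
  const double h_speed = agent[3], turn_corr = agent[4];

  const bool bounded = box_lo.size() > 0;
  const long n_steps = (long)std::ceil(T / dt);
  const double decay = quasi ? 0.0 : std::exp(-omega_d * dt);
  const int n_c = centers.nrow();

  double x[3] = {0, 0, 0}, hdg[3] = {0, 0, 0};
  for (int j = 0; j < m; ++j) x[j] = x0[j];
  hdg[0] = 1.0;
  fresh_heading(hdg, m, 0.0);

  // adapted initial condition at the starting position
  double logR = fld.logR(x, nullptr);
  double d = d0;
  double g = (C - d0 + mu * logR) / alpha;

  std::vector<double> occ(n_c, 0.0);
  const long burn_steps = (long)(burn_frac * (double)n_steps);
  if (record_every < 1) record_every = 1;
  if (record_every > n_steps) record_every = (int)n_steps;
  const long n_rec = n_steps / record_every + 1;
  NumericVector rec_t(n_rec), rec_d(n_rec), rec_g(n_rec), rec_v(n_rec);
  IntegerVector rec_tum(n_rec);
  NumericMatrix rec_x(n_rec, m);
  long i_rec = 0;
  long n_tumbles = 0;

  double speed = v0;
  for (long i = 0; i < n_steps; ++i) {
    // movement at the current dopamine level
    if (modulation == 0) {
      const double ratio = d > 0.0 ? d / d0 : 0.0;
      speed = v0 * (h_speed == 1.0 ? ratio : std::pow(ratio, h_speed));
    } else {
      speed = v0;
    }
    for (int j = 0; j < m; ++j) x[j] += speed * dt * hdg[j];
    reflect(x, box_lo.begin(), box_hi.begin(), m, bounded);

    // circuit driven by R at the new position (exponential update for the
    // fast d-equation, trapezoidal update for the integral feedback)
    logR = fld.logR(x, nullptr);
    const double f = C + mu * logR - alpha * g;
    const double d_new = f + (d - f) * decay;
    g += omega * dt * (0.5 * (d + d_new) / d0 - 1.0);
    d = d_new;

    // reorientation
    double p_tum;
    if (modulation == 0) {
      p_tum = dt / tau;
    } else {
      const double dfloor = d > 1e-3 * d0 ? d : 1e-3 * d0;
      p_tum = dt / tau * (d0 / dfloor);
      if (p_tum > 1.0) p_tum = 1.0;
    }
    int tumbled = 0;
    if (unif_rand() < p_tum) {
      fresh_heading(hdg, m, turn_corr);
      tumbled = 1;
      ++n_tumbles;
    }

    if (i >= burn_steps)
      for (int c = 0; c < n_c; ++c)
        if (in_window(x, &centers(c, 0), m, window)) occ[c] += dt;

    if (record_every > 0 && (i + 1) % record_every == 0 && i_rec < n_rec) {
      rec_t[i_rec] = (i + 1) * dt;
      for (int j = 0; j < m; ++j) rec_x(i_rec, j) = x[j];
      rec_d[i_rec] = d; rec_g[i_rec] = g; rec_v[i_rec] = speed;
      rec_tum[i_rec] = tumbled;
      ++i_rec;
    }
  }

  return List::create(
    _["times"] = rec_t[Range(0, i_rec > 0 ? i_rec - 1 : 0)],
    _["positions"] = rec_x(Range(0, i_rec > 0 ? i_rec - 1 : 0), _),
    _["d"] = rec_d[Range(0, i_rec > 0 ? i_rec - 1 : 0)],
    _["g"] = rec_g[Range(0, i_rec > 0 ? i_rec - 1 : 0)],
    _["speed"] = rec_v[Range(0, i_rec > 0 ? i_rec - 1 : 0)],
    _["tumbled"] = rec_tum[Range(0, i_rec > 0 ? i_rec - 1 : 0)],
    _["occupancy"] = NumericVector(occ.begin(), occ.end()),
    _["n_tumbles"] = (double)n_tumbles,
    _["final_x"] = NumericVector(x, x + m));
}

// Euler-Maruyama integration of dx = drift dt + sqrt(2D) dW with
// drift_mode 0: chi * grad log R (reward-taxis coarse-graining)
// drift_mode 1: chi * grad R     (non-logarithmic negative control)
// [[Rcpp::export(name = ".run_langevin_cpp")]]
List run_langevin_cpp(List field_desc, double D, double chi,
                      NumericVector x0, double T, double dt,
                      NumericVector box_lo, NumericVector box_hi,
                      int record_every, NumericMatrix centers, double window,
                      int drift_mode, double burn_frac) {
  Field fld;
  fld.kind = as<int>(field_desc["kind"]);
  fld.m = as<int>(field_desc["m"]);
  fld.p = as<std::vector<double> >(field_desc["pars"]);
  const int m = fld.m;

  const bool bounded = box_lo.size() > 0;
  const long n_steps = (long)std::ceil(T / dt);
  const double sig = std::sqrt(2.0 * D * dt);
  const int n_c = centers.nrow();

  double x[3] = {0, 0, 0}, grad[3];
  for (int j = 0; j < m; ++j) x[j] = x0[j];

  std::vector<double> occ(n_c, 0.0);
  const long burn_steps = (long)(burn_frac * (double)n_steps);
  if (record_every < 1) record_every = 1;
  if (record_every > n_steps) record_every = (int)n_steps;
  const long n_rec = n_steps / record_every + 1;
  NumericVector rec_t(n_rec);
  NumericMatrix rec_x(n_rec, m);
  long i_rec = 0;

  for (long i = 0; i < n_steps; ++i) {
    const double logR = fld.logR(x, grad);
    double scale = chi;
    if (drift_mode == 1) scale = chi * std::exp(logR); // grad R = R grad logR
    for (int j = 0; j < m; ++j)
      x[j] += scale * grad[j] * dt + sig * norm_rand();
    reflect(x, box_lo.begin(), box_hi.begin(), m, bounded);

    if (i >= burn_steps)
      for (int c = 0; c < n_c; ++c)
        if (in_window(x, &centers(c, 0), m, window)) occ[c] += dt;

    if (record_every > 0 && (i + 1) % record_every == 0 && i_rec < n_rec) {
      rec_t[i_rec] = (i + 1) * dt;
      for (int j = 0; j < m; ++j) rec_x(i_rec, j) = x[j];
      ++i_rec;
    }
  }

  return List::create(
    _["times"] = rec_t[Range(0, i_rec > 0 ? i_rec - 1 : 0)],
    _["positions"] = rec_x(Range(0, i_rec > 0 ? i_rec - 1 : 0), _),
    _["occupancy"] = NumericVector(occ.begin(), occ.end()),
    _["final_x"] = NumericVector(x, x + m));
}
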