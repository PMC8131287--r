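#include <Rcpp.h>
using namespace Rcpp;

// Internal unit system: kcal/mol, Angstrom, ps, amu.
// 1 kcal/mol = 418.4 amu A^2 / ps^2.
static const double KCAL_TO_AKMA = 418.4;

struct ToyParams {
  double well_depth;     // kcal/mol, > 0
  double well_width;     // A
  double z_lo, z_hi;     // axial range (soft walls outside)
  double wall_k;         // kcal/mol/A^2
  double radial_k;       // kcal/mol/A^2
};

struct BiasParams {
  bool   umb_on;
  double umb_k;          // kcal/mol/A^2, no 1/2 factor: V = k (z - d)^2
  double umb_d;
  bool   cyl_on;
  double cyl_r0;         // A, flat bottom inside
  double cyl_k;          // kcal/mol/A^2
};

// Axial toy potential: Gaussian well (minimum -D at z = 0) plus soft walls.
static inline double u_axial(const ToyParams& s, double z) {
  double u = -s.well_depth * std::exp(-0.5 * z * z / (s.well_width * s.well_width));
  if (z > s.z_hi) { double d = z - s.z_hi; u += s.wall_k * d * d; }
  if (z < s.z_lo) { double d = z - s.z_lo; u += s.wall_k * d * d; }
  return u;
}

static inline double f_axial(const ToyParams& s, double z) {
  double w2 = s.well_width * s.well_width;
  double f = -s.well_depth * (z / w2) * std::exp(-0.5 * z * z / w2);
  if (z > s.z_hi) f += -2.0 * s.wall_k * (z - s.z_hi);
  if (z < s.z_lo) f += -2.0 * s.wall_k * (z - s.z_lo);
  return f;
}

// Bias energy as a function of the full position (umbrella acts on z, cylinder on rho).
static inline double bias_energy(const BiasParams& b, double x, double y, double z) {
  double u = 0.0;
  if (b.umb_on) { double d = z - b.umb_d; u += b.umb_k * d * d; }
  if (b.cyl_on) {
    double rho = std::sqrt(x * x + y * y);
    if (rho > b.cyl_r0) { double d = rho - b.cyl_r0; u += b.cyl_k * d * d; }
  }
  return u;
}

// Total force; returns potential energy too (toy + bias).
static inline double force(const ToyParams& s, const BiasParams& b,
                           double x, double y, double z,
                           double& fx, double& fy, double& fz) {
  fx = -2.0 * s.radial_k * x;
  fy = -2.0 * s.radial_k * y;
  fz = f_axial(s, z);
  double u = u_axial(s, z) + s.radial_k * (x * x + y * y);
  if (b.umb_on) {
    double d = z - b.umb_d;
    fz += -2.0 * b.umb_k * d;
    u  += b.umb_k * d * d;
  }
  if (b.cyl_on) {
    double rho = std::sqrt(x * x + y * y);
    if (rho > b.cyl_r0) {
      double d = rho - b.cyl_r0;
      double pref = -2.0 * b.cyl_k * d / rho;
      fx += pref * x;
      fy += pref * y;
      u  += b.cyl_k * d * d;
    }
  }
  return u;
}

static ToyParams toy_from_list(const List& sys) {
  ToyParams s;
  s.well_depth = as<double>(sys["well_depth"]);
  s.well_width = as<double>(sys["well_width"]);
  NumericVector rng = sys["axial_range"];
  s.z_lo = rng[0]; s.z_hi = rng[1];
  s.wall_k = as<double>(sys["wall_stiffness"]);
  s.radial_k = as<double>(sys["radial_stiffness"]);
  return s;
}

// One BAOAB Langevin step (velocity form); v in A/ps.
static inline void baoab_step(const ToyParams& s, const BiasParams& b,
                              double& x, double& y, double& z,
                              double& vx, double& vy, double& vz,
                              double inv_m_conv, double dt,
                              double c1, double c2v) {
  double fx, fy, fz;
  force(s, b, x, y, z, fx, fy, fz);
  vx += 0.5 * dt * fx * inv_m_conv;
  vy += 0.5 * dt * fy * inv_m_conv;
  vz += 0.5 * dt * fz * inv_m_conv;
  x += 0.5 * dt * vx; y += 0.5 * dt * vy; z += 0.5 * dt * vz;
  vx = c1 * vx + c2v * norm_rand();
  vy = c1 * vy + c2v * norm_rand();
  vz = c1 * vz + c2v * norm_rand();
  x += 0.5 * dt * vx; y += 0.5 * dt * vy; z += 0.5 * dt * vz;
  force(s, b, x, y, z, fx, fy, fz);
  vx += 0.5 * dt * fx * inv_m_conv;
  vy += 0.5 * dt * fy * inv_m_conv;
  vz += 0.5 * dt * fz * inv_m_conv;
}

// Single-particle Langevin trajectory under the toy potential plus an optional
// (possibly moving-center) umbrella and cylindrical restraint.  Records every
// `stride` steps: step index, zeta (= z), radial distance, bias energy, and the
// full position (for snapshot seeding).
// [[Rcpp::export(name = ".simulate_path_cpp")]]
List simulate_path_cpp(List sys, NumericVector pos0, NumericVector vel0,
                       double mass, double kBT, double dt, double friction,
                       int n_steps, int stride,
                       bool umb_on, double umb_k, double umb_d0, double umb_d1,
                       bool cyl_on, double cyl_r0, double cyl_k) {
  ToyParams s = toy_from_list(sys);
  BiasParams b; b.umb_on = umb_on; b.umb_k = umb_k; b.umb_d = umb_d0;
  b.cyl_on = cyl_on; b.cyl_r0 = cyl_r0; b.cyl_k = cyl_k;

  double x = pos0[0], y = pos0[1], z = pos0[2];
  double vx = vel0[0], vy = vel0[1], vz = vel0[2];
  double inv_m_conv = KCAL_TO_AKMA / mass;
  double c1 = std::exp(-friction * dt);
  double c2v = std::sqrt((1.0 - c1 * c1) * kBT * KCAL_TO_AKMA / mass);

  int n_rec = n_steps / stride;
  IntegerVector r_step(n_rec);
  NumericVector r_z(n_rec), r_rad(n_rec), r_bias(n_rec), r_ke(n_rec);
  NumericMatrix r_pos(n_rec, 3);

  RNGScope scope;
  int k = 0;
  for (int i = 1; i <= n_steps; ++i) {
    if (umb_on && n_steps > 1)
      b.umb_d = umb_d0 + (umb_d1 - umb_d0) * (double)(i - 1) / (double)(n_steps - 1);
    baoab_step(s, b, x, y, z, vx, vy, vz, inv_m_conv, dt, c1, c2v);
    if (!std::isfinite(x) || !std::isfinite(y) || !std::isfinite(z))
      stop("non-finite coordinates at step %d: time step too large for this system", i);
    if (i % stride == 0 && k < n_rec) {
      r_step[k] = i;
      r_z[k] = z;
      r_rad[k] = std::sqrt(x * x + y * y);
      r_bias[k] = bias_energy(b, x, y, z);
      r_ke[k] = 0.5 * mass * (vx * vx + vy * vy + vz * vz) / KCAL_TO_AKMA;
      r_pos(k, 0) = x; r_pos(k, 1) = y; r_pos(k, 2) = z;
      ++k;
    }
  }
  return List::create(_["step"] = r_step, _["zeta"] = r_z, _["radial"] = r_rad,
                      _["bias_energy"] = r_bias, _["kinetic"] = r_ke,
                      _["positions"] = r_pos,
                      _["final_position"] = NumericVector::create(x, y, z),
                      _["final_velocity"] = NumericVector::create(vx, vy, vz));
}

// Propagate all REUS replicas for one dynamics segment.  Each replica i runs
// under the umbrella window it currently holds (center[i], k[i]).  Positions
// and velocities are updated in place (copies returned).
// [[Rcpp::export(name = ".propagate_ensemble_cpp")]]
List propagate_ensemble_cpp(List sys, NumericMatrix pos, NumericMatrix vel,
                            double mass, double kBT, double dt, double friction,
                            int n_steps,
                            NumericVector umb_k, NumericVector umb_d,
                            bool cyl_on, double cyl_r0, double cyl_k) {
  ToyParams s = toy_from_list(sys);
  int M = pos.nrow();
  NumericMatrix p = clone(pos), v = clone(vel);
  NumericVector zeta(M), radial(M);
  double inv_m_conv = KCAL_TO_AKMA / mass;
  double c1 = std::exp(-friction * dt);
  double c2v = std::sqrt((1.0 - c1 * c1) * kBT * KCAL_TO_AKMA / mass);

  RNGScope scope;
  for (int i = 0; i < M; ++i) {
    BiasParams b; b.umb_on = true; b.umb_k = umb_k[i]; b.umb_d = umb_d[i];
    b.cyl_on = cyl_on; b.cyl_r0 = cyl_r0; b.cyl_k = cyl_k;
    double x = p(i, 0), y = p(i, 1), z = p(i, 2);
    double vx = v(i, 0), vy = v(i, 1), vz = v(i, 2);
    for (int t = 0; t < n_steps; ++t)
      baoab_step(s, b, x, y, z, vx, vy, vz, inv_m_conv, dt, c1, c2v);
    if (!std::isfinite(x) || !std::isfinite(y) || !std::isfinite(z))
      stop("non-finite coordinates for replica %d: time step too large", i + 1);
    p(i, 0) = x; p(i, 1) = y; p(i, 2) = z;
    v(i, 0) = vx; v(i, 1) = vy; v(i, 2) = vz;
    zeta[i] = z;
    radial[i] = std::sqrt(x * x + y * y);
  }
  return List::create(_["pos"] = p, _["vel"] = v,
                      _["zeta"] = zeta, _["radial"] = radial);
}

// Self-consistent WHAM iteration.
//   logq[m, b] = -beta * V_m(zeta_b)   (bias Boltzmann log-factors)
//   N[m]       = samples in window m
//   C[b]       = pooled counts in bin b
// Iterates p_b = C_b / sum_m N_m exp(beta f_m + logq_mb),
//          f_m = -(1/beta) log sum_b p_b exp(logq_mb),
// gauge f_1 = 0, until max |delta f| < tol.
// [[Rcpp::export(name = ".wham_iterate_cpp")]]
List wham_iterate_cpp(NumericMatrix logq, NumericVector N, NumericVector C,
                      double beta, double tol, int max_iter) {
  int M = logq.nrow(), B = logq.ncol();
  std::vector<double> f(M, 0.0), fnew(M), p(B, 0.0);
  double resid = R_PosInf;
  int it = 0;
  for (it = 1; it <= max_iter; ++it) {
    // unnormalised p
    double psum = 0.0;
    for (int b = 0; b < B; ++b) {
      if (C[b] <= 0.0) { p[b] = 0.0; continue; }
      double denom = 0.0;
      for (int m = 0; m < M; ++m)
        denom += N[m] * std::exp(beta * f[m] + logq(m, b));
      p[b] = C[b] / denom;
      psum += p[b];
    }
    for (int b = 0; b < B; ++b) p[b] /= psum;
    // window free energies
    for (int m = 0; m < M; ++m) {
      double zsum = 0.0;
      for (int b = 0; b < B; ++b)
        if (p[b] > 0.0) zsum += p[b] * std::exp(logq(m, b));
      fnew[m] = -std::log(zsum) / beta;
    }
    double f0 = fnew[0];
    resid = 0.0;
    for (int m = 0; m < M; ++m) {
      fnew[m] -= f0;
      double d = std::fabs(fnew[m] - f[m]);
      if (d > resid) resid = d;
      f[m] = fnew[m];
    }
    if (resid < tol) break;
  }
  return List::create(_["f"] = NumericVector(f.begin(), f.end()),
                      _["p"] = NumericVector(p.begin(), p.end()),
                      _["iterations"] = it > max_iter ? max_iter : it,
                      _["residual"] = resid,
                      _["converged"] = resid < tol);
}
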