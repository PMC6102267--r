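// Metropolis Monte Carlo of rigid, surface-grafted bead-chain molecules with
// a WCA (cut-and-shifted repulsive Lennard-Jones) pair potential, a hard wall
// at z = 0 acting on sphere centres, x/y periodic boundaries, an optional
// quadratic tilt restraint on the top sphere, and Widom ghost insertion for
// the excess chemical potential. Lengths in nm, energies in kBT.

#include <Rcpp.h>
#include <cmath>
#include <cstdint>
#include <vector>

using namespace Rcpp;

namespace {

constexpr double WCA_CUT2_FACTOR = 1.2599210498948732; // 2^(1/3), on sigma^2
constexpr double ENERGY_CAP = 1e12;

// xoshiro256** with splitmix64 seeding: bit-reproducible across platforms,
// independent of the C++ standard library's distribution implementations.
struct RNG {
  uint64_t s[4];
  explicit RNG(uint64_t seed) {
    uint64_t x = seed;
    for (int i = 0; i < 4; ++i) {
      x += 0x9E3779B97F4A7C15ULL;
      uint64_t z = x;
      z = (z ^ (z >> 30)) * 0xBF58476D1CE4E5B9ULL;
      z = (z ^ (z >> 27)) * 0x94D049BB133111EBULL;
      s[i] = z ^ (z >> 31);
    }
  }
  static uint64_t rotl(uint64_t v, int k) { return (v << k) | (v >> (64 - k)); }
  uint64_t next() {
    const uint64_t result = rotl(s[1] * 5, 7) * 9;
    const uint64_t t = s[1] << 17;
    s[2] ^= s[0]; s[3] ^= s[1]; s[1] ^= s[2]; s[0] ^= s[3];
    s[2] ^= t; s[3] = rotl(s[3], 45);
    return result;
  }
  double unif() { return (next() >> 11) * (1.0 / 9007199254740992.0); }
  int upto(int n) { // uniform integer in [0, n)
    int k = static_cast<int>(unif() * n);
    return k >= n ? n - 1 : k;
  }
};

struct Quat {
  double w, x, y, z;
  void normalize() {
    double n = std::sqrt(w * w + x * x + y * y + z * z);
    w /= n; x /= n; y /= n; z /= n;
  }
};

inline Quat qmul(const Quat& a, const Quat& b) {
  return {a.w * b.w - a.x * b.x - a.y * b.y - a.z * b.z,
          a.w * b.x + a.x * b.w + a.y * b.z - a.z * b.y,
          a.w * b.y - a.x * b.z + a.y * b.w + a.z * b.x,
          a.w * b.z + a.x * b.y - a.y * b.x + a.z * b.w};
}

inline Quat axis_angle(double ux, double uy, double uz, double ang) {
  double h = 0.5 * ang, s = std::sin(h);
  return {std::cos(h), ux * s, uy * s, uz * s};
}

// rotate body-frame point p by quaternion q
inline void qrot(const Quat& q, const double* p, double* out) {
  // R * p via q p q^-1 expanded
  double tx = 2.0 * (q.y * p[2] - q.z * p[1]);
  double ty = 2.0 * (q.z * p[0] - q.x * p[2]);
  double tz = 2.0 * (q.x * p[1] - q.y * p[0]);
  out[0] = p[0] + q.w * tx + (q.y * tz - q.z * ty);
  out[1] = p[1] + q.w * ty + (q.z * tx - q.x * tz);
  out[2] = p[2] + q.w * tz + (q.x * ty - q.y * tx);
}

// z-component of the rotated body z-axis: cos(tilt)
inline double cos_tilt(const Quat& q) {
  return 1.0 - 2.0 * (q.x * q.x + q.y * q.y);
}

struct System {
  int n_mol = 0, n_sph = 0, top = 0;
  double Lx = 0, Ly = 0, Lz = 0;
  double kf = 0, Lmax = 0; // restraint (kBT/nm^2, nm); kf < 0 => rigid upright
  bool rigid = false;
  double eps_lj = 1.0;
  std::vector<double> body;  // n_sph x 3, graft point at origin
  std::vector<double> diam;  // n_sph
  std::vector<double> gx, gy;
  std::vector<Quat> quat;
  // scratch world coordinates of one molecule
  void world(int i, std::vector<double>& w) const {
    w.resize(3 * n_sph);
    for (int k = 0; k < n_sph; ++k) {
      double out[3];
      qrot(quat[i], &body[3 * k], out);
      w[3 * k] = out[0] + gx[i];
      w[3 * k + 1] = out[1] + gy[i];
      w[3 * k + 2] = out[2];
    }
  }
};

inline double wca(double r2, double sigma, double eps_lj) {
  double rc2 = sigma * sigma * WCA_CUT2_FACTOR;
  if (r2 >= rc2) return 0.0;
  if (r2 < 1e-8 * sigma * sigma) r2 = 1e-8 * sigma * sigma;
  double s2 = sigma * sigma / r2;
  double s6 = s2 * s2 * s2;
  double u = 4.0 * eps_lj * (s6 * s6 - s6) + eps_lj;
  return u > ENERGY_CAP ? ENERGY_CAP : u;
}

inline double wrapd(double d, double L) {
  if (d > 0.5 * L) d -= L; else if (d < -0.5 * L) d += L;
  return d;
}

// interaction energy between the molecule whose world coords are in `w`
// (with graft at wx, wy implicit in w) and molecule j of the system
double pair_energy(const System& sys, const std::vector<double>& w,
                   const std::vector<double>& dw, int j,
                   std::vector<double>& scratch) {
  sys.world(j, scratch);
  double e = 0.0;
  int m = sys.n_sph;
  for (int a = 0; a < m; ++a) {
    for (int b = 0; b < m; ++b) {
      double dx = wrapd(w[3 * a] - scratch[3 * b], sys.Lx);
      double dy = wrapd(w[3 * a + 1] - scratch[3 * b + 1], sys.Ly);
      double dz = w[3 * a + 2] - scratch[3 * b + 2];
      double sigma = 0.5 * (dw[a] + dw[b]);
      e += wca(dx * dx + dy * dy + dz * dz, sigma, sys.eps_lj);
      if (e >= ENERGY_CAP) return ENERGY_CAP;
    }
  }
  return e;
}

// energy of molecule i (given candidate world coords w) with all others
double mol_energy(const System& sys, int i, const std::vector<double>& w,
                  std::vector<double>& scratch) {
  double e = 0.0;
  for (int j = 0; j < sys.n_mol; ++j) {
    if (j == i) continue;
    e += pair_energy(sys, w, sys.diam, j, scratch);
    if (e >= ENERGY_CAP) return ENERGY_CAP;
  }
  return e;
}

double restraint_energy(const System& sys, const Quat& q) {
  if (sys.rigid || sys.kf <= 0.0) return 0.0;
  double ztop = cos_tilt(q) * sys.body[3 * sys.top + 2];
  // body top may have lateral offsets; use full rotation for generality
  double out[3];
  qrot(q, &sys.body[3 * sys.top], out);
  ztop = out[2];
  double d = ztop - sys.Lmax;
  return sys.kf * d * d;
}

bool wall_ok(const System& sys, const std::vector<double>& w) {
  for (int k = 0; k < sys.n_sph; ++k)
    if (w[3 * k + 2] < -1e-12) return false;
  return true;
}

double total_energy(const System& sys, std::vector<double>& w1,
                    std::vector<double>& w2) {
  double e = 0.0;
  for (int i = 0; i < sys.n_mol; ++i) {
    sys.world(i, w1);
    for (int j = i + 1; j < sys.n_mol; ++j) e += pair_energy(sys, w1, sys.diam, j, w2);
    e += restraint_energy(sys, sys.quat[i]);
  }
  return e;
}

// sample a ghost orientation from the single-molecule Boltzmann distribution
// of tilt (sin(theta) measure times restraint) with uniform azimuth; the
// wall constraint is applied by redrawing, i.e. the conditional distribution.
Quat sample_orientation(const System& sys, RNG& rng, const std::vector<double>& body,
                        double Lmax, double kf, bool rigid,
                        std::vector<double>& w) {
  int tries = 0;
  while (true) {
    if (++tries > 20000) stop("could not sample a wall-compatible ghost orientation");
    Quat q{1, 0, 0, 0};
    if (!rigid) {
      double ct;
      // rejection sampling: cos(theta) uniform on (0,1] is the sin(theta)
      // measure; accept with the restraint Boltzmann factor
      while (true) {
        ct = rng.unif();
        if (kf <= 0.0) break;
        double d = (ct - 1.0) * Lmax;
        if (rng.unif() < std::exp(-kf * d * d)) break;
      }
      double theta = std::acos(ct);
      double phi_az = 2.0 * M_PI * rng.unif(); // tilt-axis direction
      double psi = 2.0 * M_PI * rng.unif();    // azimuthal spin
      Quat spin = axis_angle(0, 0, 1, psi);
      Quat tiltq = axis_angle(std::cos(phi_az), std::sin(phi_az), 0.0, theta);
      q = qmul(tiltq, spin);
      q.normalize();
    }
    // wall check at origin (z does not depend on graft xy)
    w.resize(3 * static_cast<int>(body.size() / 3));
    bool ok = true;
    for (size_t k = 0; k < body.size() / 3; ++k) {
      double out[3];
      qrot(q, &body[3 * k], out);
      if (out[2] < -1e-12) { ok = false; break; }
    }
    if (ok) return q;
    if (rigid) stop("rigid upright topology violates the wall");
  }
}

} // namespace

// [[Rcpp::export]]
double wca_energy_cpp(double r, double sigma, double eps_lj) {
  if (r < 0) stop("distance must be >= 0");
  return wca(r * r, sigma, eps_lj);
}

// [[Rcpp::export]]
List mc_run_cpp(NumericMatrix body, NumericVector diam, int top_index,
                int n_mol, NumericVector box, double kf, double Lmax,
                bool rigid, double eps_lj, int n_steps, double equil_frac,
                int n_samples, double amp_t, double amp_r, bool autotune,
                int seed) {
  System sys;
  sys.n_sph = body.nrow();
  sys.n_mol = n_mol;
  sys.top = top_index - 1;
  sys.Lx = box[0]; sys.Ly = box[1]; sys.Lz = box[2];
  sys.kf = kf; sys.Lmax = Lmax; sys.rigid = rigid; sys.eps_lj = eps_lj;
  sys.body.assign(body.begin(), body.end()); // column-major! fix below
  // Rcpp matrices are column-major; repack row-major (x,y,z per sphere)
  sys.body.resize(3 * sys.n_sph);
  for (int k = 0; k < sys.n_sph; ++k)
    for (int d = 0; d < 3; ++d) sys.body[3 * k + d] = body(k, d);
  sys.diam.assign(diam.begin(), diam.end());

  RNG rng(static_cast<uint64_t>(seed) * 2654435761ULL + 1ULL);
  std::vector<double> w1, w2, wtmp;

  // --- initial configuration: random sequential insertion, lattice fallback
  sys.gx.assign(n_mol, 0.0); sys.gy.assign(n_mol, 0.0);
  sys.quat.assign(n_mol, Quat{1, 0, 0, 0});
  bool placed = true;
  {
    double thresh = 10.0;
    for (int i = 0; i < n_mol && placed; ++i) {
      bool ok = false;
      for (int t = 0; t < 500; ++t) {
        sys.gx[i] = rng.unif() * sys.Lx;
        sys.gy[i] = rng.unif() * sys.Ly;
        double psi = 2.0 * M_PI * rng.unif();
        sys.quat[i] = axis_angle(0, 0, 1, psi);
        sys.world(i, w1);
        double e = 0.0;
        for (int j = 0; j < i; ++j) {
          e += pair_energy(sys, w1, sys.diam, j, w2);
          if (e > thresh) break;
        }
        if (e <= thresh) { ok = true; break; }
      }
      if (!ok) placed = false;
    }
  }
  if (!placed) {
    // lattice fallback: all upright on a square grid
    int n_side = static_cast<int>(std::ceil(std::sqrt(static_cast<double>(n_mol))));
    double spacing = sys.Lx / n_side;
    double sigma_max = 0.0;
    for (int k = 0; k < sys.n_sph; ++k) sigma_max = std::max(sigma_max, sys.diam[k]);
    if (spacing < 0.95 * sigma_max) {
      int n_max = static_cast<int>(std::floor(sys.Lx / sigma_max)) *
                  static_cast<int>(std::floor(sys.Ly / sigma_max));
      stop("cannot construct an overlap-free initial state for %d molecules; "
           "achievable maximum in this box is about %d", n_mol, n_max);
    }
    for (int i = 0; i < n_mol; ++i) {
      sys.gx[i] = (i % n_side + 0.5) * spacing;
      sys.gy[i] = (i / n_side + 0.5) * (sys.Ly / n_side);
      sys.quat[i] = axis_angle(0, 0, 1, 2.0 * M_PI * rng.unif());
    }
  }

  double energy = total_energy(sys, w1, w2);

  int n_equil = static_cast<int>(std::floor(equil_frac * n_steps));
  if (n_equil >= n_steps) n_equil = n_steps - 1;
  int n_prod = n_steps - n_equil;
  if (n_samples > n_prod) n_samples = n_prod;
  int sample_every = std::max(1, n_prod / std::max(n_samples, 1));

  long att_t = 0, acc_t = 0, att_r = 0, acc_r = 0; // production counters
  long w_att_t = 0, w_acc_t = 0, w_att_r = 0, w_acc_r = 0; // tuning window

  std::vector<double> st_x, st_y; std::vector<Quat> st_q;
  std::vector<double> tilts;
  int recorded = 0;

  for (int step = 0; step < n_steps; ++step) {
    bool in_equil = step < n_equil;
    if (n_mol > 0) {
      int i = rng.upto(n_mol);
      bool do_rot = (!rigid) && (rng.unif() < 0.5);
      double old_gx = sys.gx[i], old_gy = sys.gy[i];
      Quat old_q = sys.quat[i];
      sys.world(i, wtmp);
      double e_old = mol_energy(sys, i, wtmp, w2) + restraint_energy(sys, old_q);

      bool legal = true;
      if (do_rot) {
        double phi_az = 2.0 * M_PI * rng.unif();
        double cz = 2.0 * rng.unif() - 1.0;
        double sz = std::sqrt(std::max(0.0, 1.0 - cz * cz));
        double ang = amp_r * (2.0 * rng.unif() - 1.0);
        Quat dq = axis_angle(sz * std::cos(phi_az), sz * std::sin(phi_az), cz, ang);
        sys.quat[i] = qmul(dq, old_q);
        sys.quat[i].normalize();
      } else {
        sys.gx[i] += amp_t * (2.0 * rng.unif() - 1.0);
        sys.gy[i] += amp_t * (2.0 * rng.unif() - 1.0);
        sys.gx[i] -= sys.Lx * std::floor(sys.gx[i] / sys.Lx);
        sys.gy[i] -= sys.Ly * std::floor(sys.gy[i] / sys.Ly);
      }
      sys.world(i, wtmp);
      if (!wall_ok(sys, wtmp)) legal = false;

      bool accept = false;
      if (legal) {
        double e_new = mol_energy(sys, i, wtmp, w2) + restraint_energy(sys, sys.quat[i]);
        double dE = e_new - e_old;
        accept = dE <= 0.0 || rng.unif() < std::exp(-dE);
        if (accept) energy += dE;
      }
      if (!accept) { sys.gx[i] = old_gx; sys.gy[i] = old_gy; sys.quat[i] = old_q; }

      if (do_rot) { ++w_att_r; if (accept) ++w_acc_r; if (!in_equil) { ++att_r; if (accept) ++acc_r; } }
      else        { ++w_att_t; if (accept) ++w_acc_t; if (!in_equil) { ++att_t; if (accept) ++acc_t; } }

      if (in_equil && autotune) {
        if (w_att_t >= 500) {
          double rate = static_cast<double>(w_acc_t) / w_att_t;
          if (rate < 0.3) amp_t *= 0.85; else if (rate > 0.5) amp_t *= 1.15;
          amp_t = std::min(std::max(amp_t, 1e-5), 0.45 * sys.Lx);
          w_att_t = w_acc_t = 0;
        }
        if (w_att_r >= 500) {
          double rate = static_cast<double>(w_acc_r) / w_att_r;
          if (rate < 0.3) amp_r *= 0.85; else if (rate > 0.5) amp_r *= 1.15;
          amp_r = std::min(std::max(amp_r, 1e-5), M_PI);
          w_att_r = w_acc_r = 0;
        }
      }
    }

    if (!in_equil && recorded < n_samples &&
        (step - n_equil) % sample_every == 0) {
      for (int i = 0; i < n_mol; ++i) {
        st_x.push_back(sys.gx[i]); st_y.push_back(sys.gy[i]);
        st_q.push_back(sys.quat[i]);
        double ct = std::min(1.0, std::max(-1.0, cos_tilt(sys.quat[i])));
        tilts.push_back(std::acos(ct));
      }
      ++recorded;
    }
  }

  double energy_check = total_energy(sys, w1, w2);

  NumericMatrix states_xy(recorded * std::max(n_mol, 1), 2);
  NumericMatrix states_q(recorded * std::max(n_mol, 1), 4);
  for (size_t k = 0; k < st_x.size(); ++k) {
    states_xy(k, 0) = st_x[k]; states_xy(k, 1) = st_y[k];
    states_q(k, 0) = st_q[k].w; states_q(k, 1) = st_q[k].x;
    states_q(k, 2) = st_q[k].y; states_q(k, 3) = st_q[k].z;
  }
  NumericMatrix final_xy(std::max(n_mol, 1), 2);
  for (int i = 0; i < n_mol; ++i) { final_xy(i, 0) = sys.gx[i]; final_xy(i, 1) = sys.gy[i]; }

  return List::create(
    _["n_mol"] = n_mol, _["n_samples"] = recorded,
    _["states_xy"] = states_xy, _["states_q"] = states_q,
    _["tilt"] = NumericVector(tilts.begin(), tilts.end()),
    _["energy_running"] = energy, _["energy_recomputed"] = energy_check,
    _["final_xy"] = final_xy,
    _["acc_trans"] = att_t > 0 ? static_cast<double>(acc_t) / att_t : NA_REAL,
    _["acc_rot"] = att_r > 0 ? static_cast<double>(acc_r) / att_r : NA_REAL,
    _["amp_trans"] = amp_t, _["amp_rot"] = amp_r,
    _["lattice_start"] = !placed);
}

// [[Rcpp::export]]
NumericVector widom_cpp(NumericMatrix states_xy, NumericMatrix states_q,
                        int n_mol, int n_samples, NumericMatrix body,
                        NumericVector diam, int top_index, NumericVector box,
                        double kf, double Lmax, bool rigid, double eps_lj,
                        NumericMatrix ghost_body, NumericVector ghost_diam,
                        int ghost_top, double ghost_kf, double ghost_Lmax,
                        bool ghost_rigid, int n_insert, int seed) {
  System sys;
  sys.n_sph = body.nrow();
  sys.n_mol = n_mol;
  sys.top = top_index - 1;
  sys.Lx = box[0]; sys.Ly = box[1]; sys.Lz = box[2];
  sys.kf = kf; sys.Lmax = Lmax; sys.rigid = rigid; sys.eps_lj = eps_lj;
  sys.body.resize(3 * sys.n_sph);
  for (int k = 0; k < sys.n_sph; ++k)
    for (int d = 0; d < 3; ++d) sys.body[3 * k + d] = body(k, d);
  sys.diam.assign(diam.begin(), diam.end());
  sys.gx.assign(std::max(n_mol, 1), 0.0);
  sys.gy.assign(std::max(n_mol, 1), 0.0);
  sys.quat.assign(std::max(n_mol, 1), Quat{1, 0, 0, 0});

  int gm = ghost_body.nrow();
  std::vector<double> gbody(3 * gm);
  for (int k = 0; k < gm; ++k)
    for (int d = 0; d < 3; ++d) gbody[3 * k + d] = ghost_body(k, d);
  std::vector<double> gdiam(ghost_diam.begin(), ghost_diam.end());
  double gLmax = ghost_Lmax > 0 ? ghost_Lmax : gbody[3 * (ghost_top - 1) + 2];

  RNG rng(static_cast<uint64_t>(seed) * 0x9E3779B97F4A7C15ULL + 7ULL);
  NumericVector s_mean(n_samples);
  std::vector<double> gw(3 * gm), scratch;

  for (int s = 0; s < n_samples; ++s) {
    // load state s into the system
    for (int i = 0; i < n_mol; ++i) {
      int row = s * n_mol + i;
      sys.gx[i] = states_xy(row, 0); sys.gy[i] = states_xy(row, 1);
      sys.quat[i] = Quat{states_q(row, 0), states_q(row, 1),
                         states_q(row, 2), states_q(row, 3)};
    }
    double acc = 0.0;
    for (int t = 0; t < n_insert; ++t) {
      double px = rng.unif() * sys.Lx, py = rng.unif() * sys.Ly;
      Quat q = sample_orientation(sys, rng, gbody, gLmax, ghost_kf,
                                  ghost_rigid, scratch);
      for (int k = 0; k < gm; ++k) {
        double out[3];
        qrot(q, &gbody[3 * k], out);
        gw[3 * k] = out[0] + px; gw[3 * k + 1] = out[1] + py; gw[3 * k + 2] = out[2];
      }
      double dU = 0.0;
      for (int j = 0; j < n_mol; ++j) {
        sys.world(j, scratch);
        for (int a = 0; a < gm && dU < 700.0; ++a) {
          for (int b = 0; b < sys.n_sph; ++b) {
            double dx = wrapd(gw[3 * a] - scratch[3 * b], sys.Lx);
            double dy = wrapd(gw[3 * a + 1] - scratch[3 * b + 1], sys.Ly);
            double dz = gw[3 * a + 2] - scratch[3 * b + 2];
            double sigma = 0.5 * (gdiam[a] + sys.diam[b]);
            dU += wca(dx * dx + dy * dy + dz * dz, sigma, eps_lj);
            if (dU >= 700.0) break;
          }
        }
        if (dU >= 700.0) break;
      }
      acc += dU >= 700.0 ? 0.0 : std::exp(-dU);
    }
    s_mean[s] = acc / n_insert;
  }
  return s_mean;
}
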