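// Structure-based model potential, analytic forces and Langevin/Verlet
// integration. Coordinates in Angstrom, energies in reduced units, all
// atom masses 1 (reduced) during dynamics.
#include <Rcpp.h>
#include <unordered_set>
#include <cmath>
using namespace Rcpp;

static inline void cross(const double* a, const double* b, double* out) {
  out[0] = a[1] * b[2] - a[2] * b[1];
  out[1] = a[2] * b[0] - a[0] * b[2];
  out[2] = a[0] * b[1] - a[1] * b[0];
}
static inline double dot(const double* a, const double* b) {
  return a[0] * b[0] + a[1] * b[1] + a[2] * b[2];
}
static inline double wrap_pi(double x) {
  while (x > M_PI) x -= 2.0 * M_PI;
  while (x <= -M_PI) x += 2.0 * M_PI;
  return x;
}

struct Terms {
  NumericMatrix bonds, angles, impropers, dihedrals, contacts;
  std::vector<char> excl_map; // n x n exclusion lookup
  int n;
  double eps_r, eps_theta, eps_xi, eps_nc, sigma_nc, nb_cutoff2;
  // Verlet neighbour list for the excluded-volume term
  std::vector<int> nb_i, nb_j;
  bool use_list = false;

  bool excluded(int i, int j) const { return excl_map[(size_t)i * n + j]; }
};

// dV/dphi for a torsion-like term distributed onto the four atoms
static void torsion_force(const double* ri, const double* rj,
                          const double* rk, const double* rl,
                          double dVdphi, double* fi, double* fj,
                          double* fk, double* fl) {
  double b1[3], b2[3], b3[3], n1[3], n2[3];
  for (int d = 0; d < 3; ++d) {
    b1[d] = rj[d] - ri[d];
    b2[d] = rk[d] - rj[d];
    b3[d] = rl[d] - rk[d];
  }
  cross(b1, b2, n1);
  cross(b2, b3, n2);
  double n1sq = dot(n1, n1), n2sq = dot(n2, n2);
  double b2len = std::sqrt(dot(b2, b2));
  if (n1sq < 1e-12 || n2sq < 1e-12 || b2len < 1e-8) return; // degenerate
  double c1 = dot(b1, b2) / (b2len * b2len);
  double c2 = dot(b3, b2) / (b2len * b2len);
  double dpi[3], dpl[3], dpj[3], dpk[3];
  for (int d = 0; d < 3; ++d) {
    dpi[d] = (b2len / n1sq) * n1[d];
    dpl[d] = -(b2len / n2sq) * n2[d];
    dpj[d] = -(1.0 + c1) * dpi[d] + c2 * dpl[d];
    dpk[d] = -(dpi[d] + dpj[d] + dpl[d]); // translational invariance
  }
  for (int d = 0; d < 3; ++d) {
    fi[d] -= dVdphi * dpi[d];
    fj[d] -= dVdphi * dpj[d];
    fk[d] -= dVdphi * dpk[d];
    fl[d] -= dVdphi * dpl[d];
  }
}

static double torsion_angle(const double* ri, const double* rj,
                            const double* rk, const double* rl) {
  double b1[3], b2[3], b3[3], n1[3], n2[3], m1[3];
  for (int d = 0; d < 3; ++d) {
    b1[d] = rj[d] - ri[d];
    b2[d] = rk[d] - rj[d];
    b3[d] = rl[d] - rk[d];
  }
  cross(b1, b2, n1);
  cross(b2, b3, n2);
  double b2len = std::sqrt(dot(b2, b2));
  double b2h[3] = {b2[0] / b2len, b2[1] / b2len, b2[2] / b2len};
  cross(n1, b2h, m1);
  return std::atan2(dot(m1, n2), dot(n1, n2));
}

// potential energy breakdown + forces; fills f (length 3n) if not null
static void eval_all(const double* x, const Terms& T, double* f,
                     double* ebreak) {
  const int n = T.n;
  for (int t = 0; t < 6; ++t) ebreak[t] = 0.0;
  if (f) std::fill(f, f + 3 * n, 0.0);

  // bonds: eps_r (r - r0)^2
  for (int r = 0; r < T.bonds.nrow(); ++r) {
    int i = (int)T.bonds(r, 0) - 1, j = (int)T.bonds(r, 1) - 1;
    double r0 = T.bonds(r, 2);
    double d[3] = {x[3 * i] - x[3 * j], x[3 * i + 1] - x[3 * j + 1],
                   x[3 * i + 2] - x[3 * j + 2]};
    double rr = std::sqrt(dot(d, d));
    double dr = rr - r0;
    ebreak[0] += T.eps_r * dr * dr;
    if (f) {
      double coef = -2.0 * T.eps_r * dr / rr;
      for (int dd = 0; dd < 3; ++dd) {
        f[3 * i + dd] += coef * d[dd];
        f[3 * j + dd] -= coef * d[dd];
      }
    }
  }

  // angles: eps_theta (theta - theta0)^2
  for (int r = 0; r < T.angles.nrow(); ++r) {
    int i = (int)T.angles(r, 0) - 1, j = (int)T.angles(r, 1) - 1,
        k = (int)T.angles(r, 2) - 1;
    double th0 = T.angles(r, 3);
    double u[3], v[3];
    for (int d = 0; d < 3; ++d) {
      u[d] = x[3 * i + d] - x[3 * j + d];
      v[d] = x[3 * k + d] - x[3 * j + d];
    }
    double lu = std::sqrt(dot(u, u)), lv = std::sqrt(dot(v, v));
    double cth = dot(u, v) / (lu * lv);
    cth = std::max(-1.0, std::min(1.0, cth));
    double th = std::acos(cth);
    double dth = th - th0;
    ebreak[1] += T.eps_theta * dth * dth;
    if (f) {
      double sth = std::sqrt(std::max(1e-12, 1.0 - cth * cth));
      double dVdth = 2.0 * T.eps_theta * dth;
      for (int d = 0; d < 3; ++d) {
        double dci = (v[d] / (lu * lv)) - cth * u[d] / (lu * lu);
        double dck = (u[d] / (lu * lv)) - cth * v[d] / (lv * lv);
        double fi = dVdth * dci / sth; // -dV/dri = -dV/dth * (-1/s) dc/dri
        double fk = dVdth * dck / sth;
        f[3 * i + d] += fi;
        f[3 * k + d] += fk;
        f[3 * j + d] -= fi + fk;
      }
    }
  }

  // impropers: eps_xi (xi - xi0)^2, wrapped
  for (int r = 0; r < T.impropers.nrow(); ++r) {
    int i = (int)T.impropers(r, 0) - 1, j = (int)T.impropers(r, 1) - 1,
        k = (int)T.impropers(r, 2) - 1, l = (int)T.impropers(r, 3) - 1;
    double xi0 = T.impropers(r, 4);
    double xi = torsion_angle(&x[3 * i], &x[3 * j], &x[3 * k], &x[3 * l]);
    double dxi = wrap_pi(xi - xi0);
    ebreak[2] += T.eps_xi * dxi * dxi;
    if (f)
      torsion_force(&x[3 * i], &x[3 * j], &x[3 * k], &x[3 * l],
                    2.0 * T.eps_xi * dxi, &f[3 * i], &f[3 * j], &f[3 * k],
                    &f[3 * l]);
  }

  // proper dihedrals: w * ([1-cos(dphi)] + 0.5 [1-cos(3 dphi)])
  for (int r = 0; r < T.dihedrals.nrow(); ++r) {
    double w = T.dihedrals(r, 5);
    if (w == 0.0) continue;
    int i = (int)T.dihedrals(r, 0) - 1, j = (int)T.dihedrals(r, 1) - 1,
        k = (int)T.dihedrals(r, 2) - 1, l = (int)T.dihedrals(r, 3) - 1;
    double phi0 = T.dihedrals(r, 4);
    double phi = torsion_angle(&x[3 * i], &x[3 * j], &x[3 * k], &x[3 * l]);
    double dphi = phi - phi0;
    ebreak[3] += w * ((1.0 - std::cos(dphi)) +
                      0.5 * (1.0 - std::cos(3.0 * dphi)));
    if (f) {
      double dVdphi = w * (std::sin(dphi) + 1.5 * std::sin(3.0 * dphi));
      torsion_force(&x[3 * i], &x[3 * j], &x[3 * k], &x[3 * l], dVdphi,
                    &f[3 * i], &f[3 * j], &f[3 * k], &f[3 * l]);
    }
  }

  // native contacts: eps [ (r0/r)^12 - 2 (r0/r)^6 ]
  for (int r = 0; r < T.contacts.nrow(); ++r) {
    int i = (int)T.contacts(r, 0) - 1, j = (int)T.contacts(r, 1) - 1;
    double r0 = T.contacts(r, 2), eps = T.contacts(r, 3);
    double d[3] = {x[3 * i] - x[3 * j], x[3 * i + 1] - x[3 * j + 1],
                   x[3 * i + 2] - x[3 * j + 2]};
    double rr = std::sqrt(dot(d, d));
    double s6 = std::pow(r0 / rr, 6), s12 = s6 * s6;
    ebreak[4] += eps * (s12 - 2.0 * s6);
    if (f) {
      // dV/dr = eps * (-12 s12 + 12 s6) / r
      double coef = -eps * (-12.0 * s12 + 12.0 * s6) / (rr * rr);
      for (int dd = 0; dd < 3; ++dd) {
        f[3 * i + dd] += coef * d[dd];
        f[3 * j + dd] -= coef * d[dd];
      }
    }
  }

  // excluded volume: eps_nc (sigma/r)^12 over non-excluded pairs
  const double cut2 = T.nb_cutoff2;
  auto pair_term = [&](int i, int j) {
    double d[3] = {x[3 * i] - x[3 * j], x[3 * i + 1] - x[3 * j + 1],
                   x[3 * i + 2] - x[3 * j + 2]};
    double r2 = dot(d, d);
    if (r2 >= cut2) return;
    double s2 = (T.sigma_nc * T.sigma_nc) / r2;
    double s12 = s2 * s2 * s2;
    s12 = s12 * s12;
    ebreak[5] += T.eps_nc * s12;
    if (f) {
      double coef = 12.0 * T.eps_nc * s12 / r2;
      for (int dd = 0; dd < 3; ++dd) {
        f[3 * i + dd] += coef * d[dd];
        f[3 * j + dd] -= coef * d[dd];
      }
    }
  };
  if (T.use_list) {
    for (size_t p = 0; p < T.nb_i.size(); ++p)
      pair_term(T.nb_i[p], T.nb_j[p]);
  } else {
    for (int i = 0; i < n; ++i)
      for (int j = i + 1; j < n; ++j)
        if (!T.excluded(i, j)) pair_term(i, j);
  }
}

// rebuild the Verlet list with `skin` beyond the interaction cutoff
static void build_nblist(const double* x, Terms& T, double skin) {
  const double cut = std::sqrt(T.nb_cutoff2) + skin;
  const double cut2 = cut * cut;
  T.nb_i.clear();
  T.nb_j.clear();
  for (int i = 0; i < T.n; ++i) {
    for (int j = i + 1; j < T.n; ++j) {
      if (T.excluded(i, j)) continue;
      double dx = x[3 * i] - x[3 * j];
      double dy = x[3 * i + 1] - x[3 * j + 1];
      double dz = x[3 * i + 2] - x[3 * j + 2];
      if (dx * dx + dy * dy + dz * dz < cut2) {
        T.nb_i.push_back(i);
        T.nb_j.push_back(j);
      }
    }
  }
  T.use_list = true;
}

static Terms make_terms(NumericMatrix bonds, NumericMatrix angles,
                        NumericMatrix impropers, NumericMatrix dihedrals,
                        NumericMatrix contacts, NumericMatrix exclusions,
                        int n, List params) {
  Terms T;
  T.bonds = bonds;
  T.angles = angles;
  T.impropers = impropers;
  T.dihedrals = dihedrals;
  T.contacts = contacts;
  T.n = n;
  T.eps_r = as<double>(params["eps_r"]);
  T.eps_theta = as<double>(params["eps_theta"]);
  T.eps_xi = as<double>(params["eps_xi"]);
  T.eps_nc = as<double>(params["eps_nc"]);
  T.sigma_nc = as<double>(params["sigma_nc"]);
  double cut = 3.0 * T.sigma_nc;
  T.nb_cutoff2 = cut * cut;
  T.excl_map.assign((size_t)n * n, 0);
  for (int r = 0; r < exclusions.nrow(); ++r) {
    int i = (int)exclusions(r, 0) - 1, j = (int)exclusions(r, 1) - 1;
    T.excl_map[(size_t)i * n + j] = 1;
    T.excl_map[(size_t)j * n + i] = 1;
  }
  return T;
}

// [[Rcpp::export(name = ".cpp_energy_forces")]]
List cpp_energy_forces(NumericMatrix xyz, NumericMatrix bonds,
                       NumericMatrix angles, NumericMatrix impropers,
                       NumericMatrix dihedrals, NumericMatrix contacts,
                       NumericMatrix exclusions, List params,
                       bool want_forces) {
  int n = xyz.nrow();
  std::vector<double> x(3 * n);
  for (int i = 0; i < n; ++i)
    for (int d = 0; d < 3; ++d) {
      x[3 * i + d] = xyz(i, d);
      if (!std::isfinite(x[3 * i + d]))
        stop("non-finite coordinate at atom %d", i + 1);
    }
  Terms T = make_terms(bonds, angles, impropers, dihedrals, contacts,
                       exclusions, n, params);
  double ebreak[6];
  NumericMatrix f(n, 3);
  std::vector<double> fv(want_forces ? 3 * n : 0);
  eval_all(x.data(), T, want_forces ? fv.data() : nullptr, ebreak);
  if (want_forces)
    for (int i = 0; i < n; ++i)
      for (int d = 0; d < 3; ++d) f(i, d) = fv[3 * i + d];
  NumericVector e = NumericVector::create(
      _["bond"] = ebreak[0], _["angle"] = ebreak[1],
      _["improper"] = ebreak[2], _["dihedral"] = ebreak[3],
      _["contact"] = ebreak[4], _["excluded_volume"] = ebreak[5]);
  return List::create(_["energy"] = e, _["forces"] = f);
}

// BAOAB Langevin (velocity Verlet when friction == 0), unit masses.
// Snapshots every save_every steps; returns frames, per-frame potential
// and kinetic energy. Uses R's RNG so results follow set.seed().
// [[Rcpp::export(name = ".cpp_langevin")]]
List cpp_langevin(NumericMatrix xyz, NumericMatrix bonds,
                  NumericMatrix angles, NumericMatrix impropers,
                  NumericMatrix dihedrals, NumericMatrix contacts,
                  NumericMatrix exclusions, List params, double dt,
                  int nsteps, int save_every, double temperature,
                  double friction, NumericVector v0, double energy_bound,
                  int nburn) {
  int n = xyz.nrow();
  std::vector<double> x(3 * n), v(3 * n), f(3 * n);
  for (int i = 0; i < n; ++i)
    for (int d = 0; d < 3; ++d) x[3 * i + d] = xyz(i, d);
  for (int i = 0; i < 3 * n; ++i) v[i] = v0[i];
  Terms T = make_terms(bonds, angles, impropers, dihedrals, contacts,
                       exclusions, n, params);
  // Verlet list: 2 A skin, rebuilt every 200 steps (ample margin at the
  // displacement per step this timestep and temperature range produce)
  const int nb_stride = 200;
  const double nb_skin = 2.0;
  build_nblist(x.data(), T, nb_skin);
  double ebreak[6];
  eval_all(x.data(), T, f.data(), ebreak);

  double c1 = (friction > 0.0) ? std::exp(-friction * dt) : 1.0;
  double c2 = (friction > 0.0 && temperature > 0.0)
                  ? std::sqrt((1.0 - c1 * c1) * temperature)
                  : 0.0;
  int nframes = nsteps / save_every;
  NumericMatrix frames(nframes, 3 * n);
  NumericVector epot(nframes), ekin(nframes);
  RNGScope rng;
  int fcount = 0;
  for (int step = 1 - nburn; step <= nsteps; ++step) {
    for (int i = 0; i < 3 * n; ++i) v[i] += 0.5 * dt * f[i]; // B
    for (int i = 0; i < 3 * n; ++i) x[i] += 0.5 * dt * v[i]; // A
    if (friction > 0.0) {                                    // O
      if (c2 > 0.0)
        for (int i = 0; i < 3 * n; ++i)
          v[i] = c1 * v[i] + c2 * norm_rand();
      else
        for (int i = 0; i < 3 * n; ++i) v[i] = c1 * v[i];
    }
    for (int i = 0; i < 3 * n; ++i) x[i] += 0.5 * dt * v[i]; // A
    if (step % nb_stride == 0) build_nblist(x.data(), T, nb_skin);
    eval_all(x.data(), T, f.data(), ebreak);
    for (int i = 0; i < 3 * n; ++i) v[i] += 0.5 * dt * f[i]; // B
    double V = ebreak[0] + ebreak[1] + ebreak[2] + ebreak[3] + ebreak[4] +
               ebreak[5];
    if (!std::isfinite(V) || std::fabs(V) > energy_bound)
      stop("energy divergence at step %d (V = %g); reduce the timestep",
           step, V);
    if (step > 0 && step % save_every == 0) {
      for (int i = 0; i < 3 * n; ++i) frames(fcount, i) = x[i];
      double K = 0.0;
      for (int i = 0; i < 3 * n; ++i) K += 0.5 * v[i] * v[i];
      epot[fcount] = V;
      ekin[fcount] = K;
      ++fcount;
    }
    if (step % 2000 == 0) checkUserInterrupt();
  }
  return List::create(_["frames"] = frames, _["potential"] = epot,
                      _["kinetic"] = ekin);
}
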