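// Compiled core of the minimalist coarse-grained model: per-term energies,
// analytic forces, and the BAOAB Langevin integrator with SHAKE/RATTLE
// holonomic bond constraints. Units: Angstrom / ps / amu / kcal/mol.
#include <Rcpp.h>
#include <random>
#include <cmath>
using namespace Rcpp;

static const double KCAL_TO_INT = 418.4;       // kcal/mol -> amu A^2/ps^2
static const double KB_KCAL = 1.9872041e-3;    // kcal/(mol K)

struct Topo {
  NumericMatrix bonds;      // i j d0          (0-based indices)
  NumericMatrix angles;     // i j k theta0 ktheta
  NumericMatrix dihedrals;  // i j k l phi0 A
  NumericMatrix local;      // i j r0 eps alpha
  NumericMatrix nonlocal;   // i j
  double nl_r0, nl_eps, nl_alpha, nl_cut, nl_shift;
  Topo(List t, double r0, double eps, double alpha, double cut)
    : bonds(as<NumericMatrix>(t["bonds"])),
      angles(as<NumericMatrix>(t["angles"])),
      dihedrals(as<NumericMatrix>(t["dihedrals"])),
      local(as<NumericMatrix>(t["local_pairs"])),
      nonlocal(as<NumericMatrix>(t["nonlocal_pairs"])),
      nl_r0(r0), nl_eps(eps), nl_alpha(alpha), nl_cut(cut) {
    double e = std::exp(-nl_alpha * (nl_cut - nl_r0));
    nl_shift = nl_eps * ((e - 1.0) * (e - 1.0) - 1.0);
  }
};

static inline void addv(std::vector<double>& f, int i, double fx, double fy,
                        double fz) {
  f[3 * i] += fx; f[3 * i + 1] += fy; f[3 * i + 2] += fz;
}

// energies: bond_penalty, angle, dihedral, local, nonlocal, total
static void eval_ff(const std::vector<double>& x, int n, const Topo& tp,
                    double harmonic_k, std::vector<double>& f,
                    double* energies) {
  std::fill(f.begin(), f.end(), 0.0);
  double e_bond = 0, e_ang = 0, e_dih = 0, e_loc = 0, e_nl = 0;

  // bond restraint (harmonic bookkeeping; zero under exact constraints)
  if (harmonic_k > 0) {
    for (int b = 0; b < tp.bonds.nrow(); ++b) {
      int i = (int)tp.bonds(b, 0), j = (int)tp.bonds(b, 1);
      double d0 = tp.bonds(b, 2);
      double dx = x[3*i] - x[3*j], dy = x[3*i+1] - x[3*j+1],
             dz = x[3*i+2] - x[3*j+2];
      double r = std::sqrt(dx*dx + dy*dy + dz*dz);
      double dr = r - d0;
      e_bond += 0.5 * harmonic_k * dr * dr;
      double fr = -harmonic_k * dr / r;
      addv(f, i, fr*dx, fr*dy, fr*dz);
      addv(f, j, -fr*dx, -fr*dy, -fr*dz);
    }
  }

  // angle: 1/2 k (cos t - cos t0)^2
  for (int a = 0; a < tp.angles.nrow(); ++a) {
    int i = (int)tp.angles(a, 0), j = (int)tp.angles(a, 1),
        k = (int)tp.angles(a, 2);
    double t0 = tp.angles(a, 3), kt = tp.angles(a, 4);
    double ux = x[3*i]-x[3*j], uy = x[3*i+1]-x[3*j+1], uz = x[3*i+2]-x[3*j+2];
    double vx = x[3*k]-x[3*j], vy = x[3*k+1]-x[3*j+1], vz = x[3*k+2]-x[3*j+2];
    double nu = std::sqrt(ux*ux + uy*uy + uz*uz);
    double nv = std::sqrt(vx*vx + vy*vy + vz*vz);
    double c = (ux*vx + uy*vy + uz*vz) / (nu * nv);
    if (c > 1) c = 1; if (c < -1) c = -1;
    double dc = c - std::cos(t0);
    e_ang += 0.5 * kt * dc * dc;
    double pref = -kt * dc;  // force = pref * dc/dr
    double inun = 1.0 / (nu * nv);
    double g1x = vx*inun - c*ux/(nu*nu), g1y = vy*inun - c*uy/(nu*nu),
           g1z = vz*inun - c*uz/(nu*nu);
    double g3x = ux*inun - c*vx/(nv*nv), g3y = uy*inun - c*vy/(nv*nv),
           g3z = uz*inun - c*vz/(nv*nv);
    addv(f, i, pref*g1x, pref*g1y, pref*g1z);
    addv(f, k, pref*g3x, pref*g3y, pref*g3z);
    addv(f, j, -pref*(g1x+g3x), -pref*(g1y+g3y), -pref*(g1z+g3z));
  }

  // dihedral: A (1 - cos(phi - phi0))
  for (int d = 0; d < tp.dihedrals.nrow(); ++d) {
    int i1 = (int)tp.dihedrals(d, 0), i2 = (int)tp.dihedrals(d, 1),
        i3 = (int)tp.dihedrals(d, 2), i4 = (int)tp.dihedrals(d, 3);
    double p0 = tp.dihedrals(d, 4), A = tp.dihedrals(d, 5);
    double b1x = x[3*i2]-x[3*i1], b1y = x[3*i2+1]-x[3*i1+1],
           b1z = x[3*i2+2]-x[3*i1+2];
    double b2x = x[3*i3]-x[3*i2], b2y = x[3*i3+1]-x[3*i2+1],
           b2z = x[3*i3+2]-x[3*i2+2];
    double b3x = x[3*i4]-x[3*i3], b3y = x[3*i4+1]-x[3*i3+1],
           b3z = x[3*i4+2]-x[3*i3+2];
    double n1x = b1y*b2z - b1z*b2y, n1y = b1z*b2x - b1x*b2z,
           n1z = b1x*b2y - b1y*b2x;
    double n2x = b2y*b3z - b2z*b3y, n2y = b2z*b3x - b2x*b3z,
           n2z = b2x*b3y - b2y*b3x;
    double nb2 = std::sqrt(b2x*b2x + b2y*b2y + b2z*b2z);
    double m1x = n1y*b2z - n1z*b2y, m1y = n1z*b2x - n1x*b2z,
           m1z = n1x*b2y - n1y*b2x;  // n1 x b2 (unnormalized)
    double sy = -(m1x*n2x + m1y*n2y + m1z*n2z) / nb2;
    double sx = n1x*n2x + n1y*n2y + n1z*n2z;
    double phi = std::atan2(sy, sx);
    e_dih += A * (1.0 - std::cos(phi - p0));
    double dUdphi = A * std::sin(phi - p0);
    double n1sq = n1x*n1x + n1y*n1y + n1z*n1z;
    double n2sq = n2x*n2x + n2y*n2y + n2z*n2z;
    if (n1sq < 1e-12 || n2sq < 1e-12) continue;  // collinear: no torque
    double t1 = -nb2 / n1sq;   // dphi/dr1 = t1 * n1
    double t4 =  nb2 / n2sq;   // dphi/dr4 = t4 * n2
    double s12 = (b1x*b2x + b1y*b2y + b1z*b2z) / (nb2*nb2);
    double s32 = (b3x*b2x + b3y*b2y + b3z*b2z) / (nb2*nb2);
    double g1x = t1*n1x, g1y = t1*n1y, g1z = t1*n1z;
    double g4x = t4*n2x, g4y = t4*n2y, g4z = t4*n2z;
    double g2x = -(1.0 + s12)*g1x + s32*g4x;
    double g2y = -(1.0 + s12)*g1y + s32*g4y;
    double g2z = -(1.0 + s12)*g1z + s32*g4z;
    double g3x = -(g1x + g2x + g4x), g3y = -(g1y + g2y + g4y),
           g3z = -(g1z + g2z + g4z);
    addv(f, i1, -dUdphi*g1x, -dUdphi*g1y, -dUdphi*g1z);
    addv(f, i2, -dUdphi*g2x, -dUdphi*g2y, -dUdphi*g2z);
    addv(f, i3, -dUdphi*g3x, -dUdphi*g3y, -dUdphi*g3z);
    addv(f, i4, -dUdphi*g4x, -dUdphi*g4y, -dUdphi*g4z);
  }

  // local Morse pairs (structure-biased)
  for (int p = 0; p < tp.local.nrow(); ++p) {
    int i = (int)tp.local(p, 0), j = (int)tp.local(p, 1);
    double r0 = tp.local(p, 2), eps = tp.local(p, 3), al = tp.local(p, 4);
    double dx = x[3*i]-x[3*j], dy = x[3*i+1]-x[3*j+1], dz = x[3*i+2]-x[3*j+2];
    double r = std::sqrt(dx*dx + dy*dy + dz*dz);
    if (r < 0.1) stop("overlapping beads %d and %d (r = %f A)", i + 1, j + 1, r);
    double e = std::exp(-al * (r - r0));
    e_loc += eps * ((e - 1.0)*(e - 1.0) - 1.0);
    double fr = 2.0 * al * eps * e * (e - 1.0) / r;  // -dU/dr / r
    addv(f, i, fr*dx, fr*dy, fr*dz);
    addv(f, j, -fr*dx, -fr*dy, -fr*dz);
  }

  // non-local Morse pairs (generic), truncated & shifted at nl_cut
  for (int p = 0; p < tp.nonlocal.nrow(); ++p) {
    int i = (int)tp.nonlocal(p, 0), j = (int)tp.nonlocal(p, 1);
    double dx = x[3*i]-x[3*j], dy = x[3*i+1]-x[3*j+1], dz = x[3*i+2]-x[3*j+2];
    double r2 = dx*dx + dy*dy + dz*dz;
    if (r2 >= tp.nl_cut * tp.nl_cut) continue;
    double r = std::sqrt(r2);
    if (r < 0.1) stop("overlapping beads %d and %d (r = %f A)", i + 1, j + 1, r);
    double e = std::exp(-tp.nl_alpha * (r - tp.nl_r0));
    e_nl += tp.nl_eps * ((e - 1.0)*(e - 1.0) - 1.0) - tp.nl_shift;
    double fr = 2.0 * tp.nl_alpha * tp.nl_eps * e * (e - 1.0) / r;
    addv(f, i, fr*dx, fr*dy, fr*dz);
    addv(f, j, -fr*dx, -fr*dy, -fr*dz);
  }

  energies[0] = e_bond; energies[1] = e_ang; energies[2] = e_dih;
  energies[3] = e_loc; energies[4] = e_nl;
  energies[5] = e_bond + e_ang + e_dih + e_loc + e_nl;
}

static std::vector<double> flatten(NumericMatrix m) {
  int n = m.nrow();
  std::vector<double> x(3 * n);
  for (int i = 0; i < n; ++i)
    for (int k = 0; k < 3; ++k) x[3*i + k] = m(i, k);
  return x;
}

// [[Rcpp::export]]
NumericVector mcg_energy_cpp(NumericMatrix coords, List topo, double harmonic_k,
                             double nl_r0, double nl_eps, double nl_alpha,
                             double nl_cut) {
  Topo tp(topo, nl_r0, nl_eps, nl_alpha, nl_cut);
  std::vector<double> x = flatten(coords), f(x.size());
  double e[6];
  eval_ff(x, coords.nrow(), tp, harmonic_k, f, e);
  return NumericVector::create(e[0], e[1], e[2], e[3], e[4], e[5]);
}

// [[Rcpp::export]]
NumericMatrix mcg_forces_cpp(NumericMatrix coords, List topo, double harmonic_k,
                             double nl_r0, double nl_eps, double nl_alpha,
                             double nl_cut) {
  Topo tp(topo, nl_r0, nl_eps, nl_alpha, nl_cut);
  std::vector<double> x = flatten(coords), f(x.size());
  double e[6];
  eval_ff(x, coords.nrow(), tp, harmonic_k, f, e);
  int n = coords.nrow();
  NumericMatrix out(n, 3);
  for (int i = 0; i < n; ++i)
    for (int k = 0; k < 3; ++k) out(i, k) = f[3*i + k];
  return out;
}

// SHAKE: iteratively restore bond lengths; corrections along the reference
// (pre-move) bond directions, mass-weighted.
static int shake(std::vector<double>& x, const std::vector<double>& xref,
                 const NumericMatrix& bonds, const std::vector<double>& mass,
                 double tol, int maxit) {
  int nb = bonds.nrow();
  for (int it = 0; it < maxit; ++it) {
    double worst = 0;
    for (int b = 0; b < nb; ++b) {
      int i = (int)bonds(b, 0), j = (int)bonds(b, 1);
      double d0 = bonds(b, 2);
      double rx = x[3*i]-x[3*j], ry = x[3*i+1]-x[3*j+1], rz = x[3*i+2]-x[3*j+2];
      double r2 = rx*rx + ry*ry + rz*rz;
      double diff = r2 - d0*d0;
      double err = std::fabs(std::sqrt(r2) - d0);
      if (err > worst) worst = err;
      if (err <= tol) continue;
      double sx = xref[3*i]-xref[3*j], sy = xref[3*i+1]-xref[3*j+1],
             sz = xref[3*i+2]-xref[3*j+2];
      double sr = sx*rx + sy*ry + sz*rz;
      double im = 1.0/mass[i] + 1.0/mass[j];
      double g = diff / (2.0 * im * sr);
      x[3*i]   -= g * sx / mass[i]; x[3*i+1] -= g * sy / mass[i];
      x[3*i+2] -= g * sz / mass[i];
      x[3*j]   += g * sx / mass[j]; x[3*j+1] += g * sy / mass[j];
      x[3*j+2] += g * sz / mass[j];
    }
    if (worst <= tol) return it + 1;
  }
  return -1;
}

// RATTLE velocity stage: project out relative velocity along each bond.
static void rattle_v(std::vector<double>& v, const std::vector<double>& x,
                     const NumericMatrix& bonds, const std::vector<double>& mass,
                     double tol, int maxit) {
  int nb = bonds.nrow();
  for (int it = 0; it < maxit; ++it) {
    double worst = 0;
    for (int b = 0; b < nb; ++b) {
      int i = (int)bonds(b, 0), j = (int)bonds(b, 1);
      double rx = x[3*i]-x[3*j], ry = x[3*i+1]-x[3*j+1], rz = x[3*i+2]-x[3*j+2];
      double r2 = rx*rx + ry*ry + rz*rz;
      double rv = (v[3*i]-v[3*j])*rx + (v[3*i+1]-v[3*j+1])*ry +
                  (v[3*i+2]-v[3*j+2])*rz;
      double im = 1.0/mass[i] + 1.0/mass[j];
      double k = rv / (r2 * im);
      double err = std::fabs(rv) / std::sqrt(r2);
      if (err > worst) worst = err;
      v[3*i]   -= k * rx / mass[i]; v[3*i+1] -= k * ry / mass[i];
      v[3*i+2] -= k * rz / mass[i];
      v[3*j]   += k * rx / mass[j]; v[3*j+1] += k * ry / mass[j];
      v[3*j+2] += k * rz / mass[j];
    }
    if (worst <= tol) break;
  }
}

// BAOAB Langevin integrator. bond_mode: 0 = holonomic constraints (SHAKE),
// 1 = stiff harmonic restraints. Returns dumped frames with per-term
// energies, kinetic energy and instantaneous temperature.
// [[Rcpp::export]]
List run_ld_cpp(NumericMatrix coords, NumericMatrix vel, List topo,
                NumericVector masses, double dt, double gamma,
                double temperature, int n_steps, int dump_interval,
                int seed, int bond_mode, double harmonic_k,
                double constraint_tol, double nl_r0, double nl_eps,
                double nl_alpha, double nl_cut, int dof) {
  int n = coords.nrow();
  Topo tp(topo, nl_r0, nl_eps, nl_alpha, nl_cut);
  std::vector<double> x = flatten(coords), v = flatten(vel), f(3 * n);
  std::vector<double> mass(masses.begin(), masses.end());
  bool constrain = (bond_mode == 0);
  double hk = constrain ? 0.0 : harmonic_k;
  double e[6];

  std::mt19937_64 rng(seed);
  std::normal_distribution<double> gauss(0.0, 1.0);
  double kbT_int = KB_KCAL * KCAL_TO_INT * temperature;  // amu A^2/ps^2
  double c1 = std::exp(-gamma * dt);
  double c2 = std::sqrt(1.0 - c1 * c1);
  if (gamma == 0) { c1 = 1.0; c2 = 0.0; }

  int n_dumps = n_steps / dump_interval + 1;  // includes the initial frame
  NumericMatrix energies(n_dumps, 6);
  NumericVector ekin(n_dumps), tinst(n_dumps), times(n_dumps);
  List frames(n_dumps);

  eval_ff(x, n, tp, hk, f, e);
  int idump = 0;
  auto dump = [&](int step) {
    NumericMatrix fr(n, 3);
    for (int i = 0; i < n; ++i)
      for (int k = 0; k < 3; ++k) fr(i, k) = x[3*i + k];
    double ke_int = 0;
    for (int i = 0; i < n; ++i)
      ke_int += 0.5 * mass[i] * (v[3*i]*v[3*i] + v[3*i+1]*v[3*i+1] +
                                 v[3*i+2]*v[3*i+2]);
    frames[idump] = fr;
    for (int k = 0; k < 6; ++k) energies(idump, k) = e[k];
    ekin[idump] = ke_int / KCAL_TO_INT;
    tinst[idump] = 2.0 * ke_int / (dof * KB_KCAL * KCAL_TO_INT);
    times[idump] = step * dt;
    ++idump;
  };
  dump(0);

  std::vector<double> xu(3 * n), xold(3 * n);
  for (int step = 1; step <= n_steps; ++step) {
    // B: half kick (forces in kcal/mol/A -> internal acceleration)
    for (int i = 0; i < n; ++i) {
      double a = 0.5 * dt * KCAL_TO_INT / mass[i];
      v[3*i] += a * f[3*i]; v[3*i+1] += a * f[3*i+1]; v[3*i+2] += a * f[3*i+2];
    }
    // A: half drift (+ SHAKE with velocity correction)
    for (int half = 0; half < 2; ++half) {
      if (half == 1) {
        // O: Ornstein-Uhlenbeck between the two half drifts
        for (int i = 0; i < n; ++i) {
          double s = std::sqrt(kbT_int / mass[i]);
          for (int k = 0; k < 3; ++k)
            v[3*i+k] = c1 * v[3*i+k] + c2 * s * gauss(rng);
        }
        if (constrain) rattle_v(v, x, tp.bonds, mass, 1e-10, 500);
      }
      xold = x;
      for (size_t k = 0; k < x.size(); ++k) xu[k] = x[k] + 0.5 * dt * v[k];
      if (constrain) {
        x = xu;
        int its = shake(x, xold, tp.bonds, mass, constraint_tol, 500);
        if (its < 0) stop("SHAKE failed to converge at step %d", step);
        for (size_t k = 0; k < x.size(); ++k)
          v[k] += (x[k] - xu[k]) / (0.5 * dt);
      } else {
        x = xu;
      }
    }
    // B: half kick with new forces
    eval_ff(x, n, tp, hk, f, e);
    for (int i = 0; i < n; ++i) {
      double a = 0.5 * dt * KCAL_TO_INT / mass[i];
      v[3*i] += a * f[3*i]; v[3*i+1] += a * f[3*i+1]; v[3*i+2] += a * f[3*i+2];
    }
    if (constrain) rattle_v(v, x, tp.bonds, mass, 1e-10, 500);

    for (size_t k = 0; k < x.size(); ++k)
      if (!std::isfinite(x[k])) {
        double md = 0;
        for (size_t q = 0; q < x.size(); ++q)
          if (std::isfinite(x[q]) && std::isfinite(xold[q]))
            md = std::max(md, std::fabs(x[q] - xold[q]));
        stop("non-finite coordinate at step %d (max finite displacement %f A):"
             " simulation blow-up, reduce dt or check the topology", step, md);
      }
    if (step % dump_interval == 0) dump(step);
  }

  NumericMatrix vout(n, 3);
  for (int i = 0; i < n; ++i)
    for (int k = 0; k < 3; ++k) vout(i, k) = v[3*i + k];
  return List::create(_["times"] = times, _["frames"] = frames,
                      _["energies"] = energies, _["ekin"] = ekin,
                      _["tinst"] = tinst, _["velocities"] = vout);
}
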