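// Inner loops of the coarse-grained engine: potential energy / analytic
// forces for the Ca Go-like model (12-10 native wells, r^-12 excluded
// volume, shifted Debye-Hueckel electrostatics, harmonic angle/restraint and
// cosine dihedral terms), a BAOAB Langevin integrator with post-step SHAKE
// on virtual bonds under cubic PBC, and a Gillespie sampler for synthetic
// continuous-time Markov chains.
//
// Units: kcal/mol, Angstrom, ps, Dalton, Kelvin, elementary charge.
#include <Rcpp.h>
#include <cmath>
#include <random>
#include <vector>
using namespace Rcpp;

// F [kcal/mol/A] / m [Da] -> acceleration [A/ps^2]
static const double FCONV = 418.4;
static const double KB = 0.0019872;  // kcal/mol/K

struct Vec3 {
  double x, y, z;
  Vec3() : x(0), y(0), z(0) {}
  Vec3(double a, double b, double c) : x(a), y(b), z(c) {}
};
static inline Vec3 operator-(const Vec3& a, const Vec3& b) {
  return Vec3(a.x - b.x, a.y - b.y, a.z - b.z);
}
static inline Vec3 operator+(const Vec3& a, const Vec3& b) {
  return Vec3(a.x + b.x, a.y + b.y, a.z + b.z);
}
static inline Vec3 operator*(double s, const Vec3& a) {
  return Vec3(s * a.x, s * a.y, s * a.z);
}
static inline double dot(const Vec3& a, const Vec3& b) {
  return a.x * b.x + a.y * b.y + a.z * b.z;
}
static inline Vec3 cross(const Vec3& a, const Vec3& b) {
  return Vec3(a.y * b.z - a.z * b.y, a.z * b.x - a.x * b.z,
              a.x * b.y - a.y * b.x);
}
static inline double norm(const Vec3& a) { return std::sqrt(dot(a, a)); }

// minimum image for cubic box; box <= 0 disables PBC
static inline Vec3 mimg(Vec3 d, double box) {
  if (box > 0) {
    d.x -= box * std::round(d.x / box);
    d.y -= box * std::round(d.y / box);
    d.z -= box * std::round(d.z / box);
  }
  return d;
}

struct System {
  int n;
  std::vector<double> mass, charge;
  // bonds (consecutive residues; SHAKE targets)
  std::vector<int> b_i, b_j;
  std::vector<double> b_r0;
  double k_bond;  // used only when bonds are unconstrained
  // angles
  std::vector<int> a_i, a_j, a_k;
  std::vector<double> a_t0;
  double k_angle;
  // dihedrals: U = k1(1-cos(phi-phi0)) + k3(1-cos(3(phi-phi0)))
  std::vector<int> d_i, d_j, d_k, d_l;
  std::vector<double> d_p0;
  double k_dih1, k_dih3;
  // nonbonded pair list (all non-excluded i<j): type 0 = excluded volume,
  // type 1 = native contact (r0/eps set); cls 0 intra, 1 inter (breakdown)
  std::vector<int> p_i, p_j, p_type, p_cls;
  std::vector<double> p_r0, p_eps;
  // harmonic distance restraints (zinc coordination)
  std::vector<int> r_i, r_j;
  std::vector<double> r_r0, r_k;
  double sigma_rep, eps_rep;
  double cutoff;
  // electrostatics: U = kc qi qj exp(-kappa r) / (epsr r), shifted
  double kc_over_epsr, kappa;
  double box;

  void unpack(const List& sys) {
    n = as<int>(sys["n"]);
    mass = as<std::vector<double>>(sys["mass"]);
    charge = as<std::vector<double>>(sys["charge"]);
    b_i = as<std::vector<int>>(sys["b_i"]);
    b_j = as<std::vector<int>>(sys["b_j"]);
    b_r0 = as<std::vector<double>>(sys["b_r0"]);
    k_bond = as<double>(sys["k_bond"]);
    a_i = as<std::vector<int>>(sys["a_i"]);
    a_j = as<std::vector<int>>(sys["a_j"]);
    a_k = as<std::vector<int>>(sys["a_k"]);
    a_t0 = as<std::vector<double>>(sys["a_t0"]);
    k_angle = as<double>(sys["k_angle"]);
    d_i = as<std::vector<int>>(sys["d_i"]);
    d_j = as<std::vector<int>>(sys["d_j"]);
    d_k = as<std::vector<int>>(sys["d_k"]);
    d_l = as<std::vector<int>>(sys["d_l"]);
    d_p0 = as<std::vector<double>>(sys["d_p0"]);
    k_dih1 = as<double>(sys["k_dih1"]);
    k_dih3 = as<double>(sys["k_dih3"]);
    p_i = as<std::vector<int>>(sys["p_i"]);
    p_j = as<std::vector<int>>(sys["p_j"]);
    p_type = as<std::vector<int>>(sys["p_type"]);
    p_cls = as<std::vector<int>>(sys["p_cls"]);
    p_r0 = as<std::vector<double>>(sys["p_r0"]);
    p_eps = as<std::vector<double>>(sys["p_eps"]);
    r_i = as<std::vector<int>>(sys["r_i"]);
    r_j = as<std::vector<int>>(sys["r_j"]);
    r_r0 = as<std::vector<double>>(sys["r_r0"]);
    r_k = as<std::vector<double>>(sys["r_k"]);
    sigma_rep = as<double>(sys["sigma_rep"]);
    eps_rep = as<double>(sys["eps_rep"]);
    cutoff = as<double>(sys["cutoff"]);
    kc_over_epsr = as<double>(sys["kc_over_epsr"]);
    kappa = as<double>(sys["kappa"]);
    box = as<double>(sys["box"]);
  }
};

struct Breakdown {
  double bond = 0, angle = 0, dihedral = 0, contact_intra = 0,
         contact_inter = 0, excluded = 0, elec = 0, restraint = 0;
  double total() const {
    return bond + angle + dihedral + contact_intra + contact_inter + excluded +
           elec + restraint;
  }
};

static inline double u1210(double r, double r0, double eps) {
  double s = r0 / r;
  double s2 = s * s;
  double s10 = s2 * s2 * s2 * s2 * s2;
  return eps * (5.0 * s10 * s2 - 6.0 * s10);
}
// dU/dr for the 12-10 well
static inline double du1210(double r, double r0, double eps) {
  double s = r0 / r;
  double s2 = s * s;
  double s10 = s2 * s2 * s2 * s2 * s2;
  return (60.0 * eps / r) * (s10 - s10 * s2);
}

// Potential energy and forces; forces accumulated into f (may be null).
static Breakdown energy_forces(const System& S, const std::vector<Vec3>& x,
                               std::vector<Vec3>* f, bool constrained_bonds) {
  Breakdown e;
  const double box = S.box;
  // bonds (skipped when SHAKE keeps them fixed)
  if (!constrained_bonds) {
    for (size_t b = 0; b < S.b_i.size(); ++b) {
      Vec3 d = mimg(x[S.b_i[b]] - x[S.b_j[b]], box);
      double r = norm(d);
      double dr = r - S.b_r0[b];
      e.bond += S.k_bond * dr * dr;
      if (f) {
        double c = -2.0 * S.k_bond * dr / r;
        (*f)[S.b_i[b]] = (*f)[S.b_i[b]] + c * d;
        (*f)[S.b_j[b]] = (*f)[S.b_j[b]] - c * d;
      }
    }
  }
  // angles: U = k (theta - theta0)^2
  for (size_t a = 0; a < S.a_i.size(); ++a) {
    Vec3 u = mimg(x[S.a_i[a]] - x[S.a_j[a]], box);
    Vec3 v = mimg(x[S.a_k[a]] - x[S.a_j[a]], box);
    double nu = norm(u), nv = norm(v);
    double ct = dot(u, v) / (nu * nv);
    ct = std::max(-1.0, std::min(1.0, ct));
    double th = std::acos(ct);
    double dth = th - S.a_t0[a];
    e.angle += S.k_angle * dth * dth;
    if (f) {
      double st = std::sqrt(std::max(1e-12, 1.0 - ct * ct));
      double dUdth = 2.0 * S.k_angle * dth;
      // dtheta/dxi = -(1/sin) * d(cos)/dxi
      Vec3 dci = (1.0 / nu) * ((1.0 / nv) * v - (ct / nu) * u);
      Vec3 dck = (1.0 / nv) * ((1.0 / nu) * u - (ct / nv) * v);
      Vec3 fi = (dUdth / st) * dci;  // force = -dU/dx; signs fold together
      Vec3 fk = (dUdth / st) * dck;
      (*f)[S.a_i[a]] = (*f)[S.a_i[a]] + fi;
      (*f)[S.a_k[a]] = (*f)[S.a_k[a]] + fk;
      (*f)[S.a_j[a]] = (*f)[S.a_j[a]] - fi - fk;
    }
  }
  // dihedrals
  for (size_t d = 0; d < S.d_i.size(); ++d) {
    Vec3 b1 = mimg(x[S.d_j[d]] - x[S.d_i[d]], box);
    Vec3 b2 = mimg(x[S.d_k[d]] - x[S.d_j[d]], box);
    Vec3 b3 = mimg(x[S.d_l[d]] - x[S.d_k[d]], box);
    Vec3 n1 = cross(b1, b2), n2 = cross(b2, b3);
    double n1sq = dot(n1, n1), n2sq = dot(n2, n2);
    double nb2 = norm(b2);
    if (n1sq < 1e-12 || n2sq < 1e-12) continue;  // collinear: undefined
    double phi = std::atan2(dot(cross(n1, n2), (1.0 / nb2) * b2), dot(n1, n2));
    double dphi = phi - S.d_p0[d];
    e.dihedral += S.k_dih1 * (1.0 - std::cos(dphi)) +
                  S.k_dih3 * (1.0 - std::cos(3.0 * dphi));
    if (f) {
      double dUdphi =
          S.k_dih1 * std::sin(dphi) + 3.0 * S.k_dih3 * std::sin(3.0 * dphi);
      Vec3 fi = (dUdphi * nb2 / n1sq) * n1;
      Vec3 fl = (-dUdphi * nb2 / n2sq) * n2;
      double t = dot(b1, b2) / (nb2 * nb2);
      double s = dot(b3, b2) / (nb2 * nb2);
      Vec3 fj = (-(1.0 + t)) * fi + s * fl;
      Vec3 fk = t * fi + (-(1.0 + s)) * fl;
      (*f)[S.d_i[d]] = (*f)[S.d_i[d]] + fi;
      (*f)[S.d_j[d]] = (*f)[S.d_j[d]] + fj;
      (*f)[S.d_k[d]] = (*f)[S.d_k[d]] + fk;
      (*f)[S.d_l[d]] = (*f)[S.d_l[d]] + fl;
    }
  }
  // nonbonded pair list: native wells, excluded volume, electrostatics,
  // all shifted to zero at the cutoff
  const double rc = S.cutoff;
  const double sig12 = std::pow(S.sigma_rep, 12);
  const double ev_shift = S.eps_rep * sig12 / std::pow(rc, 12);
  for (size_t p = 0; p < S.p_i.size(); ++p) {
    int i = S.p_i[p], j = S.p_j[p];
    Vec3 d = mimg(x[i] - x[j], box);
    double r2 = dot(d, d);
    if (r2 >= rc * rc) continue;
    double r = std::sqrt(r2);
    if (r < 1e-6) stop("overlapping particles (pair %d,%d)", i + 1, j + 1);
    double dudr = 0.0;
    if (S.p_type[p] == 1) {
      double u = u1210(r, S.p_r0[p], S.p_eps[p]) -
                 u1210(rc, S.p_r0[p], S.p_eps[p]);
      if (S.p_cls[p] == 1)
        e.contact_inter += u;
      else
        e.contact_intra += u;
      dudr += du1210(r, S.p_r0[p], S.p_eps[p]);
    } else {
      double r6 = r2 * r2 * r2;
      double r12 = r6 * r6;
      double u = S.eps_rep * sig12 / r12 - ev_shift;
      e.excluded += u;
      dudr += -12.0 * S.eps_rep * sig12 / (r12 * r);
    }
    double qq = S.charge[i] * S.charge[j];
    if (qq != 0.0) {
      double A = S.kc_over_epsr * qq;
      double u = A * std::exp(-S.kappa * r) / r -
                 A * std::exp(-S.kappa * rc) / rc;
      e.elec += u;
      dudr += -A * std::exp(-S.kappa * r) * (S.kappa * r + 1.0) / r2;
    }
    if (f && dudr != 0.0) {
      double c = -dudr / r;
      (*f)[i] = (*f)[i] + c * d;
      (*f)[j] = (*f)[j] - c * d;
    }
  }
  // restraints
  for (size_t rr = 0; rr < S.r_i.size(); ++rr) {
    Vec3 d = mimg(x[S.r_i[rr]] - x[S.r_j[rr]], box);
    double r = norm(d);
    double dr = r - S.r_r0[rr];
    e.restraint += S.r_k[rr] * dr * dr;
    if (f) {
      double c = -2.0 * S.r_k[rr] * dr / r;
      (*f)[S.r_i[rr]] = (*f)[S.r_i[rr]] + c * d;
      (*f)[S.r_j[rr]] = (*f)[S.r_j[rr]] - c * d;
    }
  }
  return e;
}

static std::vector<Vec3> mat_to_vec(const NumericMatrix& m) {
  std::vector<Vec3> x(m.nrow());
  for (int i = 0; i < m.nrow(); ++i) x[i] = Vec3(m(i, 0), m(i, 1), m(i, 2));
  return x;
}

// [[Rcpp::export]]
List cpp_energy_forces(List sys, NumericMatrix coords, bool constrained_bonds,
                       bool want_forces) {
  System S;
  S.unpack(sys);
  if (coords.nrow() != S.n) stop("coordinate count does not match topology");
  std::vector<Vec3> x = mat_to_vec(coords);
  std::vector<Vec3> f(S.n);
  Breakdown e = energy_forces(S, x, want_forces ? &f : nullptr,
                              constrained_bonds);
  NumericVector br = NumericVector::create(
      _["bond"] = e.bond, _["angle"] = e.angle, _["dihedral"] = e.dihedral,
      _["contact_intra"] = e.contact_intra,
      _["contact_inter"] = e.contact_inter, _["excluded"] = e.excluded,
      _["electrostatic"] = e.elec, _["restraint"] = e.restraint,
      _["total"] = e.total());
  List out = List::create(_["breakdown"] = br);
  if (want_forces) {
    NumericMatrix fm(S.n, 3);
    for (int i = 0; i < S.n; ++i) {
      fm(i, 0) = f[i].x;
      fm(i, 1) = f[i].y;
      fm(i, 2) = f[i].z;
    }
    out["forces"] = fm;
  }
  return out;
}

// SHAKE: iterative bond-length projection; returns iterations used or -1
static int shake(const System& S, std::vector<Vec3>& x, double tol,
                 int maxit) {
  if (S.b_i.empty()) return 0;
  for (int it = 0; it < maxit; ++it) {
    double maxdev = 0.0;
    for (size_t b = 0; b < S.b_i.size(); ++b) {
      int i = S.b_i[b], j = S.b_j[b];
      Vec3 d = mimg(x[i] - x[j], S.box);
      double r = norm(d);
      double dev = std::fabs(r - S.b_r0[b]) / S.b_r0[b];
      if (dev > maxdev) maxdev = dev;
      if (dev > 0) {
        // move i and j along d proportionally to inverse masses
        double wi = 1.0 / S.mass[i], wj = 1.0 / S.mass[j];
        double g = (r - S.b_r0[b]) / (r * (wi + wj));
        x[i] = x[i] - (g * wi) * d;
        x[j] = x[j] + (g * wj) * d;
      }
    }
    if (maxdev < tol) return it + 1;
  }
  return -1;
}

// [[Rcpp::export]]
List cpp_run_langevin(List sys, NumericMatrix x0, NumericMatrix v0,
                      int n_steps, double dt, double gamma, double temperature,
                      int save_every, int seed, bool use_shake,
                      double shake_tol, int shake_maxit) {
  System S;
  S.unpack(sys);
  int n = S.n;
  if (x0.nrow() != n) stop("coordinate count does not match topology");
  std::vector<Vec3> x = mat_to_vec(x0);   // unwrapped
  std::vector<Vec3> v = mat_to_vec(v0);
  std::mt19937_64 rng(static_cast<uint64_t>(seed));
  std::normal_distribution<double> gauss(0.0, 1.0);

  const double c1 = (gamma > 0) ? std::exp(-gamma * dt) : 1.0;
  const double c2 = (gamma > 0) ? std::sqrt(1.0 - c1 * c1) : 0.0;
  std::vector<double> sig(n);
  for (int i = 0; i < n; ++i)
    sig[i] = std::sqrt(KB * temperature * FCONV / S.mass[i]);

  int n_save = n_steps / save_every;
  NumericVector frames(Dimension(n_save, n, 3));
  NumericVector frames_u(Dimension(n_save, n, 3));
  NumericVector times(n_save), epot(n_save), ekin(n_save);

  std::vector<Vec3> f(n);
  for (auto& fi : f) fi = Vec3();
  Breakdown e = energy_forces(S, x, &f, use_shake);

  for (int step = 1; step <= n_steps; ++step) {
    // B: half kick
    for (int i = 0; i < n; ++i)
      v[i] = v[i] + (0.5 * dt * FCONV / S.mass[i]) * f[i];
    std::vector<Vec3> xprev = x;
    // A: half drift
    for (int i = 0; i < n; ++i) x[i] = x[i] + (0.5 * dt) * v[i];
    // O: Ornstein-Uhlenbeck
    if (gamma > 0) {
      for (int i = 0; i < n; ++i) {
        v[i].x = c1 * v[i].x + c2 * sig[i] * gauss(rng);
        v[i].y = c1 * v[i].y + c2 * sig[i] * gauss(rng);
        v[i].z = c1 * v[i].z + c2 * sig[i] * gauss(rng);
      }
    }
    // A: half drift
    for (int i = 0; i < n; ++i) x[i] = x[i] + (0.5 * dt) * v[i];
    // post-step SHAKE; velocity correction from the constraint displacement
    if (use_shake && !S.b_i.empty()) {
      std::vector<Vec3> xun = x;
      int it = shake(S, x, shake_tol, shake_maxit);
      if (it < 0) stop("SHAKE failed to converge at step %d", step);
      for (int i = 0; i < n; ++i) v[i] = v[i] + (1.0 / dt) * (x[i] - xun[i]);
    }
    for (int i = 0; i < n; ++i) {
      if (!std::isfinite(x[i].x) || !std::isfinite(x[i].y) ||
          !std::isfinite(x[i].z))
        stop("non-finite coordinate at step %d", step);
    }
    // B: half kick with new forces
    for (auto& fi : f) fi = Vec3();
    e = energy_forces(S, x, &f, use_shake);
    for (int i = 0; i < n; ++i)
      v[i] = v[i] + (0.5 * dt * FCONV / S.mass[i]) * f[i];

    if (step % save_every == 0) {
      int k = step / save_every - 1;
      double ke = 0.0;
      for (int i = 0; i < n; ++i) ke += 0.5 * S.mass[i] * dot(v[i], v[i]);
      ke /= FCONV;  // back to kcal/mol
      times[k] = step * dt;
      epot[k] = e.total();
      ekin[k] = ke;
      for (int i = 0; i < n; ++i) {
        double wx = x[i].x, wy = x[i].y, wz = x[i].z;
        if (S.box > 0) {
          wx -= S.box * std::floor(wx / S.box);
          wy -= S.box * std::floor(wy / S.box);
          wz -= S.box * std::floor(wz / S.box);
        }
        frames[k + n_save * i] = wx;
        frames[k + n_save * (i + n)] = wy;
        frames[k + n_save * (i + 2 * n)] = wz;
        frames_u[k + n_save * i] = x[i].x;
        frames_u[k + n_save * (i + n)] = x[i].y;
        frames_u[k + n_save * (i + 2 * n)] = x[i].z;
      }
    }
  }
  NumericMatrix xf(n, 3), vf(n, 3);
  for (int i = 0; i < n; ++i) {
    xf(i, 0) = x[i].x; xf(i, 1) = x[i].y; xf(i, 2) = x[i].z;
    vf(i, 0) = v[i].x; vf(i, 1) = v[i].y; vf(i, 2) = v[i].z;
  }
  return List::create(_["frames"] = frames, _["frames_unwrapped"] = frames_u,
                      _["times"] = times, _["epot"] = epot, _["ekin"] = ekin,
                      _["x_final"] = xf, _["v_final"] = vf);
}

// Gillespie simulation of a continuous-time Markov chain.
// Q: rate matrix (off-diagonal rates, 1/ns); returns jump times and states.
// [[Rcpp::export]]
List cpp_gillespie(NumericMatrix Q, double t_end, int init_state, int seed) {
  int ns = Q.nrow();
  std::mt19937_64 rng(static_cast<uint64_t>(seed));
  std::uniform_real_distribution<double> unif(0.0, 1.0);
  std::vector<double> times;
  std::vector<int> states;
  double t = 0.0;
  int s = init_state;  // 0-based
  times.push_back(0.0);
  states.push_back(s);
  while (t < t_end) {
    double rate = 0.0;
    for (int j = 0; j < ns; ++j)
      if (j != s) rate += Q(s, j);
    if (rate <= 0) break;  // absorbing
    double u1 = unif(rng);
    t += -std::log(u1) / rate;
    if (t >= t_end) break;
    double u2 = unif(rng) * rate;
    double acc = 0.0;
    int nxt = s;
    for (int j = 0; j < ns; ++j) {
      if (j == s) continue;
      acc += Q(s, j);
      if (u2 <= acc) { nxt = j; break; }
    }
    s = nxt;
    times.push_back(t);
    states.push_back(s);
  }
  return List::create(_["times"] = wrap(times), _["states"] = wrap(states));
}
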