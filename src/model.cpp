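// Core force field and Langevin integrator for the two-strand ladder model.
//
// Units: length nm, force pN, energy pN nm, unit bead mass; the time unit tau
// follows from these. All functions take 0-based index arrays (converted at
// the R boundary).

#include <Rcpp.h>
#include <unordered_set>
#include <random>
#include <cmath>
#include <vector>

using namespace Rcpp;

static inline double sq(double x) { return x * x; }

// ---------------------------------------------------------------------------
// Bonded terms: harmonic bonds + Kratky-Porod bending
// ---------------------------------------------------------------------------

static void add_bonds(const NumericMatrix &pos, const IntegerMatrix &bonds,
                      double k, double r0, NumericMatrix &F, double &E) {
  for (int b = 0; b < bonds.nrow(); ++b) {
    int i = bonds(b, 0), j = bonds(b, 1);
    double dx = pos(j, 0) - pos(i, 0);
    double dy = pos(j, 1) - pos(i, 1);
    double dz = pos(j, 2) - pos(i, 2);
    double r = std::sqrt(dx * dx + dy * dy + dz * dz);
    if (r < 1e-12) continue;
    double dr = r - r0;
    E += 0.5 * k * dr * dr;
    double f = k * dr / r; // force magnitude / r
    F(i, 0) += f * dx; F(i, 1) += f * dy; F(i, 2) += f * dz;
    F(j, 0) -= f * dx; F(j, 1) -= f * dy; F(j, 2) -= f * dz;
  }
}

static void add_angles(const NumericMatrix &pos, const IntegerMatrix &angles,
                       const NumericVector &kappa, NumericMatrix &F, double &E) {
  for (int a = 0; a < angles.nrow(); ++a) {
    int i = angles(a, 0), j = angles(a, 1), k = angles(a, 2);
    double b1x = pos(j, 0) - pos(i, 0), b1y = pos(j, 1) - pos(i, 1), b1z = pos(j, 2) - pos(i, 2);
    double b2x = pos(k, 0) - pos(j, 0), b2y = pos(k, 1) - pos(j, 1), b2z = pos(k, 2) - pos(j, 2);
    double n1 = std::sqrt(b1x * b1x + b1y * b1y + b1z * b1z);
    double n2 = std::sqrt(b2x * b2x + b2y * b2y + b2z * b2z);
    if (n1 < 1e-12 || n2 < 1e-12) continue;
    double e1x = b1x / n1, e1y = b1y / n1, e1z = b1z / n1;
    double e2x = b2x / n2, e2y = b2y / n2, e2z = b2z / n2;
    double c = e1x * e2x + e1y * e2y + e1z * e2z;
    double kap = kappa[a];
    E += kap * (1.0 - c);
    // dc/dxi = (c e1 - e2)/n1 ; dc/dxk = (e1 - c e2)/n2 ; F = kappa * dc/dx
    double gix = kap * (c * e1x - e2x) / n1;
    double giy = kap * (c * e1y - e2y) / n1;
    double giz = kap * (c * e1z - e2z) / n1;
    double gkx = kap * (e1x - c * e2x) / n2;
    double gky = kap * (e1y - c * e2y) / n2;
    double gkz = kap * (e1z - c * e2z) / n2;
    F(i, 0) += gix; F(i, 1) += giy; F(i, 2) += giz;
    F(k, 0) += gkx; F(k, 1) += gky; F(k, 2) += gkz;
    F(j, 0) -= gix + gkx; F(j, 1) -= giy + gky; F(j, 2) -= giz + gkz;
  }
}

// [[Rcpp::export]]
List cpp_bonded_forces(NumericMatrix pos, IntegerMatrix bonds, double bond_k,
                       double bond_r0, IntegerMatrix angles, NumericVector kappa) {
  NumericMatrix F(pos.nrow(), 3);
  double E = 0.0;
  add_bonds(pos, bonds, bond_k, bond_r0, F, E);
  add_angles(pos, angles, kappa, F, E);
  return List::create(_["forces"] = F, _["energy"] = E);
}

// ---------------------------------------------------------------------------
// Breakable Morse base pairing
// ---------------------------------------------------------------------------

static void add_pairing(const NumericMatrix &pos, const IntegerVector &pa,
                        const IntegerVector &pb, LogicalVector &state, double D,
                        double r0, double a, double cut, double perp_k,
                        bool reform, NumericMatrix &F, double &E) {
  int np = pa.size();
  for (int p = 0; p < np; ++p) {
    int i = pa[p], j = pb[p];
    double dx = pos(j, 0) - pos(i, 0);
    double dy = pos(j, 1) - pos(i, 1);
    double dz = pos(j, 2) - pos(i, 2);
    double r = std::sqrt(dx * dx + dy * dy + dz * dz);
    if (!state[p]) {
      if (reform && r < r0) state[p] = true; else continue;
    }
    if (r > cut) { state[p] = false; continue; }
    double ex = std::exp(-a * (r - r0));
    E += D * ((1.0 - ex) * (1.0 - ex) - 1.0);
    // dV/dr = 2 D a ex (1 - ex); force on i along +d when dV/dr < 0 (attraction)
    double dV = 2.0 * D * a * ex * (1.0 - ex);
    if (r < 1e-12) continue;
    double f = dV / r;
    F(i, 0) += f * dx; F(i, 1) += f * dy; F(i, 2) += f * dz;
    F(j, 0) -= f * dx; F(j, 1) -= f * dy; F(j, 2) -= f * dz;

    // orientation term: base pairs are lateral, so penalize alignment of the
    // pair vector with the local strand-A tangent; without it a ladder
    // duplex could thread the narrow pore in single file without unzipping
    if (perp_k > 0) {
      int jm = (p > 0) ? pa[p - 1] : pa[p];
      int jp = (p < np - 1) ? pa[p + 1] : pa[p];
      if (jm == jp) continue;
      double wx = pos(jp, 0) - pos(jm, 0);
      double wy = pos(jp, 1) - pos(jm, 1);
      double wz = pos(jp, 2) - pos(jm, 2);
      double nw = std::sqrt(wx * wx + wy * wy + wz * wz);
      if (nw < 1e-12) continue;
      double tx = wx / nw, ty = wy / nw, tz = wz / nw;
      double ux = dx / r, uy = dy / r, uz = dz / r;
      double c = ux * tx + uy * ty + uz * tz;
      E += perp_k * c * c;
      double g = 2.0 * perp_k * c;
      // dc/dB = (t - c u)/r ; dc/dA_p = -(t - c u)/r
      double bx = (tx - c * ux) / r, by = (ty - c * uy) / r, bz = (tz - c * uz) / r;
      // dc/dA_{p+1} = (u - c t)/|w| ; dc/dA_{p-1} = -(u - c t)/|w|
      double qx = (ux - c * tx) / nw, qy = (uy - c * ty) / nw, qz = (uz - c * tz) / nw;
      F(j, 0) -= g * bx; F(j, 1) -= g * by; F(j, 2) -= g * bz;
      F(i, 0) += g * bx; F(i, 1) += g * by; F(i, 2) += g * bz;
      F(jp, 0) -= g * qx; F(jp, 1) -= g * qy; F(jp, 2) -= g * qz;
      F(jm, 0) += g * qx; F(jm, 1) += g * qy; F(jm, 2) += g * qz;
    }
  }
}

// [[Rcpp::export]]
List cpp_pairing_forces(NumericMatrix pos, IntegerVector pa, IntegerVector pb,
                        LogicalVector state, double D, double r0, double a,
                        double cut, double perp_k, bool reform) {
  NumericMatrix F(pos.nrow(), 3);
  LogicalVector st = clone(state);
  double E = 0.0;
  add_pairing(pos, pa, pb, st, D, r0, a, cut, perp_k, reform, F, E);
  return List::create(_["forces"] = F, _["energy"] = E, _["state"] = st);
}

// ---------------------------------------------------------------------------
// Non-bonded: WCA excluded volume + shifted-force Debye-Hueckel repulsion
// ---------------------------------------------------------------------------

struct NB {
  double sigma, eps, wca_cut;
  double pref, lambda, dh_cut;
  double dh_vc, dh_fc; // value and derivative of pref*exp(-r/l)/r at dh_cut
};

static NB make_nb(double sigma, double eps, double pref, double lambda, double dh_cut) {
  NB nb;
  nb.sigma = sigma; nb.eps = eps;
  nb.wca_cut = sigma * std::pow(2.0, 1.0 / 6.0);
  nb.pref = pref; nb.lambda = lambda; nb.dh_cut = dh_cut;
  double g = pref * std::exp(-dh_cut / lambda) / dh_cut;
  nb.dh_vc = g;
  nb.dh_fc = -g * (1.0 / lambda + 1.0 / dh_cut); // g'(rc)
  return nb;
}

// returns dV/dr at separation r (pair energy added to E)
static inline double nb_pair(const NB &nb, double r, double &E) {
  double dV = 0.0;
  if (r < nb.wca_cut) {
    double s6 = std::pow(nb.sigma / r, 6);
    E += 4.0 * nb.eps * (s6 * s6 - s6) + nb.eps;
    dV += 4.0 * nb.eps * (-12.0 * s6 * s6 + 6.0 * s6) / r;
  }
  if (nb.pref > 0 && r < nb.dh_cut) {
    double g = nb.pref * std::exp(-r / nb.lambda) / r;
    E += g - nb.dh_vc - nb.dh_fc * (r - nb.dh_cut);
    dV += -g * (1.0 / nb.lambda + 1.0 / r) - nb.dh_fc;
  }
  return dV;
}

static inline long long pkey(int i, int j, int n) {
  if (i > j) std::swap(i, j);
  return (long long)i * n + j;
}

// [[Rcpp::export]]
List cpp_nonbonded_forces(NumericMatrix pos, IntegerVector excl_i, IntegerVector excl_j,
                          double sigma, double eps, double pref, double lambda,
                          double dh_cut) {
  int n = pos.nrow();
  NB nb = make_nb(sigma, eps, pref, lambda, dh_cut);
  std::unordered_set<long long> excl;
  for (int k = 0; k < excl_i.size(); ++k) excl.insert(pkey(excl_i[k], excl_j[k], n));
  NumericMatrix F(n, 3);
  double E = 0.0;
  double rc = std::max(nb.wca_cut, nb.dh_cut);
  for (int i = 0; i < n; ++i) {
    for (int j = i + 1; j < n; ++j) {
      double dx = pos(j, 0) - pos(i, 0);
      double dy = pos(j, 1) - pos(i, 1);
      double dz = pos(j, 2) - pos(i, 2);
      double r2 = dx * dx + dy * dy + dz * dz;
      if (r2 >= rc * rc) continue;
      if (excl.count(pkey(i, j, n))) continue;
      double r = std::sqrt(r2);
      if (r < 1e-12) continue;
      double dV = nb_pair(nb, r, E);
      double f = dV / r;
      F(i, 0) += f * dx; F(i, 1) += f * dy; F(i, 2) += f * dz;
      F(j, 0) -= f * dx; F(j, 1) -= f * dy; F(j, 2) -= f * dz;
    }
  }
  return List::create(_["forces"] = F, _["energy"] = E);
}

// ---------------------------------------------------------------------------
// Slab + cylindrical pore confinement
// ---------------------------------------------------------------------------

struct PoreGeom {
  double z0, H, R, wc, kw;
};

// force/energy on a single bead; returns energy, adds force
static double pore_bead(const PoreGeom &g, double x, double y, double z,
                        double &fx, double &fy, double &fz) {
  double rho = std::sqrt(x * x + y * y);
  double E = 0.0;
  if (z >= g.z0 && z <= g.z0 + g.H) {
    if (rho >= g.R) {
      // inside slab material: quadratic ramp continued linearly with depth
      double din = rho - g.R;               // radial route to pore interior
      double dfa = std::min(z - g.z0, g.z0 + g.H - z); // route through a face
      double depth = std::min(din, dfa);
      E = 0.5 * g.kw * g.wc * g.wc + g.kw * g.wc * depth;
      double fmag = g.kw * g.wc;
      if (din <= dfa) { // push radially inward
        if (rho > 1e-12) { fx += -fmag * x / rho; fy += -fmag * y / rho; }
      } else if (z - g.z0 <= g.z0 + g.H - z) {
        fz += -fmag;
      } else {
        fz += fmag;
      }
    } else {
      double s = g.R - rho; // distance to pore wall
      if (s < g.wc) {
        E = 0.5 * g.kw * sq(g.wc - s);
        if (rho > 1e-12) { // on-axis: radial direction degenerate, force 0
          double fmag = g.kw * (g.wc - s); // push toward axis
          fx += -fmag * x / rho; fy += -fmag * y / rho;
        }
      }
    }
  } else {
    double dz1 = (z < g.z0) ? (g.z0 - z) : (z - g.z0 - g.H);
    double zsign = (z < g.z0) ? -1.0 : 1.0; // outward normal direction
    if (rho >= g.R) {
      if (dz1 < g.wc) {
        E = 0.5 * g.kw * sq(g.wc - dz1);
        fz += zsign * g.kw * (g.wc - dz1);
      }
    } else {
      // above/below the pore mouth: nearest material point is the rim circle
      double zr = (z < g.z0) ? g.z0 : g.z0 + g.H;
      double dr = g.R - rho;
      double s = std::sqrt(dz1 * dz1 + dr * dr);
      if (s < g.wc && s > 1e-12) {
        E = 0.5 * g.kw * sq(g.wc - s);
        double fmag = g.kw * (g.wc - s);
        // direction away from nearest rim point
        double ux = 0.0, uy = 0.0;
        if (rho > 1e-12) { ux = -dr * x / rho / s; uy = -dr * y / rho / s; }
        double uz = (z - zr) / s;
        fx += fmag * ux; fy += fmag * uy; fz += fmag * uz;
      }
    }
  }
  return E;
}

// [[Rcpp::export]]
List cpp_confinement_forces(NumericMatrix pos, double z0, double H, double R,
                            double wc, double kw) {
  PoreGeom g{z0, H, R, wc, kw};
  NumericMatrix F(pos.nrow(), 3);
  double E = 0.0;
  for (int i = 0; i < pos.nrow(); ++i) {
    double fx = 0, fy = 0, fz = 0;
    E += pore_bead(g, pos(i, 0), pos(i, 1), pos(i, 2), fx, fy, fz);
    F(i, 0) += fx; F(i, 1) += fy; F(i, 2) += fz;
  }
  return List::create(_["forces"] = F, _["energy"] = E);
}

// ---------------------------------------------------------------------------
// Langevin dynamics (BAOAB) with in-pore equal-split driving
// ---------------------------------------------------------------------------

struct SimState {
  int n;
  std::vector<double> x, y, z, vx, vy, vz, fx, fy, fz;
};

struct VerletList {
  std::vector<int> li, lj;
  std::vector<double> x0, y0, z0;
  double rlist, skin;
};

static void build_vlist(VerletList &vl, const SimState &s,
                        const std::unordered_set<long long> &excl) {
  vl.li.clear(); vl.lj.clear();
  double r2 = vl.rlist * vl.rlist;
  for (int i = 0; i < s.n; ++i) {
    for (int j = i + 1; j < s.n; ++j) {
      double dx = s.x[j] - s.x[i], dy = s.y[j] - s.y[i], dz = s.z[j] - s.z[i];
      if (dx * dx + dy * dy + dz * dz < r2 && !excl.count(pkey(i, j, s.n))) {
        vl.li.push_back(i); vl.lj.push_back(j);
      }
    }
  }
  vl.x0.assign(s.x.begin(), s.x.end());
  vl.y0.assign(s.y.begin(), s.y.end());
  vl.z0.assign(s.z.begin(), s.z.end());
}

static bool vlist_stale(const VerletList &vl, const SimState &s) {
  double lim2 = sq(vl.skin * 0.5);
  for (int i = 0; i < s.n; ++i) {
    double dx = s.x[i] - vl.x0[i], dy = s.y[i] - vl.y0[i], dz = s.z[i] - vl.z0[i];
    if (dx * dx + dy * dy + dz * dz > lim2) return true;
  }
  return false;
}

// [[Rcpp::export]]
List cpp_run_langevin(NumericMatrix pos, NumericMatrix vel,
                      IntegerMatrix bonds, IntegerMatrix angles, NumericVector kappa,
                      IntegerVector pa, IntegerVector pb, LogicalVector pair_state,
                      List ff, List pore, List protocol, LogicalVector strandA) {
  int n = pos.nrow();
  SimState s; s.n = n;
  s.x.resize(n); s.y.resize(n); s.z.resize(n);
  s.vx.resize(n); s.vy.resize(n); s.vz.resize(n);
  s.fx.assign(n, 0.0); s.fy.assign(n, 0.0); s.fz.assign(n, 0.0);
  for (int i = 0; i < n; ++i) {
    s.x[i] = pos(i, 0); s.y[i] = pos(i, 1); s.z[i] = pos(i, 2);
    s.vx[i] = vel(i, 0); s.vy[i] = vel(i, 1); s.vz[i] = vel(i, 2);
  }

  double bond_k = ff["bond_k"], bond_r0 = ff["bond_r0"];
  double pair_D = ff["pair_depth"], pair_r0 = ff["pair_r0"], pair_a = ff["pair_a"];
  double pair_cut = ff["pair_break_cutoff"], pair_perp = ff["pair_perp"];
  bool reform = ff["pair_reform"];
  NB nb = make_nb(ff["ev_sigma"], ff["ev_epsilon"], ff["debye_prefactor"],
                  ff["debye_length"], ff["dh_cutoff"]);
  double kT = ff["temperature"], mass = ff["mass"];

  bool pore_on = pore["enabled"];
  PoreGeom g{0, 0, 0, 0, 0};
  if (pore_on) {
    g.z0 = pore["slab_z0"]; g.H = pore["slab_thickness"];
    g.R = as<double>(pore["nominal_diameter"]) / 2.0;
    g.wc = as<double>(pore["steric_range"]) / 2.0 + as<double>(pore["bead_contact"]);
    g.kw = pore["wall_k"];
  }

  int nsteps = protocol["nsteps"];
  double dt = protocol["timestep"], gamma = protocol["gamma"];
  double fdrive = protocol["total_force"];
  int pinned = protocol["pinned"]; // 0-based, -1 = none
  int stride = protocol["snapshot_stride"];
  int stall_window = protocol["stall_window"];
  bool stop_complete = protocol["terminate_on_complete"];
  unsigned int seed = (unsigned int)as<double>(protocol["seed"]);

  std::mt19937_64 rng(seed);
  std::normal_distribution<double> gauss(0.0, 1.0);

  double c1 = std::exp(-gamma * dt);
  double c2 = (kT > 0) ? std::sqrt(kT * (1.0 - c1 * c1) / mass) : 0.0;

  std::unordered_set<long long> excl;
  for (int b = 0; b < bonds.nrow(); ++b) excl.insert(pkey(bonds(b, 0), bonds(b, 1), n));
  for (int p = 0; p < pa.size(); ++p) excl.insert(pkey(pa[p], pb[p], n));
  {
    // 1-3 exclusions: for each bead with two backbone neighbours, exclude
    // the neighbour pair (bonds form simple paths)
    std::vector<int> nb1(n, -1), nb2(n, -1);
    for (int b = 0; b < bonds.nrow(); ++b) {
      int i = bonds(b, 0), j = bonds(b, 1);
      if (nb1[i] < 0) nb1[i] = j; else nb2[i] = j;
      if (nb1[j] < 0) nb1[j] = i; else nb2[j] = i;
    }
    for (int v = 0; v < n; ++v)
      if (nb1[v] >= 0 && nb2[v] >= 0) excl.insert(pkey(nb1[v], nb2[v], n));
  }
  // cross-strand nearest neighbours of the pairing ladder
  for (int p = 0; p + 1 < pa.size(); ++p) {
    excl.insert(pkey(pa[p], pb[p + 1], n));
    excl.insert(pkey(pa[p + 1], pb[p], n));
  }

  VerletList vl;
  vl.skin = 0.3;
  vl.rlist = std::max(nb.wca_cut, nb.dh_cut) + vl.skin;
  build_vlist(vl, s, excl);

  LogicalVector st = clone(pair_state);
  int nA = 0;
  for (int i = 0; i < n; ++i) if (strandA[i]) ++nA;

  // raw copies of the bonded topology for the inner loop
  int nb_cnt = bonds.nrow();
  std::vector<int> b0(nb_cnt), b1(nb_cnt);
  for (int b = 0; b < nb_cnt; ++b) { b0[b] = bonds(b, 0); b1[b] = bonds(b, 1); }
  int na = angles.nrow();
  std::vector<int> a0(na), a1(na), a2(na);
  std::vector<double> akap(na);
  for (int a = 0; a < na; ++a) {
    a0[a] = angles(a, 0); a1[a] = angles(a, 1); a2[a] = angles(a, 2);
    akap[a] = kappa[a];
  }
  int np = pa.size();
  std::vector<int> pia(np), pib(np);
  for (int p = 0; p < np; ++p) { pia[p] = pa[p]; pib[p] = pb[p]; }
  std::vector<char> pst(np);
  for (int p = 0; p < np; ++p) pst[p] = pair_state[p] ? 1 : 0;

  // snapshots
  std::vector<NumericMatrix> frames;
  std::vector<LogicalVector> pair_frames;
  std::vector<double> snap_time, snap_E, snap_fper;
  std::vector<int> snap_step, snap_Q, snap_nin;

  std::string status = "budget";
  int bad_step = -1, bad_bead = -1;

  auto countQ = [&](void) -> int {
    if (!pore_on) return NA_INTEGER;
    int q = 0;
    for (int i = 0; i < n; ++i)
      if (strandA[i] && s.z[i] > g.z0) ++q;
    return q;
  };

  double lastE = 0.0;
  int last_nin = 0; double last_fper = 0.0;

  auto eval_forces = [&](void) {
    double *X = s.x.data(), *Y = s.y.data(), *Z = s.z.data();
    double *FX = s.fx.data(), *FY = s.fy.data(), *FZ = s.fz.data();
    std::fill(s.fx.begin(), s.fx.end(), 0.0);
    std::fill(s.fy.begin(), s.fy.end(), 0.0);
    std::fill(s.fz.begin(), s.fz.end(), 0.0);
    double E = 0.0;
    for (int b = 0; b < nb_cnt; ++b) {
      int i = b0[b], j = b1[b];
      double dx = X[j] - X[i], dy = Y[j] - Y[i], dz = Z[j] - Z[i];
      double r = std::sqrt(dx * dx + dy * dy + dz * dz);
      if (r < 1e-12) continue;
      double dr = r - bond_r0;
      E += 0.5 * bond_k * dr * dr;
      double f = bond_k * dr / r;
      FX[i] += f * dx; FY[i] += f * dy; FZ[i] += f * dz;
      FX[j] -= f * dx; FY[j] -= f * dy; FZ[j] -= f * dz;
    }
    for (int a = 0; a < na; ++a) {
      int i = a0[a], j = a1[a], k = a2[a];
      double b1x = X[j] - X[i], b1y = Y[j] - Y[i], b1z = Z[j] - Z[i];
      double b2x = X[k] - X[j], b2y = Y[k] - Y[j], b2z = Z[k] - Z[j];
      double n1 = std::sqrt(b1x * b1x + b1y * b1y + b1z * b1z);
      double n2 = std::sqrt(b2x * b2x + b2y * b2y + b2z * b2z);
      if (n1 < 1e-12 || n2 < 1e-12) continue;
      double e1x = b1x / n1, e1y = b1y / n1, e1z = b1z / n1;
      double e2x = b2x / n2, e2y = b2y / n2, e2z = b2z / n2;
      double c = e1x * e2x + e1y * e2y + e1z * e2z;
      double kap = akap[a];
      E += kap * (1.0 - c);
      double gix = kap * (c * e1x - e2x) / n1;
      double giy = kap * (c * e1y - e2y) / n1;
      double giz = kap * (c * e1z - e2z) / n1;
      double gkx = kap * (e1x - c * e2x) / n2;
      double gky = kap * (e1y - c * e2y) / n2;
      double gkz = kap * (e1z - c * e2z) / n2;
      FX[i] += gix; FY[i] += giy; FZ[i] += giz;
      FX[k] += gkx; FY[k] += gky; FZ[k] += gkz;
      FX[j] -= gix + gkx; FY[j] -= giy + gky; FZ[j] -= giz + gkz;
    }
    for (int p = 0; p < np; ++p) {
      if (!pst[p]) {
        if (!reform) continue;
      }
      int i = pia[p], j = pib[p];
      double dx = X[j] - X[i], dy = Y[j] - Y[i], dz = Z[j] - Z[i];
      double r = std::sqrt(dx * dx + dy * dy + dz * dz);
      if (!pst[p]) {
        if (r < pair_r0) pst[p] = 1; else continue;
      }
      if (r > pair_cut) { pst[p] = 0; continue; }
      double ex = std::exp(-pair_a * (r - pair_r0));
      E += pair_D * ((1.0 - ex) * (1.0 - ex) - 1.0);
      double dV = 2.0 * pair_D * pair_a * ex * (1.0 - ex);
      if (r < 1e-12) continue;
      double f = dV / r;
      FX[i] += f * dx; FY[i] += f * dy; FZ[i] += f * dz;
      FX[j] -= f * dx; FY[j] -= f * dy; FZ[j] -= f * dz;
      if (pair_perp > 0) {
        int jm = (p > 0) ? pia[p - 1] : pia[p];
        int jp = (p < np - 1) ? pia[p + 1] : pia[p];
        if (jm == jp) continue;
        double wx = X[jp] - X[jm], wy = Y[jp] - Y[jm], wz = Z[jp] - Z[jm];
        double nw = std::sqrt(wx * wx + wy * wy + wz * wz);
        if (nw < 1e-12) continue;
        double tx = wx / nw, ty = wy / nw, tz = wz / nw;
        double ux = dx / r, uy = dy / r, uz = dz / r;
        double c = ux * tx + uy * ty + uz * tz;
        E += pair_perp * c * c;
        double gg = 2.0 * pair_perp * c;
        double bx = (tx - c * ux) / r, by = (ty - c * uy) / r, bz = (tz - c * uz) / r;
        double qx = (ux - c * tx) / nw, qy = (uy - c * ty) / nw, qz = (uz - c * tz) / nw;
        FX[j] -= gg * bx; FY[j] -= gg * by; FZ[j] -= gg * bz;
        FX[i] += gg * bx; FY[i] += gg * by; FZ[i] += gg * bz;
        FX[jp] -= gg * qx; FY[jp] -= gg * qy; FZ[jp] -= gg * qz;
        FX[jm] += gg * qx; FY[jm] += gg * qy; FZ[jm] += gg * qz;
      }
    }
    if (vlist_stale(vl, s)) build_vlist(vl, s, excl);
    double rc = std::max(nb.wca_cut, nb.dh_cut);
    double rc2 = rc * rc;
    for (size_t k = 0; k < vl.li.size(); ++k) {
      int i = vl.li[k], j = vl.lj[k];
      double dx = X[j] - X[i], dy = Y[j] - Y[i], dz = Z[j] - Z[i];
      double r2 = dx * dx + dy * dy + dz * dz;
      if (r2 >= rc2 || r2 < 1e-24) continue;
      double r = std::sqrt(r2);
      double f = nb_pair(nb, r, E) / r;
      FX[i] += f * dx; FY[i] += f * dy; FZ[i] += f * dz;
      FX[j] -= f * dx; FY[j] -= f * dy; FZ[j] -= f * dz;
    }
    last_nin = 0; last_fper = 0.0;
    if (pore_on) {
      for (int i = 0; i < n; ++i) {
        double fx = 0, fy = 0, fz = 0;
        E += pore_bead(g, X[i], Y[i], Z[i], fx, fy, fz);
        FX[i] += fx; FY[i] += fy; FZ[i] += fz;
      }
      if (fdrive > 0) {
        int nin = 0;
        for (int i = 0; i < n; ++i) {
          double rho2 = X[i] * X[i] + Y[i] * Y[i];
          if (Z[i] >= g.z0 && Z[i] <= g.z0 + g.H && rho2 < g.R * g.R) ++nin;
        }
        if (nin > 0) {
          double fper = fdrive / (double)nin;
          for (int i = 0; i < n; ++i) {
            double rho2 = X[i] * X[i] + Y[i] * Y[i];
            if (Z[i] >= g.z0 && Z[i] <= g.z0 + g.H && rho2 < g.R * g.R)
              FZ[i] += fper;
          }
          last_nin = nin; last_fper = fper;
        }
      }
    }
    lastE = E;
  };

  double px = 0, py = 0, pz = 0;
  if (pinned >= 0) { px = s.x[pinned]; py = s.y[pinned]; pz = s.z[pinned]; }

  eval_forces();

  auto snapshot = [&](int step) {
    NumericMatrix fr(n, 3);
    for (int i = 0; i < n; ++i) { fr(i, 0) = s.x[i]; fr(i, 1) = s.y[i]; fr(i, 2) = s.z[i]; }
    frames.push_back(fr);
    LogicalVector stv(np);
    for (int p = 0; p < np; ++p) stv[p] = pst[p] != 0;
    pair_frames.push_back(stv);
    snap_time.push_back(step * dt);
    snap_step.push_back(step);
    snap_Q.push_back(countQ());
    snap_E.push_back(lastE);
    snap_nin.push_back(last_nin);
    snap_fper.push_back(last_fper);
  };

  snapshot(0);

  int maxQ = countQ();
  if (maxQ == NA_INTEGER) maxQ = 0;
  int lastQstep = 0;
  double hdt = 0.5 * dt, hdtm = 0.5 * dt / mass;

  for (int step = 1; step <= nsteps; ++step) {
    for (int i = 0; i < n; ++i) {
      s.vx[i] += hdtm * s.fx[i]; s.vy[i] += hdtm * s.fy[i]; s.vz[i] += hdtm * s.fz[i];
      s.x[i] += hdt * s.vx[i]; s.y[i] += hdt * s.vy[i]; s.z[i] += hdt * s.vz[i];
    }
    if (gamma > 0 || kT > 0) {
      for (int i = 0; i < n; ++i) {
        s.vx[i] = c1 * s.vx[i] + c2 * gauss(rng);
        s.vy[i] = c1 * s.vy[i] + c2 * gauss(rng);
        s.vz[i] = c1 * s.vz[i] + c2 * gauss(rng);
      }
    }
    for (int i = 0; i < n; ++i) {
      s.x[i] += hdt * s.vx[i]; s.y[i] += hdt * s.vy[i]; s.z[i] += hdt * s.vz[i];
    }
    if (pinned >= 0) {
      s.x[pinned] = px; s.y[pinned] = py; s.z[pinned] = pz;
      s.vx[pinned] = 0; s.vy[pinned] = 0; s.vz[pinned] = 0;
    }
    eval_forces();
    for (int i = 0; i < n; ++i) {
      s.vx[i] += hdtm * s.fx[i]; s.vy[i] += hdtm * s.fy[i]; s.vz[i] += hdtm * s.fz[i];
    }
    if (pinned >= 0) { s.vx[pinned] = 0; s.vy[pinned] = 0; s.vz[pinned] = 0; }

    // divergence check
    bool bad = false;
    for (int i = 0; i < n && !bad; ++i) {
      if (!std::isfinite(s.x[i]) || !std::isfinite(s.y[i]) || !std::isfinite(s.z[i])) {
        bad = true; bad_bead = i;
      }
    }
    if (bad) { status = "diverged"; bad_step = step; snapshot(step); break; }

    bool do_snap = (step % stride == 0) || step == nsteps;
    int q = -1;
    if (pore_on && (do_snap || stall_window > 0 || stop_complete)) {
      q = countQ();
      if (q > maxQ) { maxQ = q; lastQstep = step; }
    }
    if (do_snap) snapshot(step);
    if (pore_on && stop_complete && q >= nA) {
      status = "completed";
      if (!do_snap) snapshot(step);
      break;
    }
    if (pore_on && stall_window > 0 && fdrive > 0 && step - lastQstep > stall_window) {
      status = "stalled";
      if (!do_snap) snapshot(step);
      break;
    }
    if (step % 20000 == 0) Rcpp::checkUserInterrupt();
  }

  for (int p = 0; p < np; ++p) st[p] = pst[p] != 0;
  NumericMatrix outp(n, 3), outv(n, 3);
  for (int i = 0; i < n; ++i) {
    outp(i, 0) = s.x[i]; outp(i, 1) = s.y[i]; outp(i, 2) = s.z[i];
    outv(i, 0) = s.vx[i]; outv(i, 1) = s.vy[i]; outv(i, 2) = s.vz[i];
  }
  return List::create(
      _["pos"] = outp, _["vel"] = outv, _["pair_state"] = st,
      _["frames"] = wrap(frames), _["pair_frames"] = wrap(pair_frames),
      _["time"] = wrap(snap_time), _["step"] = wrap(snap_step),
      _["Q"] = wrap(snap_Q), _["energy"] = wrap(snap_E),
      _["n_in_pore"] = wrap(snap_nin), _["force_per_bead"] = wrap(snap_fper),
      _["status"] = status, _["bad_step"] = bad_step, _["bad_bead"] = bad_bead);
}
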