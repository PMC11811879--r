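// Monte Carlo sampler for self-avoiding discrete worm-like chains
// (crankshaft + pivot move set, Metropolis acceptance on the bending energy,
// hard-core rejection for self-avoidance).

#include <Rcpp.h>
#include <random>
#include <vector>
#include <cmath>
#include <unordered_map>

using namespace Rcpp;

struct V3 { double x, y, z; };

static inline V3 sub(const V3 &a, const V3 &b) { return {a.x - b.x, a.y - b.y, a.z - b.z}; }
static inline double dot(const V3 &a, const V3 &b) { return a.x * b.x + a.y * b.y + a.z * b.z; }
static inline double norm(const V3 &a) { return std::sqrt(dot(a, a)); }

// rotate p about axis (through origin, unit u) by angle th
static inline V3 rot(const V3 &p, const V3 &u, double c, double sN) {
  // Rodrigues
  V3 cr{u.y * p.z - u.z * p.y, u.z * p.x - u.x * p.z, u.x * p.y - u.y * p.x};
  double du = dot(u, p);
  return {p.x * c + cr.x * sN + u.x * du * (1 - c),
          p.y * c + cr.y * sN + u.y * du * (1 - c),
          p.z * c + cr.z * sN + u.z * du * (1 - c)};
}

// bending energy contribution of the angle centred at bead j (kappa * (1-cos))
static inline double bend_at(const std::vector<V3> &x, int j, double kap) {
  int n = (int)x.size();
  if (j <= 0 || j >= n - 1) return 0.0;
  V3 b1 = sub(x[j], x[j - 1]), b2 = sub(x[j + 1], x[j]);
  double n1 = norm(b1), n2 = norm(b2);
  if (n1 < 1e-12 || n2 < 1e-12) return 0.0;
  return kap * (1.0 - dot(b1, b2) / (n1 * n2));
}

// [[Rcpp::export]]
List cpp_wlc_mc(int n, double b, double kappa_over_kT, double hard_r, int hard_excl,
                int nsweeps, double seed, int record_every,
                Rcpp::Nullable<Rcpp::NumericMatrix> start) {
  std::mt19937_64 rng((unsigned long long)seed);
  std::uniform_real_distribution<double> U(0.0, 1.0);
  std::normal_distribution<double> G(0.0, 1.0);

  std::vector<V3> x(n);
  if (start.isNotNull()) {
    NumericMatrix s(start);
    for (int i = 0; i < n; ++i) x[i] = {s(i, 0), s(i, 1), s(i, 2)};
  } else {
    for (int i = 0; i < n; ++i) x[i] = {0.0, 0.0, b * i};
  }

  double kap = kappa_over_kT; // energies in kT units
  std::vector<char> moved(n, 0);
  std::vector<double> ree;
  long accept = 0, attempt = 0;

  auto overlap_check = [&](const std::vector<V3> &xs, const std::vector<int> &mv) -> bool {
    // grid over static beads; check each moved bead against nearby static beads
    double cell = std::max(hard_r, 1e-6);
    std::fill(moved.begin(), moved.end(), 0);
    for (int i : mv) moved[i] = 1;
    double inf = std::numeric_limits<double>::infinity();
    double xmin = inf, ymin = inf, zmin = inf;
    for (int i = 0; i < n; ++i) {
      if (moved[i]) continue;
      xmin = std::min(xmin, xs[i].x); ymin = std::min(ymin, xs[i].y); zmin = std::min(zmin, xs[i].z);
    }
    if (!std::isfinite(xmin)) return false;
    // hash grid
    auto key = [&](int cx, int cy, int cz) {
      return ((long long)cx * 73856093LL) ^ ((long long)cy * 19349663LL) ^ ((long long)cz * 83492791LL);
    };
    std::unordered_map<long long, std::vector<int>> bins;
    for (int i = 0; i < n; ++i) {
      if (moved[i]) continue;
      int cx = (int)std::floor(xs[i].x / cell), cy = (int)std::floor(xs[i].y / cell),
          cz = (int)std::floor(xs[i].z / cell);
      bins[key(cx, cy, cz)].push_back(i);
    }
    double r2 = hard_r * hard_r;
    for (int i : mv) {
      int cx = (int)std::floor(xs[i].x / cell), cy = (int)std::floor(xs[i].y / cell),
          cz = (int)std::floor(xs[i].z / cell);
      for (int dx = -1; dx <= 1; ++dx)
        for (int dy = -1; dy <= 1; ++dy)
          for (int dz = -1; dz <= 1; ++dz) {
            auto it = bins.find(key(cx + dx, cy + dy, cz + dz));
            if (it == bins.end()) continue;
            for (int j : it->second) {
              if (std::abs(i - j) < hard_excl) continue;
              V3 d = sub(xs[i], xs[j]);
              if (dot(d, d) < r2) return true;
            }
          }
    }
    return false;
  };

  std::vector<V3> prop;
  for (int sweep = 0; sweep < nsweeps; ++sweep) {
    for (int mv = 0; mv < n; ++mv) {
      ++attempt;
      bool is_pivot = (U(rng) < 0.2);
      prop = x;
      std::vector<int> movedidx;
      double dE = 0.0;
      if (is_pivot) {
        int i = 1 + (int)(U(rng) * (n - 2));
        V3 u{G(rng), G(rng), G(rng)};
        double nu = norm(u);
        if (nu < 1e-12) continue;
        u = {u.x / nu, u.y / nu, u.z / nu};
        double th = (U(rng) * 2.0 - 1.0) * 1.5;
        double c = std::cos(th), sn = std::sin(th);
        double e0 = bend_at(x, i, kap);
        for (int j = i + 1; j < n; ++j) {
          V3 p = sub(x[j], x[i]);
          V3 q = rot(p, u, c, sn);
          prop[j] = {x[i].x + q.x, x[i].y + q.y, x[i].z + q.z};
          movedidx.push_back(j);
        }
        dE = bend_at(prop, i, kap) - e0;
      } else {
        int span = 2 + (int)(U(rng) * 28.0);
        int i = (int)(U(rng) * (n - span - 1));
        int j = i + span;
        if (j >= n) continue;
        V3 ax = sub(x[j], x[i]);
        double na = norm(ax);
        if (na < 1e-9) continue;
        ax = {ax.x / na, ax.y / na, ax.z / na};
        double th = (U(rng) * 2.0 - 1.0) * 2.5;
        double c = std::cos(th), sn = std::sin(th);
        double e0 = bend_at(x, i, kap) + bend_at(x, j, kap);
        for (int kk = i + 1; kk < j; ++kk) {
          V3 p = sub(x[kk], x[i]);
          V3 q = rot(p, ax, c, sn);
          prop[kk] = {x[i].x + q.x, x[i].y + q.y, x[i].z + q.z};
          movedidx.push_back(kk);
        }
        dE = bend_at(prop, i, kap) + bend_at(prop, j, kap) - e0;
      }
      if (dE > 0 && U(rng) > std::exp(-dE)) continue;
      if (overlap_check(prop, movedidx)) continue;
      x.swap(prop);
      ++accept;
    }
    if (record_every > 0 && (sweep % record_every == 0)) {
      V3 d = sub(x[n - 1], x[0]);
      ree.push_back(norm(d));
    }
    if (sweep % 50 == 0) Rcpp::checkUserInterrupt();
  }

  NumericMatrix out(n, 3);
  for (int i = 0; i < n; ++i) { out(i, 0) = x[i].x; out(i, 1) = x[i].y; out(i, 2) = x[i].z; }
  return List::create(_["pos"] = out, _["ree"] = wrap(ree),
                      _["acceptance"] = (double)accept / (double)attempt);
}
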