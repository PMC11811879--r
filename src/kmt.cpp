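// KMT-style topology-preserving polyline simplification: a vertex i is
// removable when the triangle (i-1, i, i+1) is crossed by no other segment of
// the curve. Near-degenerate intersection tests are treated as crossings so
// removal stays conservative.

#include <Rcpp.h>
#include <vector>
#include <cmath>

using namespace Rcpp;

struct P3 { double x, y, z; };

static inline P3 sub(const P3 &a, const P3 &b) { return {a.x - b.x, a.y - b.y, a.z - b.z}; }
static inline P3 cross(const P3 &a, const P3 &b) {
  return {a.y * b.z - a.z * b.y, a.z * b.x - a.x * b.z, a.x * b.y - a.y * b.x};
}
static inline double dot(const P3 &a, const P3 &b) { return a.x * b.x + a.y * b.y + a.z * b.z; }

// does segment (p,q) intersect triangle (a,b,c)? conservative on degeneracy
// 2D point-in-triangle (used for the coplanar case)
static bool pt_in_tri2(double px, double py, double ax, double ay, double bx,
                       double by, double cx, double cy) {
  double d1 = (px - bx) * (ay - by) - (ax - bx) * (py - by);
  double d2 = (px - cx) * (by - cy) - (bx - cx) * (py - cy);
  double d3 = (px - ax) * (cy - ay) - (cx - ax) * (py - ay);
  bool neg = (d1 < 0) || (d2 < 0) || (d3 < 0);
  bool pos = (d1 > 0) || (d2 > 0) || (d3 > 0);
  return !(neg && pos);
}

static bool seg2_intersect(double p1x, double p1y, double p2x, double p2y,
                           double q1x, double q1y, double q2x, double q2y) {
  double d1x = p2x - p1x, d1y = p2y - p1y, d2x = q2x - q1x, d2y = q2y - q1y;
  double den = d1x * d2y - d1y * d2x;
  if (std::fabs(den) < 1e-14) return false;
  double rx = q1x - p1x, ry = q1y - p1y;
  double t = (rx * d2y - ry * d2x) / den;
  double u = (rx * d1y - ry * d1x) / den;
  return t >= 0 && t <= 1 && u >= 0 && u <= 1;
}

static bool seg_tri(const P3 &p, const P3 &q, const P3 &a, const P3 &b, const P3 &c) {
  const double eps = 1e-10;
  P3 ab = sub(b, a), ac = sub(c, a), d = sub(q, p);
  P3 n = cross(ab, ac);
  double area2 = std::sqrt(dot(n, n));
  // degenerate (collinear) triangle: removing its apex is an isotopy along
  // the line, which no transversal segment can obstruct
  if (area2 < eps) return false;
  double denom = dot(n, d);
  double num = dot(n, sub(a, p));
  if (std::fabs(denom) < eps * area2) {
    if (std::fabs(num) > eps * area2) return false; // parallel, off-plane
    // coplanar: test overlap in the triangle plane (project on dominant axis)
    double nx = std::fabs(n.x), ny = std::fabs(n.y), nz = std::fabs(n.z);
    int drop = (nx > ny && nx > nz) ? 0 : (ny > nz ? 1 : 2);
    auto u2 = [drop](const P3 &v, double &x, double &y) {
      if (drop == 0) { x = v.y; y = v.z; }
      else if (drop == 1) { x = v.x; y = v.z; }
      else { x = v.x; y = v.y; }
    };
    double px, py, qx, qy, ax, ay, bx, by, cx, cy;
    u2(p, px, py); u2(q, qx, qy); u2(a, ax, ay); u2(b, bx, by); u2(c, cx, cy);
    if (pt_in_tri2(px, py, ax, ay, bx, by, cx, cy)) return true;
    if (pt_in_tri2(qx, qy, ax, ay, bx, by, cx, cy)) return true;
    return seg2_intersect(px, py, qx, qy, ax, ay, bx, by) ||
           seg2_intersect(px, py, qx, qy, bx, by, cx, cy) ||
           seg2_intersect(px, py, qx, qy, cx, cy, ax, ay);
  }
  double t = num / denom;
  if (t < -eps || t > 1.0 + eps) return false;
  P3 x = {p.x + t * d.x, p.y + t * d.y, p.z + t * d.z};
  // barycentric coordinates of x in (a,b,c)
  P3 v0 = ab, v1 = ac, v2 = sub(x, a);
  double d00 = dot(v0, v0), d01 = dot(v0, v1), d11 = dot(v1, v1);
  double d20 = dot(v2, v0), d21 = dot(v2, v1);
  double den = d00 * d11 - d01 * d01;
  if (std::fabs(den) < eps) return true;
  double v = (d11 * d20 - d01 * d21) / den;
  double w = (d00 * d21 - d01 * d20) / den;
  double u = 1.0 - v - w;
  double tol = 1e-9;
  return (u >= -tol && v >= -tol && w >= -tol);
}

// [[Rcpp::export]]
NumericMatrix cpp_kmt(NumericMatrix pos, bool closed) {
  int n0 = pos.nrow();
  std::vector<P3> x(n0);
  for (int i = 0; i < n0; ++i) x[i] = {pos(i, 0), pos(i, 1), pos(i, 2)};

  int minv = closed ? 3 : 2;
  bool changed = true;
  while (changed && (int)x.size() > minv) {
    changed = false;
    int n = (int)x.size();
    int lo = closed ? 0 : 1;
    int hi = closed ? n - 1 : n - 2;
    for (int i = lo; i <= hi && (int)x.size() > minv; ++i) {
      n = (int)x.size();
      if (i >= n) break;
      int im = (i - 1 + n) % n, ip = (i + 1) % n;
      if (!closed && (i == 0 || i == n - 1)) continue;
      bool blocked = false;
      int nseg = closed ? n : n - 1;
      for (int s = 0; s < nseg && !blocked; ++s) {
        int s2 = (s + 1) % n;
        // skip segments sharing a vertex with the triangle
        if (s == im || s == i || s2 == i || s2 == im || s == ip || s2 == ip) continue;
        if (seg_tri(x[s], x[s2], x[im], x[i], x[ip])) blocked = true;
      }
      if (!blocked) {
        x.erase(x.begin() + i);
        --i;
        changed = true;
      }
    }
  }

  NumericMatrix out((int)x.size(), 3);
  for (size_t i = 0; i < x.size(); ++i) {
    out((int)i, 0) = x[i].x; out((int)i, 1) = x[i].y; out((int)i, 2) = x[i].z;
  }
  return out;
}
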