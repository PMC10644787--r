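// Mesh geometry kernels: closest point on a triangle soup (uniform-grid
// accelerated) and first ray-triangle intersection. Vertices are n x 3,
// faces m x 3 one-based, as stored by the R-side triangle_mesh.

#include <Rcpp.h>
#include <vector>
#include <cmath>
#include <limits>
#include <algorithm>

using namespace Rcpp;

struct Vec3 {
  double x, y, z;
  Vec3(double x_ = 0, double y_ = 0, double z_ = 0) : x(x_), y(y_), z(z_) {}
  Vec3 operator-(const Vec3& o) const { return Vec3(x - o.x, y - o.y, z - o.z); }
  Vec3 operator+(const Vec3& o) const { return Vec3(x + o.x, y + o.y, z + o.z); }
  Vec3 operator*(double s) const { return Vec3(x * s, y * s, z * s); }
};

static inline double dot(const Vec3& a, const Vec3& b) {
  return a.x * b.x + a.y * b.y + a.z * b.z;
}
static inline Vec3 cross(const Vec3& a, const Vec3& b) {
  return Vec3(a.y * b.z - a.z * b.y, a.z * b.x - a.x * b.z, a.x * b.y - a.y * b.x);
}

// Ericson, Real-Time Collision Detection: closest point on triangle abc to p.
static Vec3 closest_point_triangle(const Vec3& p, const Vec3& a, const Vec3& b,
                                   const Vec3& c) {
  Vec3 ab = b - a, ac = c - a, ap = p - a;
  double d1 = dot(ab, ap), d2 = dot(ac, ap);
  if (d1 <= 0.0 && d2 <= 0.0) return a;

  Vec3 bp = p - b;
  double d3 = dot(ab, bp), d4 = dot(ac, bp);
  if (d3 >= 0.0 && d4 <= d3) return b;

  double vc = d1 * d4 - d3 * d2;
  if (vc <= 0.0 && d1 >= 0.0 && d3 <= 0.0) {
    double v = d1 / (d1 - d3);
    return a + ab * v;
  }

  Vec3 cp = p - c;
  double d5 = dot(ab, cp), d6 = dot(ac, cp);
  if (d6 >= 0.0 && d5 <= d6) return c;

  double vb = d5 * d2 - d1 * d6;
  if (vb <= 0.0 && d2 >= 0.0 && d6 <= 0.0) {
    double w = d2 / (d2 - d6);
    return a + ac * w;
  }

  double va = d3 * d6 - d5 * d4;
  if (va <= 0.0 && (d4 - d3) >= 0.0 && (d5 - d6) >= 0.0) {
    double w = (d4 - d3) / ((d4 - d3) + (d5 - d6));
    return b + (c - b) * w;
  }

  double denom = 1.0 / (va + vb + vc);
  double v = vb * denom, w = vc * denom;
  return a + ab * v + ac * w;
}

struct TriGrid {
  std::vector<Vec3> va, vb, vc;       // triangle vertices
  double x0, y0, z0, cell;            // grid origin and cell size
  int nx, ny, nz;
  std::vector<std::vector<int> > cells;

  int cellIndex(int ix, int iy, int iz) const {
    return (iz * ny + iy) * nx + ix;
  }
  int clampi(int v, int lo, int hi) const { return std::max(lo, std::min(hi, v)); }
};

static void build_grid(TriGrid& g, const NumericMatrix& V, const IntegerMatrix& F) {
  int m = F.nrow();
  g.va.resize(m); g.vb.resize(m); g.vc.resize(m);
  double minx = R_PosInf, miny = R_PosInf, minz = R_PosInf;
  double maxx = R_NegInf, maxy = R_NegInf, maxz = R_NegInf;
  for (int i = 0; i < m; ++i) {
    int i1 = F(i, 0) - 1, i2 = F(i, 1) - 1, i3 = F(i, 2) - 1;
    g.va[i] = Vec3(V(i1, 0), V(i1, 1), V(i1, 2));
    g.vb[i] = Vec3(V(i2, 0), V(i2, 1), V(i2, 2));
    g.vc[i] = Vec3(V(i3, 0), V(i3, 1), V(i3, 2));
  }
  int n = V.nrow();
  for (int i = 0; i < n; ++i) {
    minx = std::min(minx, V(i, 0)); maxx = std::max(maxx, V(i, 0));
    miny = std::min(miny, V(i, 1)); maxy = std::max(maxy, V(i, 1));
    minz = std::min(minz, V(i, 2)); maxz = std::max(maxz, V(i, 2));
  }
  double ext = std::max(std::max(maxx - minx, maxy - miny), maxz - minz);
  if (ext <= 0) ext = 1.0;
  // aim for roughly m cells total
  int target = std::max(1, (int)std::floor(std::cbrt((double)m)));
  g.cell = ext / target;
  if (g.cell <= 0) g.cell = 1.0;
  g.x0 = minx; g.y0 = miny; g.z0 = minz;
  g.nx = std::max(1, (int)std::floor((maxx - minx) / g.cell) + 1);
  g.ny = std::max(1, (int)std::floor((maxy - miny) / g.cell) + 1);
  g.nz = std::max(1, (int)std::floor((maxz - minz) / g.cell) + 1);
  g.cells.assign((size_t)g.nx * g.ny * g.nz, std::vector<int>());
  for (int i = 0; i < m; ++i) {
    double txmin = std::min(std::min(g.va[i].x, g.vb[i].x), g.vc[i].x);
    double txmax = std::max(std::max(g.va[i].x, g.vb[i].x), g.vc[i].x);
    double tymin = std::min(std::min(g.va[i].y, g.vb[i].y), g.vc[i].y);
    double tymax = std::max(std::max(g.va[i].y, g.vb[i].y), g.vc[i].y);
    double tzmin = std::min(std::min(g.va[i].z, g.vb[i].z), g.vc[i].z);
    double tzmax = std::max(std::max(g.va[i].z, g.vb[i].z), g.vc[i].z);
    int ix0 = g.clampi((int)((txmin - g.x0) / g.cell), 0, g.nx - 1);
    int ix1 = g.clampi((int)((txmax - g.x0) / g.cell), 0, g.nx - 1);
    int iy0 = g.clampi((int)((tymin - g.y0) / g.cell), 0, g.ny - 1);
    int iy1 = g.clampi((int)((tymax - g.y0) / g.cell), 0, g.ny - 1);
    int iz0 = g.clampi((int)((tzmin - g.z0) / g.cell), 0, g.nz - 1);
    int iz1 = g.clampi((int)((tzmax - g.z0) / g.cell), 0, g.nz - 1);
    for (int iz = iz0; iz <= iz1; ++iz)
      for (int iy = iy0; iy <= iy1; ++iy)
        for (int ix = ix0; ix <= ix1; ++ix)
          g.cells[g.cellIndex(ix, iy, iz)].push_back(i);
  }
}

// Closest point on the mesh for each query point.
// Returns list(points = k x 3, dist = k, face = k one-based face index).
// [[Rcpp::export]]
List cpp_closest_on_mesh(NumericMatrix P, NumericMatrix V, IntegerMatrix F) {
  TriGrid g;
  build_grid(g, V, F);
  int k = P.nrow();
  NumericMatrix out(k, 3);
  NumericVector dist(k);
  IntegerVector face(k);

  for (int q = 0; q < k; ++q) {
    Vec3 p(P(q, 0), P(q, 1), P(q, 2));
    int cx = g.clampi((int)((p.x - g.x0) / g.cell), 0, g.nx - 1);
    int cy = g.clampi((int)((p.y - g.y0) / g.cell), 0, g.ny - 1);
    int cz = g.clampi((int)((p.z - g.z0) / g.cell), 0, g.nz - 1);

    double best = std::numeric_limits<double>::infinity();
    Vec3 bestPt;
    int bestTri = -1;
    int maxRing = std::max(std::max(g.nx, g.ny), g.nz);

    // distance from the query to the boundary of its own cell, used in the
    // ring-termination bound
    double px = p.x - (g.x0 + cx * g.cell);
    double py = p.y - (g.y0 + cy * g.cell);
    double pz = p.z - (g.z0 + cz * g.cell);
    double inset = std::min(std::min(std::min(px, g.cell - px),
                                     std::min(py, g.cell - py)),
                            std::min(pz, g.cell - pz));
    if (inset < 0) inset = 0; // query outside grid bounds

    for (int ring = 0; ring <= maxRing; ++ring) {
      // once a hit is known, stop when the nearest possible point in this
      // ring is farther than the current best
      if (bestTri >= 0) {
        double minPossible = (ring - 1) * g.cell + inset;
        if (ring >= 1 && minPossible > std::sqrt(best)) break;
      }
      bool any = false;
      int ix0 = g.clampi(cx - ring, 0, g.nx - 1), ix1 = g.clampi(cx + ring, 0, g.nx - 1);
      int iy0 = g.clampi(cy - ring, 0, g.ny - 1), iy1 = g.clampi(cy + ring, 0, g.ny - 1);
      int iz0 = g.clampi(cz - ring, 0, g.nz - 1), iz1 = g.clampi(cz + ring, 0, g.nz - 1);
      for (int iz = iz0; iz <= iz1; ++iz) {
        for (int iy = iy0; iy <= iy1; ++iy) {
          for (int ix = ix0; ix <= ix1; ++ix) {
            // only the shell of the ring
            if (ring > 0 &&
                std::abs(ix - cx) != ring && std::abs(iy - cy) != ring &&
                std::abs(iz - cz) != ring) continue;
            const std::vector<int>& lst = g.cells[g.cellIndex(ix, iy, iz)];
            for (size_t t = 0; t < lst.size(); ++t) {
              any = true;
              int i = lst[t];
              Vec3 cpt = closest_point_triangle(p, g.va[i], g.vb[i], g.vc[i]);
              Vec3 d = p - cpt;
              double d2 = dot(d, d);
              if (d2 < best) { best = d2; bestPt = cpt; bestTri = i; }
            }
          }
        }
      }
      (void)any;
    }
    out(q, 0) = bestPt.x; out(q, 1) = bestPt.y; out(q, 2) = bestPt.z;
    dist[q] = std::sqrt(best);
    face[q] = bestTri + 1;
  }
  return List::create(_["points"] = out, _["dist"] = dist, _["face"] = face);
}

// First intersection of rays with the mesh (Moller-Trumbore, brute force).
// origins / dirs are k x 3. Returns list(t, points, face); t = NA on miss.
// [[Rcpp::export]]
List cpp_ray_mesh(NumericMatrix origins, NumericMatrix dirs,
                  NumericMatrix V, IntegerMatrix F, double tmin) {
  int k = origins.nrow();
  int m = F.nrow();
  NumericVector tv(k, NA_REAL);
  NumericMatrix pts(k, 3);
  IntegerVector face(k, NA_INTEGER);
  const double eps = 1e-12;

  for (int q = 0; q < k; ++q) {
    Vec3 o(origins(q, 0), origins(q, 1), origins(q, 2));
    Vec3 d(dirs(q, 0), dirs(q, 1), dirs(q, 2));
    double bestT = std::numeric_limits<double>::infinity();
    int bestF = -1;
    for (int i = 0; i < m; ++i) {
      int i1 = F(i, 0) - 1, i2 = F(i, 1) - 1, i3 = F(i, 2) - 1;
      Vec3 a(V(i1, 0), V(i1, 1), V(i1, 2));
      Vec3 b(V(i2, 0), V(i2, 1), V(i2, 2));
      Vec3 c(V(i3, 0), V(i3, 1), V(i3, 2));
      Vec3 e1 = b - a, e2 = c - a;
      Vec3 pv = cross(d, e2);
      double det = dot(e1, pv);
      if (std::fabs(det) < eps) continue;
      double invDet = 1.0 / det;
      Vec3 tvec = o - a;
      double u = dot(tvec, pv) * invDet;
      if (u < -1e-9 || u > 1 + 1e-9) continue;
      Vec3 qv = cross(tvec, e1);
      double v = dot(d, qv) * invDet;
      if (v < -1e-9 || u + v > 1 + 1e-9) continue;
      double t = dot(e2, qv) * invDet;
      if (t > tmin && t < bestT) { bestT = t; bestF = i; }
    }
    if (bestF >= 0) {
      tv[q] = bestT;
      pts(q, 0) = o.x + d.x * bestT;
      pts(q, 1) = o.y + d.y * bestT;
      pts(q, 2) = o.z + d.z * bestT;
      face[q] = bestF + 1;
    }
  }
  return List::create(_["t"] = tv, _["points"] = pts, _["face"] = face);
}
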