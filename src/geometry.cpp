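// Mesh geometry kernel: signed-distance grids, marching-tetrahedra surface
// extraction, BSP Booleans, point-mesh distance queries.  All coordinates in
// millimetres.  Faces arrive 1-based from R and are converted on entry.

#include <Rcpp.h>
#include <vector>
#include <array>
#include <cmath>
#include <cstdint>
#include <algorithm>
#include <unordered_map>

using namespace Rcpp;

typedef std::array<double, 3> Vec3;

static inline Vec3 vsub(const Vec3 &a, const Vec3 &b) {
  return {a[0] - b[0], a[1] - b[1], a[2] - b[2]};
}
static inline Vec3 vadd(const Vec3 &a, const Vec3 &b) {
  return {a[0] + b[0], a[1] + b[1], a[2] + b[2]};
}
static inline Vec3 vscale(const Vec3 &a, double s) {
  return {a[0] * s, a[1] * s, a[2] * s};
}
static inline double vdot(const Vec3 &a, const Vec3 &b) {
  return a[0] * b[0] + a[1] * b[1] + a[2] * b[2];
}
static inline Vec3 vcross(const Vec3 &a, const Vec3 &b) {
  return {a[1] * b[2] - a[2] * b[1], a[2] * b[0] - a[0] * b[2],
          a[0] * b[1] - a[1] * b[0]};
}
static inline double vnorm(const Vec3 &a) { return std::sqrt(vdot(a, a)); }

// Closest point on triangle (Ericson, Real-Time Collision Detection).
static Vec3 closest_point_triangle(const Vec3 &p, const Vec3 &a, const Vec3 &b,
                                   const Vec3 &c) {
  Vec3 ab = vsub(b, a), ac = vsub(c, a), ap = vsub(p, a);
  double d1 = vdot(ab, ap), d2 = vdot(ac, ap);
  if (d1 <= 0.0 && d2 <= 0.0) return a;
  Vec3 bp = vsub(p, b);
  double d3 = vdot(ab, bp), d4 = vdot(ac, bp);
  if (d3 >= 0.0 && d4 <= d3) return b;
  double vc = d1 * d4 - d3 * d2;
  if (vc <= 0.0 && d1 >= 0.0 && d3 <= 0.0) {
    double v = d1 / (d1 - d3);
    return vadd(a, vscale(ab, v));
  }
  Vec3 cp = vsub(p, c);
  double d5 = vdot(ab, cp), d6 = vdot(ac, cp);
  if (d6 >= 0.0 && d5 <= d6) return c;
  double vb = d5 * d2 - d1 * d6;
  if (vb <= 0.0 && d2 >= 0.0 && d6 <= 0.0) {
    double w = d2 / (d2 - d6);
    return vadd(a, vscale(ac, w));
  }
  double va = d3 * d6 - d5 * d4;
  if (va <= 0.0 && (d4 - d3) >= 0.0 && (d5 - d6) >= 0.0) {
    double w = (d4 - d3) / ((d4 - d3) + (d5 - d6));
    return vadd(b, vscale(vsub(c, b), w));
  }
  double denom = 1.0 / (va + vb + vc);
  double v = vb * denom, w = vc * denom;
  return vadd(a, vadd(vscale(ab, v), vscale(ac, w)));
}

struct MeshRef {
  std::vector<Vec3> v;
  std::vector<std::array<int, 3>> f;
};

static MeshRef make_mesh(const NumericMatrix &V, const IntegerMatrix &F) {
  MeshRef m;
  m.v.resize(V.nrow());
  for (int i = 0; i < V.nrow(); ++i) m.v[i] = {V(i, 0), V(i, 1), V(i, 2)};
  m.f.resize(F.nrow());
  for (int i = 0; i < F.nrow(); ++i)
    m.f[i] = {F(i, 0) - 1, F(i, 1) - 1, F(i, 2) - 1};
  return m;
}

// ---------------------------------------------------------------------------
// z-column ray parity: for each (x, y) column collect the z values where a
// vertical line crosses the mesh.  Robustness: columns hitting a vertex or
// edge exactly are retried with a tiny planar jitter.
// ---------------------------------------------------------------------------

struct ColumnGrid {
  // triangle indices binned over a 2D (x, y) grid
  double x0, y0, cell;
  int nx, ny;
  std::vector<std::vector<int>> bins;
};

static ColumnGrid build_column_grid(const MeshRef &m, int target_bins = 128) {
  ColumnGrid g;
  double xmin = 1e300, xmax = -1e300, ymin = 1e300, ymax = -1e300;
  for (const auto &p : m.v) {
    xmin = std::min(xmin, p[0]); xmax = std::max(xmax, p[0]);
    ymin = std::min(ymin, p[1]); ymax = std::max(ymax, p[1]);
  }
  double span = std::max(xmax - xmin, ymax - ymin);
  if (span <= 0) span = 1.0;
  g.cell = span / target_bins;
  g.x0 = xmin - g.cell; g.y0 = ymin - g.cell;
  g.nx = (int)((xmax - g.x0) / g.cell) + 2;
  g.ny = (int)((ymax - g.y0) / g.cell) + 2;
  g.bins.resize((size_t)g.nx * g.ny);
  for (size_t t = 0; t < m.f.size(); ++t) {
    double txmin = 1e300, txmax = -1e300, tymin = 1e300, tymax = -1e300;
    for (int k = 0; k < 3; ++k) {
      const Vec3 &p = m.v[m.f[t][k]];
      txmin = std::min(txmin, p[0]); txmax = std::max(txmax, p[0]);
      tymin = std::min(tymin, p[1]); tymax = std::max(tymax, p[1]);
    }
    int i0 = std::max(0, (int)((txmin - g.x0) / g.cell));
    int i1 = std::min(g.nx - 1, (int)((txmax - g.x0) / g.cell));
    int j0 = std::max(0, (int)((tymin - g.y0) / g.cell));
    int j1 = std::min(g.ny - 1, (int)((tymax - g.y0) / g.cell));
    for (int j = j0; j <= j1; ++j)
      for (int i = i0; i <= i1; ++i)
        g.bins[(size_t)j * g.nx + i].push_back((int)t);
  }
  return g;
}

// Returns true on success; hits sorted ascending.  Fails (returns false) when
// the column grazes an edge/vertex and needs a jitter retry.
static bool column_hits(const MeshRef &m, const ColumnGrid &g, double x,
                        double y, std::vector<double> &hits) {
  hits.clear();
  int i = (int)((x - g.x0) / g.cell), j = (int)((y - g.y0) / g.cell);
  if (i < 0 || j < 0 || i >= g.nx || j >= g.ny) return true;
  const std::vector<int> &cand = g.bins[(size_t)j * g.nx + i];
  for (int t : cand) {
    const Vec3 &a = m.v[m.f[t][0]], &b = m.v[m.f[t][1]], &c = m.v[m.f[t][2]];
    double d0 = (b[0] - a[0]) * (y - a[1]) - (b[1] - a[1]) * (x - a[0]);
    double d1 = (c[0] - b[0]) * (y - b[1]) - (c[1] - b[1]) * (x - b[0]);
    double d2 = (a[0] - c[0]) * (y - c[1]) - (a[1] - c[1]) * (x - c[0]);
    double area2 = (b[0] - a[0]) * (c[1] - a[1]) - (b[1] - a[1]) * (c[0] - a[0]);
    double scale = std::abs(d0) + std::abs(d1) + std::abs(d2);
    double eps = 1e-12 * (scale + std::abs(area2) + 1e-30);
    bool pos = d0 > eps && d1 > eps && d2 > eps;
    bool neg = d0 < -eps && d1 < -eps && d2 < -eps;
    if (!pos && !neg) {
      // on or extremely near an edge: ambiguous -> request jitter unless
      // clearly outside
      bool clearly_out = (d0 > eps || d1 > eps || d2 > eps) &&
                         (d0 < -eps || d1 < -eps || d2 < -eps);
      if (clearly_out) continue;
      return false;
    }
    if (std::abs(area2) < 1e-14) return false;  // degenerate in projection
    double w0 = d1 / area2, w1 = d2 / area2, w2 = d0 / area2;
    double z = w0 * a[2] + w1 * b[2] + w2 * c[2];
    hits.push_back(z);
  }
  std::sort(hits.begin(), hits.end());
  return true;
}

static bool column_hits_jittered(const MeshRef &m, const ColumnGrid &g,
                                 double x, double y, double jit,
                                 std::vector<double> &hits) {
  for (int attempt = 0; attempt < 6; ++attempt) {
    double dx = attempt == 0 ? 0.0 : jit * attempt * 0.6180339887;
    double dy = attempt == 0 ? 0.0 : jit * attempt * 0.4142135624;
    if (column_hits(m, g, x + dx, y + dy, hits) &&
        hits.size() % 2 == 0)
      return true;
  }
  return false;
}

// ---------------------------------------------------------------------------
// Signed distance sampled on a regular grid.
// ---------------------------------------------------------------------------

// [[Rcpp::export]]
NumericVector cpp_sdf_grid(NumericMatrix V, IntegerMatrix F,
                           NumericVector origin, double pitch,
                           IntegerVector dims, int band = 2) {
  MeshRef m = make_mesh(V, F);
  int nx = dims[0], ny = dims[1], nz = dims[2];
  double ox = origin[0], oy = origin[1], oz = origin[2];
  size_t n = (size_t)nx * ny * nz;
  double far = (band + 0.5) * pitch;
  NumericVector field(n);

  // 1) sign by z-column parity
  ColumnGrid cg = build_column_grid(m);
  std::vector<double> hits;
  std::vector<signed char> inside(n, 0);
  for (int j = 0; j < ny; ++j) {
    for (int i = 0; i < nx; ++i) {
      double x = ox + i * pitch, y = oy + j * pitch;
      bool ok = column_hits_jittered(m, cg, x, y, pitch * 1e-4, hits);
      if (!ok) hits.clear();  // give up: column counts as fully outside
      size_t h = 0;
      for (int k = 0; k < nz; ++k) {
        double z = oz + k * pitch;
        while (h < hits.size() && hits[h] < z) ++h;
        if (h & 1) inside[(size_t)k * nx * ny + (size_t)j * nx + i] = 1;
      }
    }
  }
  for (size_t idx = 0; idx < n; ++idx) field[idx] = inside[idx] ? -far : far;

  // 2) exact unsigned distance within `band` cells of each triangle
  for (size_t t = 0; t < m.f.size(); ++t) {
    const Vec3 &a = m.v[m.f[t][0]], &b = m.v[m.f[t][1]], &c = m.v[m.f[t][2]];
    double bxmin = std::min({a[0], b[0], c[0]}) - band * pitch;
    double bxmax = std::max({a[0], b[0], c[0]}) + band * pitch;
    double bymin = std::min({a[1], b[1], c[1]}) - band * pitch;
    double bymax = std::max({a[1], b[1], c[1]}) + band * pitch;
    double bzmin = std::min({a[2], b[2], c[2]}) - band * pitch;
    double bzmax = std::max({a[2], b[2], c[2]}) + band * pitch;
    int i0 = std::max(0, (int)std::ceil((bxmin - ox) / pitch));
    int i1 = std::min(nx - 1, (int)std::floor((bxmax - ox) / pitch));
    int j0 = std::max(0, (int)std::ceil((bymin - oy) / pitch));
    int j1 = std::min(ny - 1, (int)std::floor((bymax - oy) / pitch));
    int k0 = std::max(0, (int)std::ceil((bzmin - oz) / pitch));
    int k1 = std::min(nz - 1, (int)std::floor((bzmax - oz) / pitch));
    for (int k = k0; k <= k1; ++k)
      for (int j = j0; j <= j1; ++j)
        for (int i = i0; i <= i1; ++i) {
          Vec3 p = {ox + i * pitch, oy + j * pitch, oz + k * pitch};
          Vec3 q = closest_point_triangle(p, a, b, c);
          double d = vnorm(vsub(p, q));
          size_t idx = (size_t)k * nx * ny + (size_t)j * nx + i;
          double cur = std::abs(field[idx]);
          if (d < cur) field[idx] = inside[idx] ? -d : d;
        }
  }
  return field;
}

// ---------------------------------------------------------------------------
// Marching tetrahedra on a regular grid (Freudenthal 6-tet decomposition).
// Inside = field < 0.  Output triangles wind outward (toward positive field).
// ---------------------------------------------------------------------------

// [[Rcpp::export]]
List cpp_marching_tetra(NumericVector field, NumericVector origin,
                        double pitch, IntegerVector dims) {
  int nx = dims[0], ny = dims[1], nz = dims[2];
  double ox = origin[0], oy = origin[1], oz = origin[2];
  size_t nxy = (size_t)nx * ny;
  // avoid exact zeros (would generate degenerate cuts)
  std::vector<double> f(field.begin(), field.end());
  for (auto &v : f) if (std::abs(v) < 1e-12) v = 1e-12;

  auto node = [&](int i, int j, int k) -> size_t {
    return (size_t)k * nxy + (size_t)j * nx + i;
  };
  auto npos = [&](size_t id) -> Vec3 {
    int k = (int)(id / nxy);
    int rem = (int)(id % nxy);
    int j = rem / nx, i = rem % nx;
    return {ox + i * pitch, oy + j * pitch, oz + k * pitch};
  };

  std::unordered_map<uint64_t, int> edge_vert;
  std::vector<Vec3> verts;
  std::vector<std::array<int, 3>> tris;

  auto cut = [&](size_t a, size_t b) -> int {
    size_t lo = std::min(a, b), hi = std::max(a, b);
    uint64_t key = (uint64_t)lo * (uint64_t)(nxy * nz) + (uint64_t)hi;
    auto it = edge_vert.find(key);
    if (it != edge_vert.end()) return it->second;
    double fa = f[a], fb = f[b];
    double t = fa / (fa - fb);
    if (t < 1e-9) t = 1e-9;
    if (t > 1.0 - 1e-9) t = 1.0 - 1e-9;
    // parameter defined from lo to hi for consistency
    if (lo != a) t = 1.0 - t, std::swap(fa, fb);
    Vec3 pa = npos(lo), pb = npos(hi);
    Vec3 p = vadd(pa, vscale(vsub(pb, pa), t));
    int id = (int)verts.size();
    verts.push_back(p);
    edge_vert[key] = id;
    return id;
  };

  auto emit = [&](int v0, int v1, int v2, const Vec3 &ref) {
    // orient so the normal points along ref (inside -> outside)
    Vec3 n = vcross(vsub(verts[v1], verts[v0]), vsub(verts[v2], verts[v0]));
    if (vdot(n, ref) >= 0)
      tris.push_back({v0, v1, v2});
    else
      tris.push_back({v0, v2, v1});
  };

  static const int TETS[6][4] = {{0, 1, 3, 7}, {0, 3, 2, 7}, {0, 2, 6, 7},
                                 {0, 6, 4, 7}, {0, 4, 5, 7}, {0, 5, 1, 7}};

  for (int k = 0; k + 1 < nz; ++k) {
    for (int j = 0; j + 1 < ny; ++j) {
      for (int i = 0; i + 1 < nx; ++i) {
        size_t c[8] = {node(i, j, k),         node(i + 1, j, k),
                       node(i, j + 1, k),     node(i + 1, j + 1, k),
                       node(i, j, k + 1),     node(i + 1, j, k + 1),
                       node(i, j + 1, k + 1), node(i + 1, j + 1, k + 1)};
        bool any_in = false, any_out = false;
        for (int q = 0; q < 8; ++q) (f[c[q]] < 0 ? any_in : any_out) = true;
        if (!any_in || !any_out) continue;
        for (int tt = 0; tt < 6; ++tt) {
          size_t nidx[4];
          double fv[4];
          int ins[4], outs[4], ni = 0, no = 0;
          for (int q = 0; q < 4; ++q) {
            nidx[q] = c[TETS[tt][q]];
            fv[q] = f[nidx[q]];
            if (fv[q] < 0) ins[ni++] = q; else outs[no++] = q;
          }
          if (ni == 0 || ni == 4) continue;
          Vec3 cin = {0, 0, 0}, cout = {0, 0, 0};
          for (int q = 0; q < ni; ++q) cin = vadd(cin, npos(nidx[ins[q]]));
          for (int q = 0; q < no; ++q) cout = vadd(cout, npos(nidx[outs[q]]));
          cin = vscale(cin, 1.0 / ni);
          cout = vscale(cout, 1.0 / no);
          Vec3 ref = vsub(cout, cin);
          if (ni == 1) {
            int a = cut(nidx[ins[0]], nidx[outs[0]]);
            int b = cut(nidx[ins[0]], nidx[outs[1]]);
            int d = cut(nidx[ins[0]], nidx[outs[2]]);
            emit(a, b, d, ref);
          } else if (ni == 3) {
            int a = cut(nidx[ins[0]], nidx[outs[0]]);
            int b = cut(nidx[ins[1]], nidx[outs[0]]);
            int d = cut(nidx[ins[2]], nidx[outs[0]]);
            emit(a, b, d, ref);
          } else {  // ni == 2
            int q0 = cut(nidx[ins[0]], nidx[outs[0]]);
            int q1 = cut(nidx[ins[0]], nidx[outs[1]]);
            int q2 = cut(nidx[ins[1]], nidx[outs[1]]);
            int q3 = cut(nidx[ins[1]], nidx[outs[0]]);
            emit(q0, q1, q2, ref);
            emit(q0, q2, q3, ref);
          }
        }
      }
    }
  }

  NumericMatrix Vout(verts.size(), 3);
  for (size_t i = 0; i < verts.size(); ++i)
    for (int d = 0; d < 3; ++d) Vout(i, d) = verts[i][d];
  IntegerMatrix Fout(tris.size(), 3);
  for (size_t i = 0; i < tris.size(); ++i)
    for (int d = 0; d < 3; ++d) Fout(i, d) = tris[i][d] + 1;
  return List::create(_["vertices"] = Vout, _["faces"] = Fout);
}

// ---------------------------------------------------------------------------
// Point queries: inside tests and unsigned distances (uniform-grid search).
// ---------------------------------------------------------------------------

// [[Rcpp::export]]
LogicalVector cpp_points_in_mesh(NumericMatrix P, NumericMatrix V,
                                 IntegerMatrix F) {
  MeshRef m = make_mesh(V, F);
  ColumnGrid cg = build_column_grid(m);
  LogicalVector out(P.nrow());
  std::vector<double> hits;
  for (int q = 0; q < P.nrow(); ++q) {
    bool ok = column_hits_jittered(m, cg, P(q, 0), P(q, 1), 1e-6, hits);
    if (!ok) { out[q] = false; continue; }
    size_t below = 0;
    for (double z : hits) if (z < P(q, 2)) ++below;
    out[q] = (below & 1) != 0;
  }
  return out;
}

struct TriGrid3 {
  Vec3 lo;
  double cell;
  int nx, ny, nz;
  std::vector<std::vector<int>> bins;
};

static TriGrid3 build_trigrid(const MeshRef &m, int target = 48) {
  TriGrid3 g;
  Vec3 lo = {1e300, 1e300, 1e300}, hi = {-1e300, -1e300, -1e300};
  for (const auto &p : m.v)
    for (int d = 0; d < 3; ++d) {
      lo[d] = std::min(lo[d], p[d]);
      hi[d] = std::max(hi[d], p[d]);
    }
  double span = std::max({hi[0] - lo[0], hi[1] - lo[1], hi[2] - lo[2], 1e-9});
  g.cell = span / target;
  for (int d = 0; d < 3; ++d) lo[d] -= g.cell;
  g.lo = lo;
  g.nx = (int)((hi[0] - lo[0]) / g.cell) + 2;
  g.ny = (int)((hi[1] - lo[1]) / g.cell) + 2;
  g.nz = (int)((hi[2] - lo[2]) / g.cell) + 2;
  g.bins.resize((size_t)g.nx * g.ny * g.nz);
  for (size_t t = 0; t < m.f.size(); ++t) {
    Vec3 tlo = {1e300, 1e300, 1e300}, thi = {-1e300, -1e300, -1e300};
    for (int k = 0; k < 3; ++k) {
      const Vec3 &p = m.v[m.f[t][k]];
      for (int d = 0; d < 3; ++d) {
        tlo[d] = std::min(tlo[d], p[d]);
        thi[d] = std::max(thi[d], p[d]);
      }
    }
    int i0 = std::max(0, (int)((tlo[0] - g.lo[0]) / g.cell));
    int i1 = std::min(g.nx - 1, (int)((thi[0] - g.lo[0]) / g.cell));
    int j0 = std::max(0, (int)((tlo[1] - g.lo[1]) / g.cell));
    int j1 = std::min(g.ny - 1, (int)((thi[1] - g.lo[1]) / g.cell));
    int k0 = std::max(0, (int)((tlo[2] - g.lo[2]) / g.cell));
    int k1 = std::min(g.nz - 1, (int)((thi[2] - g.lo[2]) / g.cell));
    for (int k = k0; k <= k1; ++k)
      for (int j = j0; j <= j1; ++j)
        for (int i = i0; i <= i1; ++i)
          g.bins[((size_t)k * g.ny + j) * g.nx + i].push_back((int)t);
  }
  return g;
}

// [[Rcpp::export]]
NumericVector cpp_point_mesh_distance(NumericMatrix P, NumericMatrix V,
                                      IntegerMatrix F) {
  MeshRef m = make_mesh(V, F);
  TriGrid3 g = build_trigrid(m);
  NumericVector out(P.nrow());
  for (int q = 0; q < P.nrow(); ++q) {
    Vec3 p = {P(q, 0), P(q, 1), P(q, 2)};
    int ci = (int)((p[0] - g.lo[0]) / g.cell);
    int cj = (int)((p[1] - g.lo[1]) / g.cell);
    int ck = (int)((p[2] - g.lo[2]) / g.cell);
    double best = 1e300;
    int maxr = std::max({g.nx, g.ny, g.nz});
    for (int r = 0; r <= maxr; ++r) {
      // once a hit is found, search one extra ring then stop
      if (best < 1e299 && (r - 1) * g.cell > best) break;
      bool any_cell = false;
      for (int k = ck - r; k <= ck + r; ++k) {
        if (k < 0 || k >= g.nz) continue;
        for (int j = cj - r; j <= cj + r; ++j) {
          if (j < 0 || j >= g.ny) continue;
          for (int i = ci - r; i <= ci + r; ++i) {
            if (i < 0 || i >= g.nx) continue;
            if (std::max({std::abs(i - ci), std::abs(j - cj),
                          std::abs(k - ck)}) != r)
              continue;
            any_cell = true;
            for (int t : g.bins[((size_t)k * g.ny + j) * g.nx + i]) {
              Vec3 c = closest_point_triangle(p, m.v[m.f[t][0]],
                                              m.v[m.f[t][1]], m.v[m.f[t][2]]);
              best = std::min(best, vnorm(vsub(p, c)));
            }
          }
        }
      }
      if (!any_cell && r > 0 && (ci + r < 0 || ci - r >= g.nx) &&
          (cj + r < 0 || cj - r >= g.ny) && (ck + r < 0 || ck - r >= g.nz))
        break;
    }
    out[q] = best;
  }
  return out;
}

// ---------------------------------------------------------------------------
// BSP CSG (plane-splitting Boolean) for modest watertight inputs.
// ---------------------------------------------------------------------------

namespace csg {

const double EPS = 1e-8;

struct Plane {
  Vec3 n;
  double w;
};

struct Polygon {
  std::vector<Vec3> v;
  Plane plane;
};

static bool make_plane(const std::vector<Vec3> &v, Plane &pl) {
  Vec3 n = vcross(vsub(v[1], v[0]), vsub(v[2], v[0]));
  double len = vnorm(n);
  if (len < 1e-14) return false;
  pl.n = vscale(n, 1.0 / len);
  pl.w = vdot(pl.n, v[0]);
  return true;
}

static void flip(Polygon &p) {
  std::reverse(p.v.begin(), p.v.end());
  p.plane.n = vscale(p.plane.n, -1.0);
  p.plane.w = -p.plane.w;
}

enum { COPLANAR = 0, FRONT = 1, BACK = 2, SPANNING = 3 };

static void split_polygon(const Plane &pl, const Polygon &poly,
                          std::vector<Polygon> &cofront,
                          std::vector<Polygon> &coback,
                          std::vector<Polygon> &front,
                          std::vector<Polygon> &back) {
  int ptype = 0;
  std::vector<int> types(poly.v.size());
  for (size_t i = 0; i < poly.v.size(); ++i) {
    double t = vdot(pl.n, poly.v[i]) - pl.w;
    int ty = (t < -EPS) ? BACK : (t > EPS) ? FRONT : COPLANAR;
    ptype |= ty;
    types[i] = ty;
  }
  switch (ptype) {
    case COPLANAR:
      (vdot(pl.n, poly.plane.n) > 0 ? cofront : coback).push_back(poly);
      break;
    case FRONT: front.push_back(poly); break;
    case BACK: back.push_back(poly); break;
    case SPANNING: {
      std::vector<Vec3> f, b;
      size_t n = poly.v.size();
      for (size_t i = 0; i < n; ++i) {
        size_t j = (i + 1) % n;
        int ti = types[i], tj = types[j];
        const Vec3 &vi = poly.v[i], &vj = poly.v[j];
        if (ti != BACK) f.push_back(vi);
        if (ti != FRONT) b.push_back(vi);
        if ((ti | tj) == SPANNING) {
          double t = (pl.w - vdot(pl.n, vi)) / vdot(pl.n, vsub(vj, vi));
          Vec3 v = vadd(vi, vscale(vsub(vj, vi), t));
          f.push_back(v);
          b.push_back(v);
        }
      }
      if (f.size() >= 3) {
        Polygon pf;
        pf.v = f;
        pf.plane = poly.plane;
        front.push_back(pf);
      }
      if (b.size() >= 3) {
        Polygon pb;
        pb.v = b;
        pb.plane = poly.plane;
        back.push_back(pb);
      }
      break;
    }
  }
}

struct Node {
  bool has_plane = false;
  Plane plane;
  Node *front = nullptr, *back = nullptr;
  std::vector<Polygon> polygons;
  ~Node() { delete front; delete back; }

  void invert() {
    for (auto &p : polygons) csg::flip(p);
    if (has_plane) {
      plane.n = vscale(plane.n, -1.0);
      plane.w = -plane.w;
    }
    if (front) front->invert();
    if (back) back->invert();
    std::swap(front, back);
  }

  std::vector<Polygon> clip_polygons(const std::vector<Polygon> &polys) const {
    if (!has_plane) return polys;
    std::vector<Polygon> f, b;
    for (const auto &p : polys) {
      std::vector<Polygon> cf, cb;
      split_polygon(plane, p, cf, cb, f, b);
      // coplanar-front stays, coplanar-back is clipped with back subtree
      for (auto &q : cf) f.push_back(q);
      for (auto &q : cb) b.push_back(q);
    }
    if (front) f = front->clip_polygons(f);
    if (back) b = back ? back->clip_polygons(b) : b;
    else b.clear();
    f.insert(f.end(), b.begin(), b.end());
    return f;
  }

  void clip_to(const Node *bsp) {
    polygons = bsp->clip_polygons(polygons);
    if (front) front->clip_to(bsp);
    if (back) back->clip_to(bsp);
  }

  std::vector<Polygon> all_polygons() const {
    std::vector<Polygon> out = polygons;
    if (front) {
      auto f = front->all_polygons();
      out.insert(out.end(), f.begin(), f.end());
    }
    if (back) {
      auto b = back->all_polygons();
      out.insert(out.end(), b.begin(), b.end());
    }
    return out;
  }

  void build(const std::vector<Polygon> &polys) {
    if (polys.empty()) return;
    size_t start = 0;
    if (!has_plane) {
      plane = polys[0].plane;
      has_plane = true;
    }
    std::vector<Polygon> f, b;
    for (size_t i = start; i < polys.size(); ++i) {
      std::vector<Polygon> cf, cb;
      split_polygon(plane, polys[i], cf, cb, f, b);
      for (auto &q : cf) polygons.push_back(q);
      for (auto &q : cb) polygons.push_back(q);
    }
    if (!f.empty()) {
      if (!front) front = new Node();
      front->build(f);
    }
    if (!b.empty()) {
      if (!back) back = new Node();
      back->build(b);
    }
  }
};

static std::vector<Polygon> from_mesh(const MeshRef &m) {
  std::vector<Polygon> out;
  out.reserve(m.f.size());
  for (const auto &fc : m.f) {
    Polygon p;
    p.v = {m.v[fc[0]], m.v[fc[1]], m.v[fc[2]]};
    if (make_plane(p.v, p.plane)) out.push_back(p);
  }
  return out;
}

}  // namespace csg

// op: 0 = union, 1 = difference, 2 = intersection
// [[Rcpp::export]]
List cpp_csg(NumericMatrix VA, IntegerMatrix FA, NumericMatrix VB,
             IntegerMatrix FB, int op) {
  using namespace csg;
  MeshRef ma = make_mesh(VA, FA), mb = make_mesh(VB, FB);
  std::vector<Polygon> pa = from_mesh(ma), pb = from_mesh(mb);

  Node *a = new Node();
  Node *b = new Node();
  a->build(pa);
  b->build(pb);

  if (op == 1) a->invert();            // difference: ~(~A | B)
  if (op == 2) { a->invert(); b->invert(); }  // intersection: ~(~A | ~B)

  // union core
  a->clip_to(b);
  b->clip_to(a);
  b->invert();
  b->clip_to(a);
  b->invert();
  a->build(b->all_polygons());

  if (op == 1 || op == 2) a->invert();

  std::vector<Polygon> res = a->all_polygons();
  delete a;
  delete b;

  // triangulate by fan
  std::vector<Vec3> verts;
  std::vector<std::array<int, 3>> tris;
  for (const auto &p : res) {
    int base = (int)verts.size();
    for (const auto &v : p.v) verts.push_back(v);
    for (size_t i = 2; i < p.v.size(); ++i)
      tris.push_back({base, base + (int)i - 1, base + (int)i});
  }
  NumericMatrix Vout(verts.size(), 3);
  for (size_t i = 0; i < verts.size(); ++i)
    for (int d = 0; d < 3; ++d) Vout(i, d) = verts[i][d];
  IntegerMatrix Fout(tris.size(), 3);
  for (size_t i = 0; i < tris.size(); ++i)
    for (int d = 0; d < 3; ++d) Fout(i, d) = tris[i][d] + 1;
  return List::create(_["vertices"] = Vout, _["faces"] = Fout);
}

// ---------------------------------------------------------------------------
// Misc helpers
// ---------------------------------------------------------------------------

// [[Rcpp::export]]
double cpp_mesh_volume(NumericMatrix V, IntegerMatrix F) {
  double vol = 0.0;
  for (int t = 0; t < F.nrow(); ++t) {
    int a = F(t, 0) - 1, bq = F(t, 1) - 1, c = F(t, 2) - 1;
    Vec3 pa = {V(a, 0), V(a, 1), V(a, 2)};
    Vec3 pb = {V(bq, 0), V(bq, 1), V(bq, 2)};
    Vec3 pc = {V(c, 0), V(c, 1), V(c, 2)};
    vol += vdot(pa, vcross(pb, pc)) / 6.0;
  }
  return vol;
}
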