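// First-hit ray casting against a canopy triangle mesh.
//
// Intersections use the plane-parameter form t = N.(p1 - o) / (N.d) with a
// same-side cross-product inside test; the accelerated path walks a uniform
// 2-D grid (plan view) over facet bounding boxes with an Amanatides-Woo
// traversal and must agree exactly with the exhaustive loop (tested).

#include <Rcpp.h>
#include <vector>
#include <cmath>
#include <algorithm>
using namespace Rcpp;

struct Vec3 {
  double x, y, z;
};
static inline Vec3 vsub(const Vec3 &a, const Vec3 &b) {
  return {a.x - b.x, a.y - b.y, a.z - b.z};
}
static inline Vec3 vcross(const Vec3 &a, const Vec3 &b) {
  return {a.y * b.z - a.z * b.y, a.z * b.x - a.x * b.z, a.x * b.y - a.y * b.x};
}
static inline double vdot(const Vec3 &a, const Vec3 &b) {
  return a.x * b.x + a.y * b.y + a.z * b.z;
}
static inline double vnorm(const Vec3 &a) { return std::sqrt(vdot(a, a)); }

// Intersection of one ray with one triangle.
// Returns t > 0 on hit (writes cosine), or -1 on miss.
static double ray_tri(const Vec3 &o, const Vec3 &d, const Vec3 &p1,
                      const Vec3 &p2, const Vec3 &p3, double &cosine) {
  Vec3 N = vcross(vsub(p2, p1), vsub(p3, p1));
  double nlen = vnorm(N);
  if (nlen < 1e-300) return -1.0;  // degenerate facet
  double dlen = vnorm(d);
  double F = vdot(N, d);
  if (std::fabs(F) < 1e-12 * nlen * dlen) return -1.0;  // parallel
  double t = vdot(N, vsub(p1, o)) / F;
  if (t <= 1e-12) return -1.0;  // behind or at the origin
  Vec3 p = {o.x + t * d.x, o.y + t * d.y, o.z + t * d.z};
  Vec3 n1 = vsub(p, p1), n2 = vsub(p, p2), n3 = vsub(p, p3);
  double c12 = vdot(vcross(n1, n2), N);
  double c23 = vdot(vcross(n2, n3), N);
  double c31 = vdot(vcross(n3, n1), N);
  double tol = -1e-9 * nlen * nlen;
  if (c12 < tol || c23 < tol || c31 < tol) return -1.0;
  cosine = std::fabs(F) / (nlen * dlen);
  return t;
}

// [[Rcpp::export]]
List cpp_ray_triangle(NumericVector origin, NumericVector dir,
                      NumericVector v1, NumericVector v2, NumericVector v3) {
  Vec3 o = {origin[0], origin[1], origin[2]};
  Vec3 d = {dir[0], dir[1], dir[2]};
  Vec3 p1 = {v1[0], v1[1], v1[2]};
  Vec3 p2 = {v2[0], v2[1], v2[2]};
  Vec3 p3 = {v3[0], v3[1], v3[2]};
  double cosine = NA_REAL;
  double t = ray_tri(o, d, p1, p2, p3, cosine);
  if (t < 0)
    return List::create(_["hit"] = false);
  return List::create(
      _["hit"] = true, _["t"] = t,
      _["point"] = NumericVector::create(o.x + t * d.x, o.y + t * d.y,
                                         o.z + t * d.z),
      _["incidence_cosine"] = cosine);
}

struct Mesh {
  std::vector<Vec3> v;
  std::vector<int> t1, t2, t3;  // 0-based vertex indices
  int m;
};

static Mesh build_mesh(const NumericMatrix &verts, const IntegerMatrix &tris) {
  Mesh mesh;
  int nv = verts.nrow();
  mesh.v.resize(nv);
  for (int i = 0; i < nv; ++i) mesh.v[i] = {verts(i, 0), verts(i, 1), verts(i, 2)};
  mesh.m = tris.nrow();
  mesh.t1.resize(mesh.m);
  mesh.t2.resize(mesh.m);
  mesh.t3.resize(mesh.m);
  for (int j = 0; j < mesh.m; ++j) {
    mesh.t1[j] = tris(j, 0) - 1;  // R indices are 1-based
    mesh.t2[j] = tris(j, 1) - 1;
    mesh.t3[j] = tris(j, 2) - 1;
  }
  return mesh;
}

// Uniform plan-view grid over facet bounding boxes.
struct Grid {
  double x0, y0, cell;
  int nx, ny;
  std::vector<std::vector<int>> cells;
  double zmin, zmax;
};

static Grid build_grid(const Mesh &mesh, double cell_size) {
  Grid g;
  double xmin = R_PosInf, xmax = R_NegInf, ymin = R_PosInf, ymax = R_NegInf;
  g.zmin = R_PosInf;
  g.zmax = R_NegInf;
  for (const Vec3 &p : mesh.v) {
    xmin = std::min(xmin, p.x); xmax = std::max(xmax, p.x);
    ymin = std::min(ymin, p.y); ymax = std::max(ymax, p.y);
    g.zmin = std::min(g.zmin, p.z); g.zmax = std::max(g.zmax, p.z);
  }
  g.cell = cell_size;
  g.x0 = xmin - 1e-9;
  g.y0 = ymin - 1e-9;
  g.nx = std::max(1, (int)std::ceil((xmax - g.x0) / g.cell + 1e-9));
  g.ny = std::max(1, (int)std::ceil((ymax - g.y0) / g.cell + 1e-9));
  g.cells.assign((size_t)g.nx * g.ny, {});
  for (int j = 0; j < mesh.m; ++j) {
    const Vec3 &a = mesh.v[mesh.t1[j]], &b = mesh.v[mesh.t2[j]],
               &c = mesh.v[mesh.t3[j]];
    double bx0 = std::min({a.x, b.x, c.x}), bx1 = std::max({a.x, b.x, c.x});
    double by0 = std::min({a.y, b.y, c.y}), by1 = std::max({a.y, b.y, c.y});
    int i0 = std::max(0, (int)std::floor((bx0 - g.x0) / g.cell));
    int i1 = std::min(g.nx - 1, (int)std::floor((bx1 - g.x0) / g.cell));
    int k0 = std::max(0, (int)std::floor((by0 - g.y0) / g.cell));
    int k1 = std::min(g.ny - 1, (int)std::floor((by1 - g.y0) / g.cell));
    for (int i = i0; i <= i1; ++i)
      for (int k = k0; k <= k1; ++k)
        g.cells[(size_t)k * g.nx + i].push_back(j);
  }
  return g;
}

struct HitRec {
  int tri;  // 0-based, -1 = none
  double t, cosine;
};

static const double TIE_EPS = 1e-9;

static inline void consider(const Mesh &mesh, int j, const Vec3 &o,
                            const Vec3 &d, int skip_facet, int skip_group,
                            const int *groups, HitRec &best) {
  if (j == skip_facet) return;
  if (skip_group >= 0 && groups && groups[j] == skip_group) return;
  double cosine;
  double t = ray_tri(o, d, mesh.v[mesh.t1[j]], mesh.v[mesh.t2[j]],
                     mesh.v[mesh.t3[j]], cosine);
  if (t < 0) return;
  if (t < best.t - TIE_EPS ||
      (t < best.t + TIE_EPS && (best.tri < 0 || j < best.tri))) {
    best.tri = j;
    best.t = t;
    best.cosine = cosine;
  }
}

static HitRec first_hit_brute(const Mesh &mesh, const Vec3 &o, const Vec3 &d,
                              int skip_facet, int skip_group,
                              const int *groups) {
  HitRec best = {-1, R_PosInf, NA_REAL};
  for (int j = 0; j < mesh.m; ++j)
    consider(mesh, j, o, d, skip_facet, skip_group, groups, best);
  return best;
}

static HitRec first_hit_grid(const Mesh &mesh, const Grid &g, const Vec3 &o,
                             const Vec3 &d, int skip_facet, int skip_group,
                             const int *groups, std::vector<int> &stamp,
                             int ray_id) {
  HitRec best = {-1, R_PosInf, NA_REAL};
  // clip the ray parameter to the grid's xy extent and the mesh z slab
  double t0 = 0.0, t1 = R_PosInf;
  double gx1 = g.x0 + g.nx * g.cell, gy1 = g.y0 + g.ny * g.cell;
  const double lo[3] = {g.x0, g.y0, g.zmin - 1e-9};
  const double hi[3] = {gx1, gy1, g.zmax + 1e-9};
  const double oc[3] = {o.x, o.y, o.z};
  const double dc[3] = {d.x, d.y, d.z};
  for (int ax = 0; ax < 3; ++ax) {
    if (std::fabs(dc[ax]) < 1e-15) {
      if (oc[ax] < lo[ax] || oc[ax] > hi[ax]) return best;
    } else {
      double ta = (lo[ax] - oc[ax]) / dc[ax];
      double tb = (hi[ax] - oc[ax]) / dc[ax];
      if (ta > tb) std::swap(ta, tb);
      t0 = std::max(t0, ta);
      t1 = std::min(t1, tb);
    }
  }
  if (t1 < t0) return best;
  // entry cell
  double px = o.x + t0 * d.x, py = o.y + t0 * d.y;
  int ci = std::min(g.nx - 1, std::max(0, (int)std::floor((px - g.x0) / g.cell)));
  int ck = std::min(g.ny - 1, std::max(0, (int)std::floor((py - g.y0) / g.cell)));
  int stepx = d.x > 0 ? 1 : (d.x < 0 ? -1 : 0);
  int stepy = d.y > 0 ? 1 : (d.y < 0 ? -1 : 0);
  double tmaxx = R_PosInf, tmaxy = R_PosInf, tdx = R_PosInf, tdy = R_PosInf;
  if (stepx != 0) {
    double edge = g.x0 + (ci + (stepx > 0 ? 1 : 0)) * g.cell;
    tmaxx = (edge - o.x) / d.x;
    tdx = g.cell / std::fabs(d.x);
  }
  if (stepy != 0) {
    double edge = g.y0 + (ck + (stepy > 0 ? 1 : 0)) * g.cell;
    tmaxy = (edge - o.y) / d.y;
    tdy = g.cell / std::fabs(d.y);
  }
  double tcell = t0;
  while (true) {
    // visiting cell (ci, ck), entered at parameter tcell
    if (best.tri >= 0 && tcell > best.t + TIE_EPS) break;
    for (int j : g.cells[(size_t)ck * g.nx + ci]) {
      if (stamp[j] == ray_id) continue;
      stamp[j] = ray_id;
      consider(mesh, j, o, d, skip_facet, skip_group, groups, best);
    }
    double tnext = std::min(tmaxx, tmaxy);
    if (tnext > t1 + 1e-12) break;
    if (tmaxx <= tmaxy) {
      ci += stepx;
      if (ci < 0 || ci >= g.nx) break;
      tcell = tmaxx;
      tmaxx += tdx;
    } else {
      ck += stepy;
      if (ck < 0 || ck >= g.ny) break;
      tcell = tmaxy;
      tmaxy += tdy;
    }
  }
  return best;
}

// [[Rcpp::export]]
List cpp_first_hits(NumericMatrix verts, IntegerMatrix tris,
                    NumericMatrix origins, NumericMatrix dirs,
                    IntegerVector skip_facet, IntegerVector skip_group,
                    IntegerVector tri_group, double cell_size, bool brute) {
  Mesh mesh = build_mesh(verts, tris);
  int n = origins.nrow();
  bool one_dir = dirs.nrow() == 1;
  const int *groups = tri_group.size() == mesh.m ? &tri_group[0] : nullptr;
  bool have_skip_f = skip_facet.size() == n;
  bool have_skip_g = skip_group.size() == n;

  IntegerVector out_tri(n);
  NumericVector out_t(n), out_cos(n), px(n), py(n), pz(n);

  Grid grid;
  std::vector<int> stamp;
  bool use_grid = !brute && mesh.m > 0;
  if (use_grid) {
    grid = build_grid(mesh, cell_size);
    stamp.assign(mesh.m, -1);
  }
  for (int i = 0; i < n; ++i) {
    Vec3 o = {origins(i, 0), origins(i, 1), origins(i, 2)};
    int r = one_dir ? 0 : i;
    Vec3 d = {dirs(r, 0), dirs(r, 1), dirs(r, 2)};
    int sf = have_skip_f ? (skip_facet[i] == NA_INTEGER ? -1 : skip_facet[i] - 1) : -1;
    int sg = have_skip_g ? (skip_group[i] == NA_INTEGER ? -1 : skip_group[i]) : -1;
    HitRec h = mesh.m == 0 ? HitRec{-1, R_PosInf, NA_REAL}
               : (use_grid ? first_hit_grid(mesh, grid, o, d, sf, sg, groups,
                                            stamp, i)
                           : first_hit_brute(mesh, o, d, sf, sg, groups));
    if (h.tri < 0) {
      out_tri[i] = NA_INTEGER;
      out_t[i] = NA_REAL;
      out_cos[i] = NA_REAL;
      px[i] = NA_REAL; py[i] = NA_REAL; pz[i] = NA_REAL;
    } else {
      out_tri[i] = h.tri + 1;
      out_t[i] = h.t;
      out_cos[i] = h.cosine;
      px[i] = o.x + h.t * d.x;
      py[i] = o.y + h.t * d.y;
      pz[i] = o.z + h.t * d.z;
    }
  }
  return List::create(_["triangle"] = out_tri, _["t"] = out_t,
                      _["x"] = px, _["y"] = py, _["z"] = pz,
                      _["incidence_cosine"] = out_cos);
}
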