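// Planar Delaunay triangulation (Bowyer-Watson incremental insertion).
//
// Point sets are footprint samples: a few hundred well-separated points
// per crown, so the O(n * m) bad-triangle scan per insertion is ample.
// Cocircular rings are handled by treating on-circle points as outside the
// circumcircle (any triangulation of a cocircular fan is Delaunay).

#include <Rcpp.h>
#include <vector>
#include <array>
#include <cmath>
#include <map>
using namespace Rcpp;

struct Tri {
  int a, b, c;
  bool alive;
};

// > 0 iff d lies strictly inside the circumcircle of CCW triangle (a,b,c);
// extended precision keeps the far super-triangle tests consistent
static long double incircle(double ax, double ay, double bx, double by,
                            double cx, double cy, double dx, double dy) {
  long double adx = (long double)ax - dx, ady = (long double)ay - dy;
  long double bdx = (long double)bx - dx, bdy = (long double)by - dy;
  long double cdx = (long double)cx - dx, cdy = (long double)cy - dy;
  long double ad = adx * adx + ady * ady;
  long double bd = bdx * bdx + bdy * bdy;
  long double cd = cdx * cdx + cdy * cdy;
  return adx * (bdy * cd - bd * cdy) - ady * (bdx * cd - bd * cdx) +
         ad * (bdx * cdy - bdy * cdx);
}

static long double orient2d(double ax, double ay, double bx, double by,
                            double cx, double cy) {
  return ((long double)bx - ax) * ((long double)cy - ay) -
         ((long double)by - ay) * ((long double)cx - ax);
}

// [[Rcpp::export]]
IntegerMatrix cpp_delaunay(NumericMatrix pts) {
  int n = pts.nrow();
  if (n < 3) stop("need at least 3 points");
  // condition: shift/scale into the unit box
  double xmin = R_PosInf, xmax = R_NegInf, ymin = R_PosInf, ymax = R_NegInf;
  for (int i = 0; i < n; ++i) {
    xmin = std::min(xmin, pts(i, 0)); xmax = std::max(xmax, pts(i, 0));
    ymin = std::min(ymin, pts(i, 1)); ymax = std::max(ymax, pts(i, 1));
  }
  double span = std::max(xmax - xmin, ymax - ymin);
  if (span <= 0) stop("degenerate point set");
  std::vector<double> px(n + 3), py(n + 3);
  for (int i = 0; i < n; ++i) {
    px[i] = (pts(i, 0) - xmin) / span;
    py[i] = (pts(i, 1) - ymin) / span;
  }
  // super-triangle well outside the unit box
  px[n] = -1e6;    py[n] = -1e6;
  px[n + 1] = 2e6;  py[n + 1] = -1e6;
  px[n + 2] = 0.5;  py[n + 2] = 3e6;

  std::vector<Tri> tris;
  tris.push_back({n, n + 1, n + 2, true});

  const long double EPS = 1e-12;
  std::vector<int> bad;
  for (int p = 0; p < n; ++p) {
    bad.clear();
    for (int t = 0; t < (int)tris.size(); ++t) {
      if (!tris[t].alive) continue;
      const Tri &T = tris[t];
      if (incircle(px[T.a], py[T.a], px[T.b], py[T.b], px[T.c], py[T.c],
                   px[p], py[p]) > EPS)
        bad.push_back(t);
    }
    // cavity boundary: edges of bad triangles not shared by two bad ones
    std::map<std::pair<int, int>, int> edge_count;
    for (int t : bad) {
      const Tri &T = tris[t];
      int e[3][2] = {{T.a, T.b}, {T.b, T.c}, {T.c, T.a}};
      for (auto &ed : e) {
        int u = std::min(ed[0], ed[1]), v = std::max(ed[0], ed[1]);
        edge_count[{u, v}]++;
      }
      tris[t].alive = false;
    }
    for (auto &kv : edge_count) {
      if (kv.second != 1) continue;
      int u = kv.first.first, v = kv.first.second;
      // orient CCW
      if (orient2d(px[u], py[u], px[v], py[v], px[p], py[p]) > 0)
        tris.push_back({u, v, p, true});
      else
        tris.push_back({v, u, p, true});
    }
    // periodic compaction keeps the scan linear in live triangles
    if (tris.size() > 8 * (size_t)(p + 4)) {
      std::vector<Tri> keep;
      keep.reserve(tris.size());
      for (const Tri &T : tris)
        if (T.alive) keep.push_back(T);
      tris.swap(keep);
    }
  }
  std::vector<std::array<int, 3>> out;
  for (const Tri &T : tris) {
    if (!T.alive) continue;
    if (T.a >= n || T.b >= n || T.c >= n) continue;  // touches super-triangle
    out.push_back({T.a + 1, T.b + 1, T.c + 1});
  }
  IntegerMatrix res(out.size(), 3);
  for (size_t i = 0; i < out.size(); ++i) {
    res(i, 0) = out[i][0];
    res(i, 1) = out[i][1];
    res(i, 2) = out[i][2];
  }
  return res;
}
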