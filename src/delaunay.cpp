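#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

// Bowyer-Watson Delaunay triangulation in the plane.  Quadratic in the number
// of points, which is ample for histology-scale patterns (a few hundred
// centroids); degenerate near-cocircular quadruples (e.g. points on a regular
// lattice) are resolved by insertion order, which does not affect the
// distance-thresholded connectivity downstream.

struct Tri { int a, b, c; bool dead; };

static inline double orient(double ax, double ay, double bx, double by,
                            double cx, double cy) {
  return (bx - ax) * (cy - ay) - (by - ay) * (cx - ax);
}

// > 0 iff p strictly inside the circumcircle of CCW triangle (a,b,c)
static inline double incircle(double ax, double ay, double bx, double by,
                              double cx, double cy, double px, double py) {
  const double adx = ax - px, ady = ay - py;
  const double bdx = bx - px, bdy = by - py;
  const double cdx = cx - px, cdy = cy - py;
  const double ad = adx * adx + ady * ady;
  const double bd = bdx * bdx + bdy * bdy;
  const double cd = cdx * cdx + cdy * cdy;
  return adx * (bdy * cd - bd * cdy)
       - ady * (bdx * cd - bd * cdx)
       + ad  * (bdx * cdy - bdy * cdx);
}

// [[Rcpp::export]]
IntegerMatrix cpp_delaunay(NumericVector xin, NumericVector yin) {
  const int n = xin.size();
  if (n < 3) return IntegerMatrix(0, 3);

  // working copies with 3 super-triangle vertices appended
  std::vector<double> x(xin.begin(), xin.end()), y(yin.begin(), yin.end());
  double xmin = x[0], xmax = x[0], ymin = y[0], ymax = y[0];
  for (int i = 1; i < n; i++) {
    if (x[i] < xmin) xmin = x[i];
    if (x[i] > xmax) xmax = x[i];
    if (y[i] < ymin) ymin = y[i];
    if (y[i] > ymax) ymax = y[i];
  }
  // the enclosing triangle must be far enough away that no circumcircle of a
  // real hull triangle can reach its vertices; 1e5 x the data extent leaves
  // ample slack while the difference-based incircle predicate keeps precision
  const double dx = xmax - xmin, dy = ymax - ymin;
  const double dmax = ((dx > dy ? dx : dy) + 1.0) * 1e5;
  const double cx = (xmin + xmax) / 2.0, cy = (ymin + ymax) / 2.0;
  x.push_back(cx - 3.0 * dmax); y.push_back(cy - dmax);
  x.push_back(cx + 3.0 * dmax); y.push_back(cy - dmax);
  x.push_back(cx);              y.push_back(cy + 3.0 * dmax);

  std::vector<Tri> tris;
  {
    Tri t0; t0.a = n; t0.b = n + 1; t0.c = n + 2; t0.dead = false;
    if (orient(x[t0.a], y[t0.a], x[t0.b], y[t0.b], x[t0.c], y[t0.c]) < 0)
      std::swap(t0.b, t0.c);
    tris.push_back(t0);
  }

  std::vector<int> bad;
  std::vector<std::pair<int, int> > poly;

  for (int p = 0; p < n; p++) {
    bad.clear();
    for (size_t t = 0; t < tris.size(); t++) {
      if (tris[t].dead) continue;
      if (incircle(x[tris[t].a], y[tris[t].a], x[tris[t].b], y[tris[t].b],
                   x[tris[t].c], y[tris[t].c], x[p], y[p]) > 0)
        bad.push_back((int)t);
    }
    // boundary of the cavity: edges of bad triangles not shared by two of them
    poly.clear();
    for (size_t bi = 0; bi < bad.size(); bi++) {
      const Tri& T = tris[bad[bi]];
      int e[3][2] = { {T.a, T.b}, {T.b, T.c}, {T.c, T.a} };
      for (int k = 0; k < 3; k++) {
        bool shared = false;
        for (size_t bj = 0; bj < bad.size() && !shared; bj++) {
          if (bj == bi) continue;
          const Tri& U = tris[bad[bj]];
          int f[3][2] = { {U.a, U.b}, {U.b, U.c}, {U.c, U.a} };
          for (int m = 0; m < 3; m++) {
            if ((e[k][0] == f[m][0] && e[k][1] == f[m][1]) ||
                (e[k][0] == f[m][1] && e[k][1] == f[m][0])) { shared = true; break; }
          }
        }
        if (!shared) poly.push_back(std::make_pair(e[k][0], e[k][1]));
      }
    }
    for (size_t bi = 0; bi < bad.size(); bi++) tris[bad[bi]].dead = true;
    for (size_t k = 0; k < poly.size(); k++) {
      Tri t; t.a = poly[k].first; t.b = poly[k].second; t.c = p; t.dead = false;
      if (orient(x[t.a], y[t.a], x[t.b], y[t.b], x[t.c], y[t.c]) < 0)
        std::swap(t.b, t.c);
      tris.push_back(t);
    }
  }

  int m = 0;
  for (size_t t = 0; t < tris.size(); t++) {
    if (!tris[t].dead && tris[t].a < n && tris[t].b < n && tris[t].c < n) m++;
  }
  IntegerMatrix out(m, 3);
  int r = 0;
  for (size_t t = 0; t < tris.size(); t++) {
    if (!tris[t].dead && tris[t].a < n && tris[t].b < n && tris[t].c < n) {
      out(r, 0) = tris[t].a + 1;  // 1-based for R
      out(r, 1) = tris[t].b + 1;
      out(r, 2) = tris[t].c + 1;
      r++;
    }
  }
  return out;
}
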