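// Planar Delaunay triangulation (Bowyer-Watson with walk-based point
// location) and Voronoi cells clipped to an axis-aligned ROI rectangle.
//
// Cells are built per generator as the intersection of the ROI rectangle
// with the perpendicular-bisector half-planes of its Delaunay neighbours;
// this equals the true Voronoi cell restricted to the rectangle, because
// the facets of an (unbounded) Voronoi cell correspond exactly to the
// Delaunay neighbours of its generator. Coordinates are rescaled to unit
// size internally for numerical conditioning.

#include <Rcpp.h>
#include <vector>
#include <array>
#include <queue>
#include <unordered_map>
#include <unordered_set>
#include <algorithm>
#include <cmath>
#include <cstdint>

using namespace Rcpp;

static inline double orient2d(double ax, double ay, double bx, double by,
                              double cx, double cy) {
  return (bx - ax) * (cy - ay) - (by - ay) * (cx - ax);
}

// > 0 iff d lies strictly inside the circumcircle of CCW triangle (a,b,c)
static inline double incircle(double ax, double ay, double bx, double by,
                              double cx, double cy, double dx, double dy) {
  const double adx = ax - dx, ady = ay - dy;
  const double bdx = bx - dx, bdy = by - dy;
  const double cdx = cx - dx, cdy = cy - dy;
  const double ad = adx * adx + ady * ady;
  const double bd = bdx * bdx + bdy * bdy;
  const double cd = cdx * cdx + cdy * cdy;
  return adx * (bdy * cd - bd * cdy) - ady * (bdx * cd - bd * cdx) +
         ad * (bdx * cdy - bdy * cdx);
}

namespace {

struct Triangulation {
  std::vector<double> px, py;             // n real points + 3 super vertices
  int n = 0;                              // number of real points
  std::vector<std::array<int, 3>> tv;     // triangle vertices, CCW
  std::vector<std::array<int, 3>> tn;     // tn[t][k]: neighbour across edge opposite vertex k
  std::vector<char> alive;
  std::vector<int> freeList;
  int lastTri = 0;

  int newTriangle(int a, int b, int c) {
    int t;
    if (!freeList.empty()) {
      t = freeList.back();
      freeList.pop_back();
      tv[t] = {a, b, c};
      tn[t] = {-1, -1, -1};
      alive[t] = 1;
    } else {
      t = (int)tv.size();
      tv.push_back({a, b, c});
      tn.push_back({-1, -1, -1});
      alive.push_back(1);
    }
    return t;
  }

  // walk toward p from triangle `start`
  int locate(double x, double y, int start) const {
    int t = start;
    if (t < 0 || t >= (int)tv.size() || !alive[t]) {
      for (int i = (int)tv.size() - 1; i >= 0; --i)
        if (alive[i]) { t = i; break; }
    }
    const size_t maxSteps = 4 * tv.size() + 16;
    for (size_t step = 0; step < maxSteps; ++step) {
      bool moved = false;
      for (int k = 0; k < 3; ++k) {
        const int a = tv[t][(k + 1) % 3], b = tv[t][(k + 2) % 3];
        if (orient2d(px[a], py[a], px[b], py[b], x, y) < 0.0) {
          const int nb = tn[t][k];
          if (nb >= 0) { t = nb; moved = true; break; }
        }
      }
      if (!moved) return t;
    }
    // fallback: exhaustive scan (degenerate walking cycles)
    for (int i = 0; i < (int)tv.size(); ++i) {
      if (!alive[i]) continue;
      bool inside = true;
      for (int k = 0; k < 3 && inside; ++k) {
        const int a = tv[i][(k + 1) % 3], b = tv[i][(k + 2) % 3];
        if (orient2d(px[a], py[a], px[b], py[b], x, y) < -1e-12) inside = false;
      }
      if (inside) return i;
    }
    return t;
  }

  void insert(int pIdx) {
    const double x = px[pIdx], y = py[pIdx];
    const int t0 = locate(x, y, lastTri);

    // grow the cavity of triangles whose circumcircle contains p
    std::vector<int> bad;
    std::unordered_set<int> badSet;
    std::queue<int> q;
    q.push(t0);
    badSet.insert(t0);
    while (!q.empty()) {
      const int t = q.front();
      q.pop();
      const int a = tv[t][0], b = tv[t][1], c = tv[t][2];
      const bool isBad =
          (t == t0) ||
          incircle(px[a], py[a], px[b], py[b], px[c], py[c], x, y) > 0.0;
      if (!isBad) continue;
      bad.push_back(t);
      for (int k = 0; k < 3; ++k) {
        const int nb = tn[t][k];
        if (nb >= 0 && badSet.insert(nb).second) q.push(nb);
      }
    }
    std::unordered_set<int> isBad(bad.begin(), bad.end());

    // cavity boundary edges (a, b) with their outside neighbour
    struct BEdge { int a, b, outside; };
    std::vector<BEdge> boundary;
    for (int t : bad) {
      for (int k = 0; k < 3; ++k) {
        const int nb = tn[t][k];
        if (nb < 0 || !isBad.count(nb)) {
          boundary.push_back({tv[t][(k + 1) % 3], tv[t][(k + 2) % 3], nb});
        }
      }
    }
    for (int t : bad) {
      alive[t] = 0;
      freeList.push_back(t);
    }

    // re-triangulate the cavity as a fan around p
    std::unordered_map<int64_t, std::pair<int, int>> pending;  // edge key -> (tri, slot)
    int newest = -1;
    for (const BEdge& e : boundary) {
      const int t = newTriangle(e.a, e.b, pIdx);
      newest = t;
      tn[t][2] = e.outside;
      if (e.outside >= 0) {
        for (int k = 0; k < 3; ++k) {
          const int u = tv[e.outside][(k + 1) % 3], v = tv[e.outside][(k + 2) % 3];
          if ((u == e.a && v == e.b) || (u == e.b && v == e.a)) {
            tn[e.outside][k] = t;
            break;
          }
        }
      }
      // internal edges (b, p) [slot 0] and (p, a) [slot 1]
      for (int k = 0; k < 2; ++k) {
        const int other = (k == 0) ? e.b : e.a;
        const int64_t key = ((int64_t)std::min(other, pIdx) << 32) |
                            (int64_t)std::max(other, pIdx);
        auto it = pending.find(key);
        if (it == pending.end()) {
          pending[key] = {t, k};
        } else {
          tn[t][k] = it->second.first;
          tn[it->second.first][it->second.second] = t;
          pending.erase(it);
        }
      }
    }
    lastTri = newest;
  }
};

struct LabelledPoly {
  std::vector<double> vx, vy;
  std::vector<int> lab;  // label of directed edge starting at vertex k (-1 = ROI wall)
};

// Sutherland-Hodgman clip of `poly` by half-plane {q : (q - m) . d <= 0}
static void clipHalfPlane(LabelledPoly& poly, double mx, double my, double dx,
                          double dy, int newLabel) {
  const size_t nv = poly.vx.size();
  if (nv == 0) return;
  LabelledPoly out;
  out.vx.reserve(nv + 2);
  out.vy.reserve(nv + 2);
  out.lab.reserve(nv + 2);
  std::vector<double> f(nv);
  for (size_t k = 0; k < nv; ++k)
    f[k] = (poly.vx[k] - mx) * dx + (poly.vy[k] - my) * dy;
  for (size_t k = 0; k < nv; ++k) {
    const size_t k2 = (k + 1) % nv;
    const bool in1 = f[k] <= 0.0, in2 = f[k2] <= 0.0;
    if (in1) {
      out.vx.push_back(poly.vx[k]);
      out.vy.push_back(poly.vy[k]);
      out.lab.push_back(poly.lab[k]);
    }
    if (in1 != in2) {
      const double t = f[k] / (f[k] - f[k2]);
      out.vx.push_back(poly.vx[k] + t * (poly.vx[k2] - poly.vx[k]));
      out.vy.push_back(poly.vy[k] + t * (poly.vy[k2] - poly.vy[k]));
      // leaving the half-plane: the closing edge runs along the clip line;
      // entering: the remainder of the original edge keeps its label
      out.lab.push_back(in1 ? newLabel : poly.lab[k]);
    }
  }
  poly = out;
}

static double polyArea(const LabelledPoly& p) {
  double a = 0.0;
  const size_t nv = p.vx.size();
  for (size_t k = 0; k < nv; ++k) {
    const size_t k2 = (k + 1) % nv;
    a += p.vx[k] * p.vy[k2] - p.vx[k2] * p.vy[k];
  }
  return 0.5 * a;
}

}  // namespace

// [[Rcpp::export]]
List cpp_voronoi(NumericVector x, NumericVector y, double width, double height,
                 bool returnPolygons) {
  const int n = x.size();
  if (n < 1) stop("no points");

  // condition: rescale so max(width, height) == 1
  const double scale = 1.0 / std::max(width, height);
  const double W = width * scale, H = height * scale;

  Triangulation T;
  T.n = n;
  T.px.resize(n + 3);
  T.py.resize(n + 3);
  for (int i = 0; i < n; ++i) {
    T.px[i] = x[i] * scale;
    T.py[i] = y[i] * scale;
  }
  const double L = 1.0e3;
  T.px[n] = -L;        T.py[n] = -L;
  T.px[n + 1] = 2 * L; T.py[n + 1] = -L;
  T.px[n + 2] = -L;    T.py[n + 2] = 2 * L;
  T.newTriangle(n, n + 1, n + 2);

  // serpentine grid order for walk locality
  std::vector<int> order(n);
  for (int i = 0; i < n; ++i) order[i] = i;
  const int ng = std::max(1, (int)std::ceil(std::sqrt((double)n / 4.0)));
  std::vector<int64_t> key(n);
  for (int i = 0; i < n; ++i) {
    int ix = std::min(ng - 1, std::max(0, (int)(T.px[i] / W * ng)));
    int iy = std::min(ng - 1, std::max(0, (int)(T.py[i] / H * ng)));
    if (iy % 2 == 1) ix = ng - 1 - ix;
    key[i] = (int64_t)iy * ng + ix;
  }
  std::stable_sort(order.begin(), order.end(),
                   [&](int a, int b) { return key[a] < key[b]; });

  for (int i : order) T.insert(i);

  // Delaunay adjacency over real points
  std::vector<std::vector<int>> nbr(n);
  for (size_t t = 0; t < T.tv.size(); ++t) {
    if (!T.alive[t]) continue;
    for (int k = 0; k < 3; ++k) {
      const int a = T.tv[t][k], b = T.tv[t][(k + 1) % 3];
      if (a < n && b < n && a < b) {
        nbr[a].push_back(b);
        nbr[b].push_back(a);
      }
    }
  }
  for (int i = 0; i < n; ++i) {
    std::sort(nbr[i].begin(), nbr[i].end());
    nbr[i].erase(std::unique(nbr[i].begin(), nbr[i].end()), nbr[i].end());
  }

  // clipped Voronoi cells
  const double lenTol2 = 1e-20;
  NumericVector area(n);
  LogicalVector touches(n);
  List polys(returnPolygons ? n : 0);
  // facet presence i -> j (for symmetric positive-length adjacency)
  std::vector<std::unordered_set<int>> facet(n);

  for (int i = 0; i < n; ++i) {
    LabelledPoly poly;
    poly.vx = {0.0, W, W, 0.0};
    poly.vy = {0.0, 0.0, H, H};
    poly.lab = {-1, -1, -1, -1};
    for (int j : nbr[i]) {
      const double mx = 0.5 * (T.px[i] + T.px[j]);
      const double my = 0.5 * (T.py[i] + T.py[j]);
      clipHalfPlane(poly, mx, my, T.px[j] - T.px[i], T.py[j] - T.py[i], j);
      if (poly.vx.size() < 3) break;
    }
    area[i] = (poly.vx.size() >= 3 ? polyArea(poly) : 0.0) / (scale * scale);
    bool onWall = false;
    const size_t nv = poly.vx.size();
    for (size_t k = 0; k < nv; ++k) {
      const size_t k2 = (k + 1) % nv;
      const double ex = poly.vx[k2] - poly.vx[k];
      const double ey = poly.vy[k2] - poly.vy[k];
      if (ex * ex + ey * ey <= lenTol2) continue;
      if (poly.lab[k] == -1)
        onWall = true;
      else
        facet[i].insert(poly.lab[k]);
    }
    touches[i] = onWall;
    if (returnPolygons) {
      NumericMatrix m(nv, 2);
      for (size_t k = 0; k < nv; ++k) {
        m(k, 0) = poly.vx[k] / scale;
        m(k, 1) = poly.vy[k] / scale;
      }
      polys[i] = m;
    }
  }

  // symmetric adjacency: facet present from both sides
  std::vector<int> ea, eb;
  for (int i = 0; i < n; ++i) {
    for (int j : facet[i]) {
      if (j > i && facet[j].count(i)) {
        ea.push_back(i + 1);
        eb.push_back(j + 1);
      }
    }
  }
  IntegerMatrix edges(ea.size(), 2);
  for (size_t k = 0; k < ea.size(); ++k) {
    edges(k, 0) = ea[k];
    edges(k, 1) = eb[k];
  }

  List out = List::create(_["area"] = area, _["touchesBoundary"] = touches,
                          _["edges"] = edges);
  if (returnPolygons) out["polygons"] = polys;
  return out;
}
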