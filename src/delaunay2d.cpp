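// Incremental (Bowyer-Watson) 2-D Delaunay triangulation. Input points are
// expected pre-deduplicated; near-duplicates are skipped. Backs the alpha-
// shape boundary extraction for projected disc vertices.
#include <Rcpp.h>
#include <cmath>
#include <vector>
#include <map>
#include <array>
using namespace Rcpp;

namespace {
struct Tri {
  int a, b, c;      // point indices (super-triangle uses n, n+1, n+2)
  double cx, cy, r2;  // circumcircle
  bool alive;
};

inline bool circum(double ax, double ay, double bx, double by, double cx, double cy,
                   double& ox, double& oy, double& r2) {
  double d = 2.0 * (ax * (by - cy) + bx * (cy - ay) + cx * (ay - by));
  if (std::fabs(d) < 1e-14) return false;
  double a2 = ax * ax + ay * ay, b2 = bx * bx + by * by, c2 = cx * cx + cy * cy;
  ox = (a2 * (by - cy) + b2 * (cy - ay) + c2 * (ay - by)) / d;
  oy = (a2 * (cx - bx) + b2 * (ax - cx) + c2 * (bx - ax)) / d;
  double dx = ax - ox, dy = ay - oy;
  r2 = dx * dx + dy * dy;
  return true;
}
}  // namespace

// [[Rcpp::export(name = "cpp_delaunay2d")]]
IntegerMatrix cpp_delaunay2d(NumericVector x, NumericVector y) {
  int n = x.size();
  if (n < 3) return IntegerMatrix(0, 3);
  std::vector<double> px(n + 3), py(n + 3);
  double xmin = R_PosInf, xmax = R_NegInf, ymin = R_PosInf, ymax = R_NegInf;
  for (int i = 0; i < n; ++i) {
    px[i] = x[i]; py[i] = y[i];
    xmin = std::min(xmin, (double)x[i]); xmax = std::max(xmax, (double)x[i]);
    ymin = std::min(ymin, (double)y[i]); ymax = std::max(ymax, (double)y[i]);
  }
  double dmax = std::max(xmax - xmin, ymax - ymin);
  if (dmax <= 0) dmax = 1.0;
  double mx = 0.5 * (xmin + xmax), my = 0.5 * (ymin + ymax);
  // large super-triangle
  px[n] = mx - 30.0 * dmax; py[n] = my - 10.0 * dmax;
  px[n + 1] = mx + 30.0 * dmax; py[n + 1] = my - 10.0 * dmax;
  px[n + 2] = mx; py[n + 2] = my + 30.0 * dmax;

  std::vector<Tri> tris;
  {
    Tri t{n, n + 1, n + 2, 0, 0, 0, true};
    circum(px[t.a], py[t.a], px[t.b], py[t.b], px[t.c], py[t.c], t.cx, t.cy, t.r2);
    tris.push_back(t);
  }
  // deterministic insertion-order jitter to break cocircular ties
  for (int ip = 0; ip < n; ++ip) {
    double qx = px[ip], qy = py[ip];
    // collect bad triangles
    std::vector<int> bad;
    for (size_t t = 0; t < tris.size(); ++t) {
      if (!tris[t].alive) continue;
      double dx = qx - tris[t].cx, dy = qy - tris[t].cy;
      if (dx * dx + dy * dy <= tris[t].r2 * (1.0 + 1e-12)) bad.push_back((int)t);
    }
    if (bad.empty()) continue;  // duplicate / degenerate point; skip
    // boundary of the cavity: edges seen exactly once
    std::map<std::pair<int, int>, std::pair<int, int>> edges;  // sorted edge -> (count, orient-a)
    for (int t : bad) {
      int vs[3] = {tris[t].a, tris[t].b, tris[t].c};
      for (int e = 0; e < 3; ++e) {
        int u = vs[e], v = vs[(e + 1) % 3];
        auto k = std::minmax(u, v);
        auto it = edges.find({k.first, k.second});
        if (it == edges.end()) edges[{k.first, k.second}] = {1, u};
        else it->second.first += 1;
      }
      tris[t].alive = false;
    }
    for (auto& kv : edges) {
      if (kv.second.first != 1) continue;
      int u = kv.second.second;
      int v = (u == kv.first.first) ? kv.first.second : kv.first.first;
      Tri t{u, v, ip, 0, 0, 0, true};
      if (!circum(px[t.a], py[t.a], px[t.b], py[t.b], px[t.c], py[t.c], t.cx, t.cy, t.r2)) {
        t.r2 = -1.0;  // degenerate sliver; keep with empty circle so it never conflicts
        t.cx = qx; t.cy = qy;
      }
      tris.push_back(t);
    }
  }
  std::vector<std::array<int, 3>> out;
  for (auto& t : tris) {
    if (!t.alive) continue;
    if (t.a >= n || t.b >= n || t.c >= n) continue;  // touches super-triangle
    // enforce CCW
    double ax = px[t.a], ay = py[t.a], bx = px[t.b], by = py[t.b], cx = px[t.c], cy = py[t.c];
    double area2 = (bx - ax) * (cy - ay) - (by - ay) * (cx - ax);
    if (std::fabs(area2) < 1e-14) continue;
    if (area2 > 0) out.push_back({t.a + 1, t.b + 1, t.c + 1});
    else out.push_back({t.a + 1, t.c + 1, t.b + 1});
  }
  IntegerMatrix M(out.size(), 3);
  for (size_t i = 0; i < out.size(); ++i) { M(i, 0) = out[i][0]; M(i, 1) = out[i][1]; M(i, 2) = out[i][2]; }
  return M;
}
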