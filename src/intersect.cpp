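// Surface self-intersection detection: Moller's triangle-triangle overlap
// test over grid-hashed candidate pairs, skipping pairs that share a vertex.
#include <Rcpp.h>
#include <cmath>
#include <vector>
#include <unordered_map>
using namespace Rcpp;

namespace {

typedef double Vec3[3];

inline void sub(Vec3 r, const Vec3 a, const Vec3 b) {
  r[0] = a[0] - b[0]; r[1] = a[1] - b[1]; r[2] = a[2] - b[2];
}
inline void crossp(Vec3 r, const Vec3 a, const Vec3 b) {
  r[0] = a[1] * b[2] - a[2] * b[1];
  r[1] = a[2] * b[0] - a[0] * b[2];
  r[2] = a[0] * b[1] - a[1] * b[0];
}
inline double dotp(const Vec3 a, const Vec3 b) {
  return a[0] * b[0] + a[1] * b[1] + a[2] * b[2];
}

const double TTI_EPS = 1e-10;

inline void isect2(double vv0, double vv1, double vv2, double d0, double d1, double d2,
                   double& i0, double& i1) {
  i0 = vv0 + (vv1 - vv0) * d0 / (d0 - d1);
  i1 = vv0 + (vv2 - vv0) * d0 / (d0 - d2);
}

// coplanar case: project to dominant plane, edge-edge + containment tests
inline bool edge_edge(const double* v0, const double* v1, const double* u0, const double* u1,
                      int i0, int i1) {
  double ax = v1[i0] - v0[i0], ay = v1[i1] - v0[i1];
  double bx = u0[i0] - u1[i0], by = u0[i1] - u1[i1];
  double cx = v0[i0] - u0[i0], cy = v0[i1] - u0[i1];
  double f = ay * bx - ax * by;
  double d = by * cx - bx * cy;
  if ((f > 0 && d >= 0 && d <= f) || (f < 0 && d <= 0 && d >= f)) {
    double e = ax * cy - ay * cx;
    if (f > 0) { if (e >= 0 && e <= f) return true; }
    else { if (e <= 0 && e >= f) return true; }
  }
  return false;
}

inline bool point_in_tri2(const double* p, const double* a, const double* b, const double* c,
                          int i0, int i1) {
  double d0 = (b[i0] - a[i0]) * (p[i1] - a[i1]) - (b[i1] - a[i1]) * (p[i0] - a[i0]);
  double d1 = (c[i0] - b[i0]) * (p[i1] - b[i1]) - (c[i1] - b[i1]) * (p[i0] - b[i0]);
  double d2 = (a[i0] - c[i0]) * (p[i1] - c[i1]) - (a[i1] - c[i1]) * (p[i0] - c[i0]);
  bool has_neg = (d0 < 0) || (d1 < 0) || (d2 < 0);
  bool has_pos = (d0 > 0) || (d1 > 0) || (d2 > 0);
  return !(has_neg && has_pos);
}

inline bool coplanar_tri_tri(const Vec3 n, const Vec3 v0, const Vec3 v1, const Vec3 v2,
                             const Vec3 u0, const Vec3 u1, const Vec3 u2) {
  double a[3] = {std::fabs(n[0]), std::fabs(n[1]), std::fabs(n[2])};
  int i0, i1;
  if (a[0] > a[1]) { if (a[0] > a[2]) { i0 = 1; i1 = 2; } else { i0 = 0; i1 = 1; } }
  else { if (a[2] > a[1]) { i0 = 0; i1 = 1; } else { i0 = 0; i1 = 2; } }
  if (edge_edge(v0, v1, u0, u1, i0, i1)) return true;
  if (edge_edge(v0, v1, u1, u2, i0, i1)) return true;
  if (edge_edge(v0, v1, u2, u0, i0, i1)) return true;
  if (edge_edge(v1, v2, u0, u1, i0, i1)) return true;
  if (edge_edge(v1, v2, u1, u2, i0, i1)) return true;
  if (edge_edge(v1, v2, u2, u0, i0, i1)) return true;
  if (edge_edge(v2, v0, u0, u1, i0, i1)) return true;
  if (edge_edge(v2, v0, u1, u2, i0, i1)) return true;
  if (edge_edge(v2, v0, u2, u0, i0, i1)) return true;
  if (point_in_tri2(v0, u0, u1, u2, i0, i1)) return true;
  if (point_in_tri2(u0, v0, v1, v2, i0, i1)) return true;
  return false;
}

bool tri_tri_overlap(const Vec3 v0, const Vec3 v1, const Vec3 v2,
                     const Vec3 u0, const Vec3 u1, const Vec3 u2) {
  Vec3 e1, e2, n1, n2, dvec;
  sub(e1, v1, v0); sub(e2, v2, v0); crossp(n1, e1, e2);
  double d1 = -dotp(n1, v0);
  double du0 = dotp(n1, u0) + d1, du1 = dotp(n1, u1) + d1, du2 = dotp(n1, u2) + d1;
  if (std::fabs(du0) < TTI_EPS) du0 = 0.0;
  if (std::fabs(du1) < TTI_EPS) du1 = 0.0;
  if (std::fabs(du2) < TTI_EPS) du2 = 0.0;
  double du0du1 = du0 * du1, du0du2 = du0 * du2;
  if (du0du1 > 0.0 && du0du2 > 0.0) return false;

  sub(e1, u1, u0); sub(e2, u2, u0); crossp(n2, e1, e2);
  double d2 = -dotp(n2, u0);
  double dv0 = dotp(n2, v0) + d2, dv1 = dotp(n2, v1) + d2, dv2 = dotp(n2, v2) + d2;
  if (std::fabs(dv0) < TTI_EPS) dv0 = 0.0;
  if (std::fabs(dv1) < TTI_EPS) dv1 = 0.0;
  if (std::fabs(dv2) < TTI_EPS) dv2 = 0.0;
  double dv0dv1 = dv0 * dv1, dv0dv2 = dv0 * dv2;
  if (dv0dv1 > 0.0 && dv0dv2 > 0.0) return false;

  crossp(dvec, n1, n2);
  double mx = std::fabs(dvec[0]);
  int index = 0;
  double b = std::fabs(dvec[1]), c = std::fabs(dvec[2]);
  if (b > mx) { mx = b; index = 1; }
  if (c > mx) { mx = c; index = 2; }
  if (mx < TTI_EPS) {
    if (du0 == 0.0 && du1 == 0.0 && du2 == 0.0)
      return coplanar_tri_tri(n1, v0, v1, v2, u0, u1, u2);
    return false;
  }
  double vp0 = v0[index], vp1 = v1[index], vp2 = v2[index];
  double up0 = u0[index], up1 = u1[index], up2 = u2[index];

  double isect1[2], isect2v[2];
  // triangle 1 interval
  {
    double a0 = dv0, a1 = dv1, a2 = dv2, p0 = vp0, p1 = vp1, p2 = vp2;
    if (a0 * a1 > 0.0) isect2(p2, p0, p1, a2, a0, a1, isect1[0], isect1[1]);
    else if (a0 * a2 > 0.0) isect2(p1, p0, p2, a1, a0, a2, isect1[0], isect1[1]);
    else if (a1 * a2 > 0.0 || a0 != 0.0) isect2(p0, p1, p2, a0, a1, a2, isect1[0], isect1[1]);
    else if (a1 != 0.0) isect2(p1, p0, p2, a1, a0, a2, isect1[0], isect1[1]);
    else if (a2 != 0.0) isect2(p2, p0, p1, a2, a0, a1, isect1[0], isect1[1]);
    else return coplanar_tri_tri(n1, v0, v1, v2, u0, u1, u2);
  }
  // triangle 2 interval
  {
    double a0 = du0, a1 = du1, a2 = du2, p0 = up0, p1 = up1, p2 = up2;
    if (a0 * a1 > 0.0) isect2(p2, p0, p1, a2, a0, a1, isect2v[0], isect2v[1]);
    else if (a0 * a2 > 0.0) isect2(p1, p0, p2, a1, a0, a2, isect2v[0], isect2v[1]);
    else if (a1 * a2 > 0.0 || a0 != 0.0) isect2(p0, p1, p2, a0, a1, a2, isect2v[0], isect2v[1]);
    else if (a1 != 0.0) isect2(p1, p0, p2, a1, a0, a2, isect2v[0], isect2v[1]);
    else if (a2 != 0.0) isect2(p2, p0, p1, a2, a0, a1, isect2v[0], isect2v[1]);
    else return coplanar_tri_tri(n1, v0, v1, v2, u0, u1, u2);
  }
  if (isect1[0] > isect1[1]) std::swap(isect1[0], isect1[1]);
  if (isect2v[0] > isect2v[1]) std::swap(isect2v[0], isect2v[1]);
  if (isect1[1] < isect2v[0] || isect2v[1] < isect1[0]) return false;
  return true;
}

}  // namespace

// Returns a 2-column matrix of intersecting non-adjacent face pairs (1-based),
// at most max_pairs rows (0 rows => no self-intersection found).
// [[Rcpp::export(name = "cpp_self_intersections")]]
IntegerMatrix cpp_self_intersections(NumericMatrix V, IntegerMatrix F, int max_pairs) {
  int nf = F.nrow();
  // bounding boxes and grid hashing by face bbox cells
  std::vector<double> lo(3 * nf), hi(3 * nf);
  double gmin[3] = {R_PosInf, R_PosInf, R_PosInf}, gmax[3] = {R_NegInf, R_NegInf, R_NegInf};
  double avg_edge = 0.0;
  for (int f = 0; f < nf; ++f) {
    for (int k = 0; k < 3; ++k) {
      double a = V(F(f, 0) - 1, k), b = V(F(f, 1) - 1, k), c = V(F(f, 2) - 1, k);
      double l = std::min(a, std::min(b, c)), h = std::max(a, std::max(b, c));
      lo[3 * f + k] = l; hi[3 * f + k] = h;
      if (l < gmin[k]) gmin[k] = l;
      if (h > gmax[k]) gmax[k] = h;
    }
    double dx = V(F(f, 1) - 1, 0) - V(F(f, 0) - 1, 0);
    double dy = V(F(f, 1) - 1, 1) - V(F(f, 0) - 1, 1);
    double dz = V(F(f, 1) - 1, 2) - V(F(f, 0) - 1, 2);
    avg_edge += std::sqrt(dx * dx + dy * dy + dz * dz);
  }
  avg_edge /= std::max(1, nf);
  double cell = std::max(avg_edge * 2.0, 1e-6);
  std::unordered_map<long long, std::vector<int>> grid;
  auto key = [&](int i, int j, int k) {
    return ((long long)(i + 1048576) << 42) | ((long long)(j + 1048576) << 21) | (long long)(k + 1048576);
  };
  for (int f = 0; f < nf; ++f) {
    int x0 = (int)std::floor(lo[3 * f] / cell), x1 = (int)std::floor(hi[3 * f] / cell);
    int y0 = (int)std::floor(lo[3 * f + 1] / cell), y1 = (int)std::floor(hi[3 * f + 1] / cell);
    int z0 = (int)std::floor(lo[3 * f + 2] / cell), z1 = (int)std::floor(hi[3 * f + 2] / cell);
    for (int i = x0; i <= x1; ++i)
      for (int j = y0; j <= y1; ++j)
        for (int k = z0; k <= z1; ++k) grid[key(i, j, k)].push_back(f);
  }
  std::vector<std::pair<int, int>> hits;
  std::unordered_map<long long, char> tested;
  for (auto& kv : grid) {
    auto& cellfaces = kv.second;
    int m = cellfaces.size();
    for (int a = 0; a < m; ++a)
      for (int b = a + 1; b < m; ++b) {
        int f1 = cellfaces[a], f2 = cellfaces[b];
        if (f1 > f2) std::swap(f1, f2);
        long long pk = (long long)f1 * nf + f2;
        if (tested.count(pk)) continue;
        tested[pk] = 1;
        // bbox reject
        bool sep = false;
        for (int k = 0; k < 3 && !sep; ++k)
          if (lo[3 * f1 + k] > hi[3 * f2 + k] || lo[3 * f2 + k] > hi[3 * f1 + k]) sep = true;
        if (sep) continue;
        // skip adjacent (shared vertex)
        bool adj = false;
        for (int i = 0; i < 3 && !adj; ++i)
          for (int j = 0; j < 3; ++j)
            if (F(f1, i) == F(f2, j)) { adj = true; break; }
        if (adj) continue;
        Vec3 v0, v1, v2, u0, u1, u2;
        for (int k = 0; k < 3; ++k) {
          v0[k] = V(F(f1, 0) - 1, k); v1[k] = V(F(f1, 1) - 1, k); v2[k] = V(F(f1, 2) - 1, k);
          u0[k] = V(F(f2, 0) - 1, k); u1[k] = V(F(f2, 1) - 1, k); u2[k] = V(F(f2, 2) - 1, k);
        }
        if (tri_tri_overlap(v0, v1, v2, u0, u1, u2)) {
          hits.push_back({f1 + 1, f2 + 1});
          if ((int)hits.size() >= max_pairs) goto done;
        }
      }
  }
done:
  IntegerMatrix out(hits.size(), 2);
  for (size_t i = 0; i < hits.size(); ++i) { out(i, 0) = hits[i].first; out(i, 1) = hits[i].second; }
  return out;
}
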