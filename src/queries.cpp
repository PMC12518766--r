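// Point/mesh query kernels: ray casting, generalized winding numbers,
// closest point on a triangle soup, ray all-hits, pairwise minimum distance.
// Vertices are passed as n x 3 numeric matrices, faces as m x 3 *1-based*
// integer matrices (converted to 0-based here).
#include <Rcpp.h>
#include <cmath>
#include <vector>
#include <algorithm>
#include <functional>
#include <unordered_map>
using namespace Rcpp;

namespace {

struct V3 {
  double x, y, z;
};
inline V3 v3(double x, double y, double z) { return V3{x, y, z}; }
inline V3 operator-(const V3& a, const V3& b) { return v3(a.x - b.x, a.y - b.y, a.z - b.z); }
inline V3 operator+(const V3& a, const V3& b) { return v3(a.x + b.x, a.y + b.y, a.z + b.z); }
inline V3 operator*(double s, const V3& a) { return v3(s * a.x, s * a.y, s * a.z); }
inline double dot(const V3& a, const V3& b) { return a.x * b.x + a.y * b.y + a.z * b.z; }
inline V3 cross(const V3& a, const V3& b) {
  return v3(a.y * b.z - a.z * b.y, a.z * b.x - a.x * b.z, a.x * b.y - a.y * b.x);
}
inline double norm(const V3& a) { return std::sqrt(dot(a, a)); }

inline V3 row3(const NumericMatrix& M, int i) { return v3(M(i, 0), M(i, 1), M(i, 2)); }

// Moller-Trumbore. Returns true on hit with t >= tmin; u,v barycentric.
inline bool ray_tri(const V3& o, const V3& d, const V3& a, const V3& b, const V3& c,
                    double& t, double& u, double& v) {
  const double EPS = 1e-13;
  V3 e1 = b - a, e2 = c - a;
  V3 p = cross(d, e2);
  double det = dot(e1, p);
  if (std::fabs(det) < EPS) return false;
  double inv = 1.0 / det;
  V3 s = o - a;
  u = dot(s, p) * inv;
  if (u < 0.0 || u > 1.0) return false;
  V3 q = cross(s, e1);
  v = dot(d, q) * inv;
  if (v < 0.0 || u + v > 1.0) return false;
  t = dot(e2, q) * inv;
  return true;
}

// Squared distance from point p to triangle (a,b,c) (Ericson, RTCD 5.1.5).
inline double point_tri_d2(const V3& p, const V3& a, const V3& b, const V3& c, V3* nearest = nullptr) {
  V3 ab = b - a, ac = c - a, ap = p - a;
  double d1 = dot(ab, ap), d2 = dot(ac, ap);
  if (d1 <= 0.0 && d2 <= 0.0) { if (nearest) *nearest = a; V3 d = p - a; return dot(d, d); }
  V3 bp = p - b;
  double d3 = dot(ab, bp), d4 = dot(ac, bp);
  if (d3 >= 0.0 && d4 <= d3) { if (nearest) *nearest = b; V3 d = p - b; return dot(d, d); }
  double vc = d1 * d4 - d3 * d2;
  if (vc <= 0.0 && d1 >= 0.0 && d3 <= 0.0) {
    double v = d1 / (d1 - d3);
    V3 q = a + v * ab; if (nearest) *nearest = q; V3 d = p - q; return dot(d, d);
  }
  V3 cp = p - c;
  double d5 = dot(ab, cp), d6 = dot(ac, cp);
  if (d6 >= 0.0 && d5 <= d6) { if (nearest) *nearest = c; V3 d = p - c; return dot(d, d); }
  double vb = d5 * d2 - d1 * d6;
  if (vb <= 0.0 && d2 >= 0.0 && d6 <= 0.0) {
    double w = d2 / (d2 - d6);
    V3 q = a + w * ac; if (nearest) *nearest = q; V3 d = p - q; return dot(d, d);
  }
  double va = d3 * d6 - d5 * d4;
  if (va <= 0.0 && (d4 - d3) >= 0.0 && (d5 - d6) >= 0.0) {
    double w = (d4 - d3) / ((d4 - d3) + (d5 - d6));
    V3 q = b + w * (c - b); if (nearest) *nearest = q; V3 d = p - q; return dot(d, d);
  }
  double denom = 1.0 / (va + vb + vc);
  double v = vb * denom, w = vc * denom;
  V3 q = a + v * ab + w * ac;
  if (nearest) *nearest = q; V3 d = p - q; return dot(d, d);
}

// Signed solid angle of triangle (a,b,c) seen from p (van Oosterom & Strackee).
inline double solid_angle(const V3& p, const V3& a, const V3& b, const V3& c) {
  V3 ra = a - p, rb = b - p, rc = c - p;
  double la = norm(ra), lb = norm(rb), lc = norm(rc);
  double num = dot(ra, cross(rb, rc));
  double den = la * lb * lc + dot(ra, rb) * lc + dot(rb, rc) * la + dot(rc, ra) * lb;
  return 2.0 * std::atan2(num, den);
}

}  // namespace

// [[Rcpp::export(name = "cpp_winding_number")]]
NumericVector cpp_winding_number(NumericMatrix V, IntegerMatrix F, NumericMatrix P) {
  int nf = F.nrow(), np = P.nrow();
  NumericVector out(np);
  for (int ip = 0; ip < np; ++ip) {
    V3 p = row3(P, ip);
    double s = 0.0;
    for (int f = 0; f < nf; ++f) {
      s += solid_angle(p, row3(V, F(f, 0) - 1), row3(V, F(f, 1) - 1), row3(V, F(f, 2) - 1));
    }
    out[ip] = s / (4.0 * M_PI);
  }
  return out;
}

// Distance from each point to the surface (brute force over faces).
// [[Rcpp::export(name = "cpp_dist_to_mesh")]]
NumericVector cpp_dist_to_mesh(NumericMatrix V, IntegerMatrix F, NumericMatrix P) {
  int nf = F.nrow(), np = P.nrow();
  NumericVector out(np);
  for (int ip = 0; ip < np; ++ip) {
    V3 p = row3(P, ip);
    double best = R_PosInf;
    for (int f = 0; f < nf; ++f) {
      double d2 = point_tri_d2(p, row3(V, F(f, 0) - 1), row3(V, F(f, 1) - 1), row3(V, F(f, 2) - 1));
      if (d2 < best) best = d2;
    }
    out[ip] = std::sqrt(best);
  }
  return out;
}

// Closest surface point for each query point. Returns list(dist, points).
// [[Rcpp::export(name = "cpp_closest_on_mesh")]]
List cpp_closest_on_mesh(NumericMatrix V, IntegerMatrix F, NumericMatrix P) {
  int nf = F.nrow(), np = P.nrow();
  NumericVector dist(np);
  NumericMatrix Q(np, 3);
  for (int ip = 0; ip < np; ++ip) {
    V3 p = row3(P, ip);
    double best = R_PosInf; V3 bq = p;
    for (int f = 0; f < nf; ++f) {
      V3 q;
      double d2 = point_tri_d2(p, row3(V, F(f, 0) - 1), row3(V, F(f, 1) - 1), row3(V, F(f, 2) - 1), &q);
      if (d2 < best) { best = d2; bq = q; }
    }
    dist[ip] = std::sqrt(best);
    Q(ip, 0) = bq.x; Q(ip, 1) = bq.y; Q(ip, 2) = bq.z;
  }
  return List::create(_["dist"] = dist, _["points"] = Q);
}

// Containment test: ray casting with a generalized-winding-number fallback
// for rays that graze edges/vertices. Points within `band` of the surface
// are classified inside (documented convention).
// [[Rcpp::export(name = "cpp_points_in_mesh")]]
LogicalVector cpp_points_in_mesh(NumericMatrix V, IntegerMatrix F, NumericMatrix P, double band) {
  int nf = F.nrow(), np = P.nrow();
  LogicalVector out(np);
  // A few fixed irrational-ish directions; retried in order on degeneracy.
  const double dirs[4][3] = {
    {0.285203917243847, 0.577350269189626, 0.765167040529483},
    {-0.532089111, 0.742397821, 0.407231775},
    {0.815492103, -0.130287441, 0.563901214},
    {0.097210311, 0.308219117, -0.946327891}};
  for (int ip = 0; ip < np; ++ip) {
    V3 p = row3(P, ip);
    bool decided = false, inside = false;
    for (int attempt = 0; attempt < 4 && !decided; ++attempt) {
      V3 d = v3(dirs[attempt][0], dirs[attempt][1], dirs[attempt][2]);
      int crossings = 0;
      bool degenerate = false, on_surface = false;
      for (int f = 0; f < nf; ++f) {
        double t, u, v;
        V3 a = row3(V, F(f, 0) - 1), b = row3(V, F(f, 1) - 1), c = row3(V, F(f, 2) - 1);
        if (!ray_tri(p, d, a, b, c, t, u, v)) continue;
        if (std::fabs(t) <= band) { on_surface = true; break; }
        if (t > 0.0) {
          double w = 1.0 - u - v;
          if (u < 1e-10 || v < 1e-10 || w < 1e-10) { degenerate = true; break; }
          ++crossings;
        }
      }
      if (on_surface) { inside = true; decided = true; break; }
      if (!degenerate) { inside = (crossings % 2) == 1; decided = true; }
    }
    if (!decided) {
      // winding-number fallback
      double s = 0.0;
      for (int f = 0; f < nf; ++f)
        s += solid_angle(p, row3(V, F(f, 0) - 1), row3(V, F(f, 1) - 1), row3(V, F(f, 2) - 1));
      inside = (s / (4.0 * M_PI)) > 0.5;
      if (!inside) {
        // near-surface band check only when ambiguous
        double best = R_PosInf;
        for (int f = 0; f < nf; ++f) {
          double d2 = point_tri_d2(p, row3(V, F(f, 0) - 1), row3(V, F(f, 1) - 1), row3(V, F(f, 2) - 1));
          if (d2 < best) best = d2;
        }
        if (std::sqrt(best) <= band) inside = true;
      }
    }
    out[ip] = inside;
  }
  return out;
}

// All ray-surface intersection parameters t (sorted) for each origin, with a
// single shared direction. Used for sweep constructions.
// [[Rcpp::export(name = "cpp_ray_all_hits")]]
List cpp_ray_all_hits(NumericMatrix V, IntegerMatrix F, NumericMatrix O, NumericVector dir) {
  int nf = F.nrow(), no = O.nrow();
  V3 d = v3(dir[0], dir[1], dir[2]);
  List out(no);
  for (int io = 0; io < no; ++io) {
    V3 o = row3(O, io);
    std::vector<double> ts;
    for (int f = 0; f < nf; ++f) {
      double t, u, v;
      if (ray_tri(o, d, row3(V, F(f, 0) - 1), row3(V, F(f, 1) - 1), row3(V, F(f, 2) - 1), t, u, v))
        ts.push_back(t);
    }
    std::sort(ts.begin(), ts.end());
    // merge hits duplicated on shared edges
    std::vector<double> uniq;
    for (double t : ts) {
      if (uniq.empty() || t - uniq.back() > 1e-9) uniq.push_back(t);
    }
    out[io] = NumericVector(uniq.begin(), uniq.end());
  }
  return out;
}

// First hit distance along a per-point direction (t >= tmin), Inf if none.
// Used by the thin-feature guard of the inward offset.
// [[Rcpp::export(name = "cpp_first_hit_along")]]
NumericVector cpp_first_hit_along(NumericMatrix V, IntegerMatrix F, NumericMatrix O,
                                  NumericMatrix D, double tmin) {
  int nf = F.nrow(), no = O.nrow();
  NumericVector out(no, R_PosInf);
  for (int io = 0; io < no; ++io) {
    V3 o = row3(O, io), d = row3(D, io);
    double best = R_PosInf;
    for (int f = 0; f < nf; ++f) {
      double t, u, v;
      if (ray_tri(o, d, row3(V, F(f, 0) - 1), row3(V, F(f, 1) - 1), row3(V, F(f, 2) - 1), t, u, v))
        if (t >= tmin && t < best) best = t;
    }
    out[io] = best;
  }
  return out;
}

// Minimum distance between two vertex clouds via grid hashing.
// [[Rcpp::export(name = "cpp_min_point_dist")]]
double cpp_min_point_dist(NumericMatrix A, NumericMatrix B, double cell) {
  int na = A.nrow(), nb = B.nrow();
  std::unordered_map<long long, std::vector<int>> grid;
  auto key = [&](int i, int j, int k) {
    return ((long long)(i + 1048576) << 42) | ((long long)(j + 1048576) << 21) | (long long)(k + 1048576);
  };
  for (int i = 0; i < nb; ++i) {
    int gx = (int)std::floor(B(i, 0) / cell), gy = (int)std::floor(B(i, 1) / cell),
        gz = (int)std::floor(B(i, 2) / cell);
    grid[key(gx, gy, gz)].push_back(i);
  }
  double best2 = R_PosInf;
  int ring = 1;
  while (!R_FINITE(best2) && ring < 64) {
    for (int i = 0; i < na; ++i) {
      int gx = (int)std::floor(A(i, 0) / cell), gy = (int)std::floor(A(i, 1) / cell),
          gz = (int)std::floor(A(i, 2) / cell);
      for (int dx = -ring; dx <= ring; ++dx)
        for (int dy = -ring; dy <= ring; ++dy)
          for (int dz = -ring; dz <= ring; ++dz) {
            auto it = grid.find(key(gx + dx, gy + dy, gz + dz));
            if (it == grid.end()) continue;
            for (int j : it->second) {
              double ddx = A(i, 0) - B(j, 0), ddy = A(i, 1) - B(j, 1), ddz = A(i, 2) - B(j, 2);
              double d2 = ddx * ddx + ddy * ddy + ddz * ddz;
              if (d2 < best2) best2 = d2;
            }
          }
    }
    ring *= 2;
  }
  if (!R_FINITE(best2)) {  // degenerate fallback: brute force
    for (int i = 0; i < na; ++i)
      for (int j = 0; j < nb; ++j) {
        double ddx = A(i, 0) - B(j, 0), ddy = A(i, 1) - B(j, 1), ddz = A(i, 2) - B(j, 2);
        double d2 = ddx * ddx + ddy * ddy + ddz * ddz;
        if (d2 < best2) best2 = d2;
      }
  }
  return std::sqrt(best2);
}

// Single-linkage clustering at a Euclidean cutoff == connected components of
// the <=cutoff proximity graph; grid-accelerated union-find.
// [[Rcpp::export(name = "cpp_cluster_points")]]
IntegerVector cpp_cluster_points(NumericMatrix P, double cutoff) {
  int n = P.nrow();
  std::vector<int> parent(n);
  for (int i = 0; i < n; ++i) parent[i] = i;
  std::function<int(int)> find = [&](int x) {
    while (parent[x] != x) { parent[x] = parent[parent[x]]; x = parent[x]; }
    return x;
  };
  auto unite = [&](int a, int b) {
    a = find(a); b = find(b);
    if (a != b) parent[b] = a;
  };
  double cell = cutoff;
  std::unordered_map<long long, std::vector<int>> grid;
  auto key = [&](int i, int j, int k) {
    return ((long long)(i + 1048576) << 42) | ((long long)(j + 1048576) << 21) | (long long)(k + 1048576);
  };
  for (int i = 0; i < n; ++i) {
    int gx = (int)std::floor(P(i, 0) / cell), gy = (int)std::floor(P(i, 1) / cell),
        gz = (int)std::floor(P(i, 2) / cell);
    grid[key(gx, gy, gz)].push_back(i);
  }
  double c2 = cutoff * cutoff;
  for (int i = 0; i < n; ++i) {
    int gx = (int)std::floor(P(i, 0) / cell), gy = (int)std::floor(P(i, 1) / cell),
        gz = (int)std::floor(P(i, 2) / cell);
    for (int dx = -1; dx <= 1; ++dx)
      for (int dy = -1; dy <= 1; ++dy)
        for (int dz = -1; dz <= 1; ++dz) {
          auto it = grid.find(key(gx + dx, gy + dy, gz + dz));
          if (it == grid.end()) continue;
          for (int j : it->second) {
            if (j <= i) continue;
            double ddx = P(i, 0) - P(j, 0), ddy = P(i, 1) - P(j, 1), ddz = P(i, 2) - P(j, 2);
            if (ddx * ddx + ddy * ddy + ddz * ddz <= c2) unite(i, j);
          }
        }
  }
  // compact labels, 1-based, in order of first appearance
  IntegerVector lab(n);
  std::unordered_map<int, int> remap;
  int next = 0;
  for (int i = 0; i < n; ++i) {
    int r = find(i);
    auto it = remap.find(r);
    if (it == remap.end()) { remap[r] = ++next; lab[i] = next; }
    else lab[i] = it->second;
  }
  return lab;
}
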