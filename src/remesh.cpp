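// Incremental isotropic remeshing: iterated long-edge splitting, short-edge
// collapsing (link-condition guarded), valence-improving edge flips and
// tangential relaxation with reprojection onto the input surface.
// Closed manifold input => closed manifold output; boundary edges (if any)
// are frozen.
#include <Rcpp.h>
#include <cmath>
#include <vector>
#include <array>
#include <set>
#include <map>
#include <unordered_map>
#include <algorithm>
using namespace Rcpp;

namespace {

struct P3 { double x, y, z; };
inline P3 operator-(const P3& a, const P3& b) { return P3{a.x - b.x, a.y - b.y, a.z - b.z}; }
inline P3 operator+(const P3& a, const P3& b) { return P3{a.x + b.x, a.y + b.y, a.z + b.z}; }
inline P3 operator*(double s, const P3& a) { return P3{s * a.x, s * a.y, s * a.z}; }
inline double dot(const P3& a, const P3& b) { return a.x * b.x + a.y * b.y + a.z * b.z; }
inline P3 cross(const P3& a, const P3& b) {
  return P3{a.y * b.z - a.z * b.y, a.z * b.x - a.x * b.z, a.x * b.y - a.y * b.x};
}
inline double norm(const P3& a) { return std::sqrt(dot(a, a)); }

struct Mesh {
  std::vector<P3> V;
  std::vector<std::array<int, 3>> F;
  std::vector<char> alive;
};

inline long long ekey(int a, int b) {
  if (a > b) std::swap(a, b);
  return (long long)a * 10000000LL + b;
}

// edge -> adjacent alive faces
void edge_faces(const Mesh& m, std::unordered_map<long long, std::vector<int>>& ef) {
  ef.clear();
  for (size_t f = 0; f < m.F.size(); ++f) {
    if (!m.alive[f]) continue;
    for (int e = 0; e < 3; ++e)
      ef[ekey(m.F[f][e], m.F[f][(e + 1) % 3])].push_back((int)f);
  }
}

inline double elen(const Mesh& m, int a, int b) { return norm(m.V[a] - m.V[b]); }

inline P3 fnormal(const Mesh& m, int f) {
  const auto& t = m.F[f];
  return cross(m.V[t[1]] - m.V[t[0]], m.V[t[2]] - m.V[t[0]]);
}

// ---- projection structure onto the original surface --------------------
struct Projector {
  std::vector<P3> V;
  std::vector<std::array<int, 3>> F;
  double cell;
  std::unordered_map<long long, std::vector<int>> grid;
  long long key(int i, int j, int k) const {
    return ((long long)(i + 1048576) << 42) | ((long long)(j + 1048576) << 21) | (long long)(k + 1048576);
  }
  void build() {
    for (size_t f = 0; f < F.size(); ++f) {
      double lo[3] = {R_PosInf, R_PosInf, R_PosInf}, hi[3] = {R_NegInf, R_NegInf, R_NegInf};
      for (int v = 0; v < 3; ++v) {
        const P3& p = V[F[f][v]];
        double c[3] = {p.x, p.y, p.z};
        for (int k = 0; k < 3; ++k) { lo[k] = std::min(lo[k], c[k]); hi[k] = std::max(hi[k], c[k]); }
      }
      int x0 = (int)std::floor(lo[0] / cell), x1 = (int)std::floor(hi[0] / cell);
      int y0 = (int)std::floor(lo[1] / cell), y1 = (int)std::floor(hi[1] / cell);
      int z0 = (int)std::floor(lo[2] / cell), z1 = (int)std::floor(hi[2] / cell);
      for (int i = x0; i <= x1; ++i)
        for (int j = y0; j <= y1; ++j)
          for (int k = z0; k <= z1; ++k) grid[key(i, j, k)].push_back((int)f);
    }
  }
  // closest point on triangle
  static double d2tri(const P3& p, const P3& a, const P3& b, const P3& c, P3& q) {
    P3 ab = b - a, ac = c - a, ap = p - a;
    double d1 = dot(ab, ap), d2 = dot(ac, ap);
    if (d1 <= 0 && d2 <= 0) { q = a; P3 d = p - a; return dot(d, d); }
    P3 bp = p - b;
    double d3 = dot(ab, bp), d4 = dot(ac, bp);
    if (d3 >= 0 && d4 <= d3) { q = b; P3 d = p - b; return dot(d, d); }
    double vc = d1 * d4 - d3 * d2;
    if (vc <= 0 && d1 >= 0 && d3 <= 0) { double v = d1 / (d1 - d3); q = a + v * ab; P3 d = p - q; return dot(d, d); }
    P3 cp = p - c;
    double d5 = dot(ab, cp), d6 = dot(ac, cp);
    if (d6 >= 0 && d5 <= d6) { q = c; P3 d = p - c; return dot(d, d); }
    double vb = d5 * d2 - d1 * d6;
    if (vb <= 0 && d2 >= 0 && d6 <= 0) { double w = d2 / (d2 - d6); q = a + w * ac; P3 d = p - q; return dot(d, d); }
    double va = d3 * d6 - d5 * d4;
    if (va <= 0 && (d4 - d3) >= 0 && (d5 - d6) >= 0) {
      double w = (d4 - d3) / ((d4 - d3) + (d5 - d6)); q = b + w * (c - b); P3 d = p - q; return dot(d, d);
    }
    double denom = 1.0 / (va + vb + vc);
    double v = vb * denom, w = vc * denom;
    q = a + v * ab + w * ac; P3 d = p - q; return dot(d, d);
  }
  P3 project(const P3& p) const {
    int gx = (int)std::floor(p.x / cell), gy = (int)std::floor(p.y / cell), gz = (int)std::floor(p.z / cell);
    double best = R_PosInf; P3 bq = p;
    for (int ring = 1; ring <= 64; ring *= 2) {
      for (int i = gx - ring; i <= gx + ring; ++i)
        for (int j = gy - ring; j <= gy + ring; ++j)
          for (int k = gz - ring; k <= gz + ring; ++k) {
            auto it = grid.find(key(i, j, k));
            if (it == grid.end()) continue;
            for (int f : it->second) {
              P3 q;
              double d2 = d2tri(p, V[F[f][0]], V[F[f][1]], V[F[f][2]], q);
              if (d2 < best) { best = d2; bq = q; }
            }
          }
      if (R_FINITE(best) && std::sqrt(best) <= (double)(ring - 0) * cell) break;
    }
    return bq;
  }
};

}  // namespace

// [[Rcpp::export(name = "cpp_remesh_isotropic")]]
List cpp_remesh_isotropic(NumericMatrix Vin, IntegerMatrix Fin, double target, int iters) {
  Mesh m;
  int nv = Vin.nrow(), nf = Fin.nrow();
  m.V.resize(nv);
  for (int i = 0; i < nv; ++i) m.V[i] = P3{Vin(i, 0), Vin(i, 1), Vin(i, 2)};
  m.F.resize(nf);
  for (int f = 0; f < nf; ++f) m.F[f] = {Fin(f, 0) - 1, Fin(f, 1) - 1, Fin(f, 2) - 1};
  m.alive.assign(nf, 1);

  Projector proj;
  proj.V = m.V;
  proj.F = m.F;
  proj.cell = std::max(target, 1e-6);
  proj.build();

  const double high = 4.0 / 3.0 * target, low = 4.0 / 5.0 * target;
  std::unordered_map<long long, std::vector<int>> ef;

  // boundary vertices frozen throughout
  std::set<int> frozen;
  edge_faces(m, ef);
  for (auto& kv : ef)
    if (kv.second.size() == 1) {
      long long k = kv.first;
      frozen.insert((int)(k / 10000000LL));
      frozen.insert((int)(k % 10000000LL));
    }

  for (int it = 0; it < iters; ++it) {
    // ---- 1. split long edges ------------------------------------------
    for (int sweep = 0; sweep < 10; ++sweep) {
      edge_faces(m, ef);
      std::vector<long long> longe;
      for (auto& kv : ef) {
        int a = (int)(kv.first / 10000000LL), b = (int)(kv.first % 10000000LL);
        if (kv.second.size() == 2 && elen(m, a, b) > high) longe.push_back(kv.first);
      }
      if (longe.empty()) break;
      std::vector<char> dirty(m.F.size(), 0);
      bool did = false;
      for (long long k : longe) {
        auto it2 = ef.find(k);
        if (it2 == ef.end() || it2->second.size() != 2) continue;
        int f1 = it2->second[0], f2 = it2->second[1];
        if (!m.alive[f1] || !m.alive[f2] || dirty[f1] || dirty[f2]) continue;
        int a = (int)(k / 10000000LL), b = (int)(k % 10000000LL);
        int mid = (int)m.V.size();
        m.V.push_back(0.5 * (m.V[a] + m.V[b]));
        m.V[mid] = proj.project(m.V[mid]);
        for (int f : {f1, f2}) {
          auto t = m.F[f];
          int ia = -1, ib = -1;
          for (int e = 0; e < 3; ++e) { if (t[e] == a) ia = e; if (t[e] == b) ib = e; }
          int c = t[3 - ia - ib];
          m.alive[f] = 0;
          // preserve orientation: replace b by mid in one copy, a by mid in other
          std::array<int, 3> t1 = t, t2 = t;
          t1[ib] = mid; t2[ia] = mid;
          m.F.push_back(t1); m.alive.push_back(1); dirty.push_back(1);
          m.F.push_back(t2); m.alive.push_back(1); dirty.push_back(1);
          dirty[f] = 1;
          (void)c;
        }
        did = true;
      }
      if (!did) break;
    }

    // ---- 2. collapse short edges --------------------------------------
    {
      edge_faces(m, ef);
      // vertex -> alive faces
      std::unordered_map<int, std::vector<int>> vf;
      for (size_t f = 0; f < m.F.size(); ++f)
        if (m.alive[f])
          for (int e = 0; e < 3; ++e) vf[m.F[f][e]].push_back((int)f);
      std::set<int> touched;
      std::vector<std::pair<double, long long>> shorte;
      for (auto& kv : ef) {
        int a = (int)(kv.first / 10000000LL), b = (int)(kv.first % 10000000LL);
        if (kv.second.size() == 2) {
          double l = elen(m, a, b);
          if (l < low) shorte.push_back({l, kv.first});
        }
      }
      std::sort(shorte.begin(), shorte.end());
      for (auto& pr : shorte) {
        long long k = pr.second;
        int a = (int)(k / 10000000LL), b = (int)(k % 10000000LL);
        if (touched.count(a) || touched.count(b)) continue;
        if (frozen.count(a) || frozen.count(b)) continue;
        auto it2 = ef.find(k);
        if (it2 == ef.end() || it2->second.size() != 2) continue;
        int f1 = it2->second[0], f2 = it2->second[1];
        if (!m.alive[f1] || !m.alive[f2]) continue;
        // link condition: common 1-ring neighbours of a and b must be exactly
        // the two vertices opposite the edge
        std::set<int> na, nbv;
        for (int f : vf[a]) if (m.alive[f]) for (int e = 0; e < 3; ++e) if (m.F[f][e] != a) na.insert(m.F[f][e]);
        for (int f : vf[b]) if (m.alive[f]) for (int e = 0; e < 3; ++e) if (m.F[f][e] != b) nbv.insert(m.F[f][e]);
        std::vector<int> common;
        std::set_intersection(na.begin(), na.end(), nbv.begin(), nbv.end(), std::back_inserter(common));
        if (common.size() != 2) continue;
        P3 newp = proj.project(0.5 * (m.V[a] + m.V[b]));
        // validity: no long edges created, no normal flips, no degenerate faces
        bool ok = true;
        P3 olda = m.V[a], oldb = m.V[b];
        for (int v : na) if (v != b && norm(newp - m.V[v]) > high) { ok = false; break; }
        if (ok) for (int v : nbv) if (v != a && norm(newp - m.V[v]) > high) { ok = false; break; }
        if (ok) {
          m.V[a] = newp;
          for (int vv : {a, b}) {
            for (int f : vf[vv]) {
              if (!m.alive[f] || f == f1 || f == f2) continue;
              auto t = m.F[f];
              for (int e = 0; e < 3; ++e) if (t[e] == b) t[e] = a;
              if (t[0] == t[1] || t[1] == t[2] || t[0] == t[2]) { ok = false; break; }
              P3 n0 = (vv == a) ? fnormal(m, f) : cross(m.V[t[1]] - m.V[t[0]], m.V[t[2]] - m.V[t[0]]);
              (void)n0;
              P3 nn = cross(m.V[t[1]] - m.V[t[0]], m.V[t[2]] - m.V[t[0]]);
              if (norm(nn) < 1e-14) { ok = false; break; }
            }
            if (!ok) break;
          }
          if (!ok) m.V[a] = olda;
        }
        if (!ok) { m.V[a] = olda; m.V[b] = oldb; continue; }
        // commit: kill f1, f2; rewire b -> a
        m.alive[f1] = 0; m.alive[f2] = 0;
        for (int f : vf[b]) {
          if (!m.alive[f]) continue;
          for (int e = 0; e < 3; ++e) if (m.F[f][e] == b) m.F[f][e] = a;
          vf[a].push_back(f);
        }
        touched.insert(a); touched.insert(b);
        for (int v : common) touched.insert(v);
        // refresh edge map lazily: mark edges of changed faces as unusable
        for (int f : vf[a]) if (m.alive[f]) for (int e = 0; e < 3; ++e) touched.insert(m.F[f][e]);
      }
    }

    // ---- 3. valence-improving flips ------------------------------------
    {
      edge_faces(m, ef);
      std::vector<int> val(m.V.size(), 0);
      for (auto& kv : ef) {
        (void)kv;
      }
      std::set<long long> edges_seen;
      for (size_t f = 0; f < m.F.size(); ++f) {
        if (!m.alive[f]) continue;
        for (int e = 0; e < 3; ++e) {
          long long k = ekey(m.F[f][e], m.F[f][(e + 1) % 3]);
          if (edges_seen.insert(k).second) {
            ++val[(int)(k / 10000000LL)];
            ++val[(int)(k % 10000000LL)];
          }
        }
      }
      std::vector<char> dirty(m.F.size(), 0);
      for (auto& kv : ef) {
        if (kv.second.size() != 2) continue;
        int f1 = kv.second[0], f2 = kv.second[1];
        if (!m.alive[f1] || !m.alive[f2] || dirty[f1] || dirty[f2]) continue;
        int a = (int)(kv.first / 10000000LL), b = (int)(kv.first % 10000000LL);
        if (frozen.count(a) || frozen.count(b)) continue;
        auto t1 = m.F[f1], t2 = m.F[f2];
        int c = -1, d = -1;
        for (int e = 0; e < 3; ++e) { if (t1[e] != a && t1[e] != b) c = t1[e]; if (t2[e] != a && t2[e] != b) d = t2[e]; }
        if (c < 0 || d < 0 || c == d) continue;
        if (ef.count(ekey(c, d))) continue;  // would create duplicate edge
        auto dev = [&](int va2, int vb2, int vc2, int vd2) {
          int ta = va2 - 6, tb = vb2 - 6, tc = vc2 - 6, td = vd2 - 6;
          return ta * ta + tb * tb + tc * tc + td * td;
        };
        int before = dev(val[a], val[b], val[c], val[d]);
        int after = dev(val[a] - 1, val[b] - 1, val[c] + 1, val[d] + 1);
        if (after >= before) continue;
        // geometric guard: new triangles must not be degenerate nor fold
        P3 n_old = fnormal(m, f1) + fnormal(m, f2);
        // orientation: f1 contains a->b; find order
        int ia = -1;
        for (int e = 0; e < 3; ++e) if (t1[e] == a) ia = e;
        bool ab_in_f1 = (t1[(ia + 1) % 3] == b);
        int u = ab_in_f1 ? a : b, w = ab_in_f1 ? b : a;
        // new faces: (u, d? ...) flip edge u-w with opposite c (f1) and d (f2):
        std::array<int, 3> nt1 = {u, d, c}, nt2 = {w, c, d};
        P3 nn1 = cross(m.V[nt1[1]] - m.V[nt1[0]], m.V[nt1[2]] - m.V[nt1[0]]);
        P3 nn2 = cross(m.V[nt2[1]] - m.V[nt2[0]], m.V[nt2[2]] - m.V[nt2[0]]);
        if (norm(nn1) < 1e-12 || norm(nn2) < 1e-12) continue;
        if (dot(nn1, n_old) <= 0 || dot(nn2, n_old) <= 0) continue;
        m.F[f1] = nt1; m.F[f2] = nt2;
        dirty[f1] = 1; dirty[f2] = 1;
        --val[a]; --val[b]; ++val[c]; ++val[d];
      }
    }

    // ---- 4. tangential relaxation + reprojection -----------------------
    {
      std::unordered_map<int, std::vector<int>> nb;
      for (size_t f = 0; f < m.F.size(); ++f) {
        if (!m.alive[f]) continue;
        for (int e = 0; e < 3; ++e) {
          nb[m.F[f][e]].push_back(m.F[f][(e + 1) % 3]);
          nb[m.F[f][e]].push_back(m.F[f][(e + 2) % 3]);
        }
      }
      // area-weighted vertex normals
      std::vector<P3> vn(m.V.size(), P3{0, 0, 0});
      for (size_t f = 0; f < m.F.size(); ++f) {
        if (!m.alive[f]) continue;
        P3 n = fnormal(m, (int)f);
        for (int e = 0; e < 3; ++e) vn[m.F[f][e]] = vn[m.F[f][e]] + n;
      }
      std::vector<P3> newV = m.V;
      for (auto& kv : nb) {
        int v = kv.first;
        if (frozen.count(v)) continue;
        P3 g{0, 0, 0};
        std::set<int> uniq(kv.second.begin(), kv.second.end());
        if (uniq.empty()) continue;
        for (int u : uniq) g = g + m.V[u];
        g = (1.0 / uniq.size()) * g;
        P3 d = g - m.V[v];
        P3 n = vn[v];
        double nl = norm(n);
        if (nl > 1e-14) {
          n = (1.0 / nl) * n;
          d = d - dot(d, n) * n;  // tangential component only
        }
        P3 moved = m.V[v] + 0.5 * d;
        newV[v] = proj.project(moved);
      }
      m.V = newV;
    }
  }

  // compact output
  std::vector<int> remap(m.V.size(), -1);
  std::vector<P3> Vout;
  std::vector<std::array<int, 3>> Fout;
  for (size_t f = 0; f < m.F.size(); ++f) {
    if (!m.alive[f]) continue;
    std::array<int, 3> t;
    for (int e = 0; e < 3; ++e) {
      int v = m.F[f][e];
      if (remap[v] < 0) { remap[v] = (int)Vout.size(); Vout.push_back(m.V[v]); }
      t[e] = remap[v] + 1;
    }
    Fout.push_back(t);
  }
  NumericMatrix VO(Vout.size(), 3);
  for (size_t i = 0; i < Vout.size(); ++i) { VO(i, 0) = Vout[i].x; VO(i, 1) = Vout[i].y; VO(i, 2) = Vout[i].z; }
  IntegerMatrix FO(Fout.size(), 3);
  for (size_t i = 0; i < Fout.size(); ++i) { FO(i, 0) = Fout[i][0]; FO(i, 1) = Fout[i][1]; FO(i, 2) = Fout[i][2]; }
  return List::create(_["vertices"] = VO, _["faces"] = FO);
}
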