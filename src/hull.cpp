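// Exact low-dimensional convex hull geometry for functional diversity.
//
// Functional richness is the volume of the convex hull of a community's
// taxa in the first m ordination axes (m <= 3), and functional beta
// diversity needs the exact volume of the intersection of two such hulls.
// Point sets are small (tens of taxa), so facets are found by brute-force
// plane enumeration with early rejection, coplanar triples are merged into
// polygonal faces, and the intersection polytope's vertices are collected
// by clipping each hull's edges against the other's half-space
// representation.

#include <Rcpp.h>
#include <vector>
#include <cmath>
#include <algorithm>
#include <utility>

using namespace Rcpp;

namespace {

struct V3 {
  double x, y, z;
};

inline V3 v3(double x, double y, double z) { V3 v; v.x = x; v.y = y; v.z = z; return v; }
inline V3 operator-(const V3& a, const V3& b) { return v3(a.x - b.x, a.y - b.y, a.z - b.z); }
inline V3 operator+(const V3& a, const V3& b) { return v3(a.x + b.x, a.y + b.y, a.z + b.z); }
inline V3 operator*(const V3& a, double s) { return v3(a.x * s, a.y * s, a.z * s); }
inline double dot(const V3& a, const V3& b) { return a.x * b.x + a.y * b.y + a.z * b.z; }
inline V3 cross(const V3& a, const V3& b) {
  return v3(a.y * b.z - a.z * b.y, a.z * b.x - a.x * b.z, a.x * b.y - a.y * b.x);
}
inline double norm(const V3& a) { return std::sqrt(dot(a, a)); }

struct Face {
  V3 n;                    // outward unit normal; interior satisfies dot(n, x) <= d
  double d;
  std::vector<int> poly;   // vertex indices in boundary order
  double area;
};

struct Hull3 {
  std::vector<Face> faces;
  std::vector<std::pair<int, int> > edges;  // unique vertex-index pairs (i < j)
  double volume;
  double tol;
  bool degenerate;
};

inline V3 row(const NumericMatrix& X, int i) { return v3(X(i, 0), X(i, 1), X(i, 2)); }

// 2D monotone-chain hull on points given as (u, v) with original indices.
// Returns boundary indices in counter-clockwise order; collinear interior
// points are dropped.
std::vector<int> chain2(const std::vector<double>& u, const std::vector<double>& v,
                        const std::vector<int>& idx, double tol2) {
  const int n = (int)idx.size();
  std::vector<int> ord(n);
  for (int i = 0; i < n; ++i) ord[i] = i;
  std::sort(ord.begin(), ord.end(), [&](int a, int b) {
    if (u[a] != u[b]) return u[a] < u[b];
    return v[a] < v[b];
  });
  std::vector<int> h(2 * n);
  int k = 0;
  for (int ii = 0; ii < n; ++ii) {
    int i = ord[ii];
    while (k >= 2) {
      int a = h[k - 2], b = h[k - 1];
      double cr = (u[b] - u[a]) * (v[i] - v[a]) - (v[b] - v[a]) * (u[i] - u[a]);
      if (cr <= tol2) --k; else break;
    }
    h[k++] = i;
  }
  int lower = k + 1;
  for (int ii = n - 2; ii >= 0; --ii) {
    int i = ord[ii];
    while (k >= lower) {
      int a = h[k - 2], b = h[k - 1];
      double cr = (u[b] - u[a]) * (v[i] - v[a]) - (v[b] - v[a]) * (u[i] - u[a]);
      if (cr <= tol2) --k; else break;
    }
    h[k++] = i;
  }
  std::vector<int> out;
  out.reserve(k - 1);
  for (int i = 0; i < k - 1; ++i) out.push_back(idx[h[i]]);
  return out;
}

double coordScale(const NumericMatrix& X) {
  double s = 0.0;
  for (int i = 0; i < X.nrow(); ++i)
    for (int j = 0; j < X.ncol(); ++j)
      s = std::max(s, std::fabs(X(i, j)));
  return s > 0 ? s : 1.0;
}

Hull3 buildHull3(const NumericMatrix& X) {
  Hull3 H;
  const int n = X.nrow();
  const double scale = coordScale(X);
  const double tol = 3e-8 * scale;
  H.tol = tol;
  H.degenerate = true;
  H.volume = 0.0;
  if (n < 4) return H;

  // facet planes: triples whose plane supports the whole set
  for (int i = 0; i < n - 2; ++i) {
    V3 a = row(X, i);
    for (int j = i + 1; j < n - 1; ++j) {
      V3 b = row(X, j);
      for (int k = j + 1; k < n; ++k) {
        V3 c = row(X, k);
        V3 nr = cross(b - a, c - a);
        double nn = norm(nr);
        // skip sliver triples: their normals are too inaccurate to dedupe
        // reliably, and every true facet also contains a fat triple
        if (nn < 1e-7 * scale * scale) continue;
        nr = nr * (1.0 / nn);
        double d = dot(nr, a);
        bool pos = false, neg = false;
        for (int p = 0; p < n; ++p) {
          double s = dot(nr, row(X, p)) - d;
          if (s > tol) pos = true; else if (s < -tol) neg = true;
          if (pos && neg) break;
        }
        if (pos && neg) continue;
        V3 on = nr;
        double od = d;
        if (pos) { on = nr * (-1.0); od = -d; }  // flip outward
        bool dup = false;
        for (size_t f = 0; f < H.faces.size(); ++f) {
          if (dot(H.faces[f].n, on) > 1.0 - 1e-8 &&
              std::fabs(H.faces[f].d - od) < 1e-6 * scale) {
            dup = true; break;
          }
        }
        if (dup) continue;
        Face f;
        f.n = on;
        f.d = od;
        H.faces.push_back(f);
      }
    }
  }
  if (H.faces.size() < 4) return H;  // flat or lower-dimensional point set

  // polygonal boundary of each face, its area, and the hull edge set
  std::vector<std::pair<int, int> > eset;
  for (size_t f = 0; f < H.faces.size(); ++f) {
    Face& F = H.faces[f];
    std::vector<int> on;
    for (int p = 0; p < n; ++p)
      if (std::fabs(dot(F.n, row(X, p)) - F.d) <= 4 * tol) on.push_back(p);
    if ((int)on.size() < 3) { F.area = 0.0; continue; }
    // orthonormal basis in the face plane
    V3 ref = std::fabs(F.n.x) < 0.9 ? v3(1, 0, 0) : v3(0, 1, 0);
    V3 u = cross(F.n, ref);
    u = u * (1.0 / norm(u));
    V3 v = cross(F.n, u);
    std::vector<double> uu(on.size()), vv(on.size());
    for (size_t q = 0; q < on.size(); ++q) {
      V3 p = row(X, on[q]);
      uu[q] = dot(p, u);
      vv[q] = dot(p, v);
    }
    F.poly = chain2(uu, vv, on, 1e-14 * scale * scale);
    double area = 0.0;
    for (size_t q = 0; q < F.poly.size(); ++q) {
      size_t r = (q + 1) % F.poly.size();
      V3 p1 = row(X, F.poly[q]), p2 = row(X, F.poly[r]);
      area += dot(F.n, cross(p1, p2));
    }
    F.area = std::fabs(area) / 2.0;
    for (size_t q = 0; q < F.poly.size(); ++q) {
      size_t r = (q + 1) % F.poly.size();
      int a2 = F.poly[q], b2 = F.poly[r];
      if (a2 > b2) std::swap(a2, b2);
      eset.push_back(std::make_pair(a2, b2));
    }
  }
  std::sort(eset.begin(), eset.end());
  eset.erase(std::unique(eset.begin(), eset.end()), eset.end());
  H.edges = eset;

  // volume: cones from the centroid over each face
  V3 C = v3(0, 0, 0);
  for (int p = 0; p < n; ++p) C = C + row(X, p);
  C = C * (1.0 / n);
  double vol = 0.0;
  for (size_t f = 0; f < H.faces.size(); ++f) {
    const Face& F = H.faces[f];
    vol += F.area * (F.d - dot(F.n, C)) / 3.0;
  }
  H.volume = vol;
  H.degenerate = !(vol > tol * scale * scale);
  return H;
}

// clip segment [p, q] to the interior of a hull's half-spaces; append the
// surviving endpoints to `out`
void clipSegment(const V3& p, const V3& q, const Hull3& H, std::vector<V3>& out) {
  double t0 = 0.0, t1 = 1.0;
  const double tol = H.tol;
  for (size_t f = 0; f < H.faces.size(); ++f) {
    const Face& F = H.faces[f];
    double fp = dot(F.n, p) - F.d;
    double fq = dot(F.n, q) - F.d;
    double dv = fq - fp;
    if (std::fabs(dv) < 1e-300) {
      if (fp > tol) return;  // parallel and outside
      continue;
    }
    double t = -fp / dv;  // f(p) + t*dv <= 0: clip exactly at the plane
    if (dv > 0) { if (t < t1) t1 = t; }
    else        { if (t > t0) t0 = t; }
    if (t0 > t1 + 1e-12) return;
  }
  out.push_back(p + (q - p) * t0);
  out.push_back(p + (q - p) * t1);
}

// volume of the intersection polytope from its known half-space planes and
// its (possibly noisy) candidate vertex list: per plane, the in-plane 2D
// hull of incident vertices gives the face area, coned from the vertex
// centroid. Avoids re-deriving planes from clipped points, whose noise can
// defeat facet detection.
double volumeFromHrep(const std::vector<Face>& planes, const std::vector<V3>& pts,
                      double scale) {
  if (pts.size() < 4) return 0.0;
  const double ptol = 1e-6 * scale;
  V3 c = v3(0, 0, 0);
  for (size_t i = 0; i < pts.size(); ++i) c = c + pts[i];
  c = c * (1.0 / (double)pts.size());
  double vol = 0.0;
  for (size_t f = 0; f < planes.size(); ++f) {
    const Face& F = planes[f];
    std::vector<double> uu, vv;
    std::vector<int> idx;
    V3 ref = std::fabs(F.n.x) < 0.9 ? v3(1, 0, 0) : v3(0, 1, 0);
    V3 u = cross(F.n, ref);
    u = u * (1.0 / norm(u));
    V3 v = cross(F.n, u);
    for (size_t i = 0; i < pts.size(); ++i) {
      if (std::fabs(dot(F.n, pts[i]) - F.d) <= ptol) {
        uu.push_back(dot(pts[i], u));
        vv.push_back(dot(pts[i], v));
        idx.push_back((int)idx.size());
      }
    }
    if (idx.size() < 3) continue;
    std::vector<int> poly = chain2(uu, vv, idx, 1e-14 * scale * scale);
    if ((int)poly.size() < 3) continue;
    double area = 0.0;
    for (size_t q = 0; q < poly.size(); ++q) {
      size_t r = (q + 1) % poly.size();
      area += uu[poly[q]] * vv[poly[r]] - uu[poly[r]] * vv[poly[q]];
    }
    area = std::fabs(area) / 2.0;
    double h = F.d - dot(F.n, c);
    if (h > 0) vol += area * h / 3.0;
  }
  return vol;
}

double area2(const NumericMatrix& X) {
  const int n = X.nrow();
  if (n < 3) return 0.0;
  const double scale = coordScale(X);
  std::vector<double> u(n), v(n);
  std::vector<int> idx(n);
  for (int i = 0; i < n; ++i) { u[i] = X(i, 0); v[i] = X(i, 1); idx[i] = i; }
  std::vector<int> poly = chain2(u, v, idx, 1e-14 * scale * scale);
  if ((int)poly.size() < 3) return 0.0;
  double a = 0.0;
  for (size_t q = 0; q < poly.size(); ++q) {
    size_t r = (q + 1) % poly.size();
    a += u[poly[q]] * v[poly[r]] - u[poly[r]] * v[poly[q]];
  }
  return std::fabs(a) / 2.0;
}

}  // namespace

//' @noRd
// [[Rcpp::export(name = ".hull3_volume_cpp")]]
List hull3_volume_cpp(NumericMatrix X) {
  Hull3 H = buildHull3(X);
  return List::create(_["volume"] = H.volume, _["degenerate"] = H.degenerate,
                      _["n_faces"] = (int)H.faces.size());
}

//' @noRd
// [[Rcpp::export(name = ".hull2_area_cpp")]]
double hull2_area_cpp(NumericMatrix X) {
  return area2(X);
}

//' @noRd
// [[Rcpp::export(name = ".hull3_pair_cpp")]]
List hull3_pair_cpp(NumericMatrix A, NumericMatrix B) {
  Hull3 HA = buildHull3(A);
  Hull3 HB = buildHull3(B);
  if (HA.degenerate || HB.degenerate) {
    return List::create(_["va"] = HA.degenerate ? NA_REAL : HA.volume,
                        _["vb"] = HB.degenerate ? NA_REAL : HB.volume,
                        _["vshared"] = NA_REAL, _["degenerate"] = true);
  }
  std::vector<V3> pts;
  for (size_t e = 0; e < HA.edges.size(); ++e)
    clipSegment(row(A, HA.edges[e].first), row(A, HA.edges[e].second), HB, pts);
  for (size_t e = 0; e < HB.edges.size(); ++e)
    clipSegment(row(B, HB.edges[e].first), row(B, HB.edges[e].second), HA, pts);
  // drop near-duplicate vertices (each polytope vertex is collected once
  // per incident clipped edge) so the final hull stays small
  double dtol = 10.0 * std::max(HA.tol, HB.tol);
  std::vector<V3> uniq;
  for (size_t i = 0; i < pts.size(); ++i) {
    bool seen = false;
    for (size_t j = 0; j < uniq.size(); ++j) {
      V3 d = pts[i] - uniq[j];
      if (std::fabs(d.x) < dtol && std::fabs(d.y) < dtol && std::fabs(d.z) < dtol) {
        seen = true; break;
      }
    }
    if (!seen) uniq.push_back(pts[i]);
  }
  pts.swap(uniq);
  double vs = 0.0;
  if (pts.size() >= 4) {
    // combined, deduplicated half-space representation of the intersection
    std::vector<Face> planes = HA.faces;
    double scale = std::max(coordScale(A), coordScale(B));
    for (size_t f = 0; f < HB.faces.size(); ++f) {
      bool dup = false;
      for (size_t g = 0; g < planes.size(); ++g) {
        if (dot(planes[g].n, HB.faces[f].n) > 1.0 - 1e-8 &&
            std::fabs(planes[g].d - HB.faces[f].d) < 1e-6 * scale) {
          dup = true; break;
        }
      }
      if (!dup) planes.push_back(HB.faces[f]);
    }
    vs = volumeFromHrep(planes, pts, scale);
  }
  // guard against tolerance overshoot
  vs = std::min(vs, std::min(HA.volume, HB.volume));
  return List::create(_["va"] = HA.volume, _["vb"] = HB.volume,
                      _["vshared"] = vs, _["degenerate"] = false);
}

//' @noRd
// [[Rcpp::export(name = ".in_hull_fw_cpp")]]
LogicalVector in_hull_fw_cpp(NumericMatrix P, NumericMatrix X, double tol = 1e-6) {
  // Frank-Wolfe projection onto conv(X): entirely independent of the
  // facet-based hull construction above; used as a Monte-Carlo membership
  // oracle in the test-suite.
  const int k = P.nrow(), n = X.nrow();
  LogicalVector out(k);
  double scale = coordScale(X);
  double atol2 = tol * tol * scale * scale;
  std::vector<double> w(n);
  for (int s = 0; s < k; ++s) {
    V3 p = row(P, s);
    std::fill(w.begin(), w.end(), 0.0);
    w[0] = 1.0;
    V3 x = row(X, 0);
    bool inside = false, outside = false;
    // pairwise Frank-Wolfe projection of p onto conv(X). Certificates:
    // inside when dist^2 < atol2; outside when f - gap > 0, since the FW
    // gap bounds suboptimality (f - f* <= gap), so f* > 0 is certified --
    // and for interior points f - gap <= f* = 0 can never fire.
    for (int it = 0; it < 20000; ++it) {
      V3 r = x - p;
      double f = dot(r, r);
      if (f < atol2) { inside = true; break; }
      int fw = 0, aw = -1;
      double bfw = dot(r, row(X, 0)), baw = -1e300;
      for (int i = 0; i < n; ++i) {
        double v = dot(r, row(X, i));
        if (v < bfw) { bfw = v; fw = i; }
        if (w[i] > 0 && v > baw) { baw = v; aw = i; }
      }
      double gap = 2.0 * (dot(r, x) - bfw);
      if (f - gap > 0) { outside = true; break; }
      if (aw < 0 || aw == fw) break;
      V3 d = row(X, fw) - row(X, aw);
      double dd = dot(d, d);
      if (dd <= 0) break;
      double t = -dot(r, d) / dd;
      if (t <= 0) break;
      if (t > w[aw]) t = w[aw];
      w[fw] += t;
      w[aw] -= t;
      x = x + d * t;
    }
    // uncertified exit (stall or iteration cap): classify by distance at a
    // loose tolerance; only boundary-grazing points land here
    if (!inside && !outside) inside = dot(x - p, x - p) < 1e-6 * scale * scale;
    out[s] = inside;
  }
  return out;
}

//' @noRd
// [[Rcpp::export(name = ".hull2_pair_cpp")]]
List hull2_pair_cpp(NumericMatrix A, NumericMatrix B) {
  // lift to z = 0 and z = 1 prisms would be overkill: clip in 2D directly
  // via the 3D machinery by embedding each polygon as a flat slab of unit
  // thickness, so the shared "volume" equals the shared area.
  int na = A.nrow(), nb = B.nrow();
  NumericMatrix A3(2 * na, 3), B3(2 * nb, 3);
  for (int i = 0; i < na; ++i) {
    A3(i, 0) = A(i, 0); A3(i, 1) = A(i, 1); A3(i, 2) = 0.0;
    A3(na + i, 0) = A(i, 0); A3(na + i, 1) = A(i, 1); A3(na + i, 2) = 1.0;
  }
  for (int i = 0; i < nb; ++i) {
    B3(i, 0) = B(i, 0); B3(i, 1) = B(i, 1); B3(i, 2) = 0.0;
    B3(nb + i, 0) = B(i, 0); B3(nb + i, 1) = B(i, 1); B3(nb + i, 2) = 1.0;
  }
  List r = hull3_pair_cpp(A3, B3);
  return r;  // va/vb/vshared are the polygon areas
}
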