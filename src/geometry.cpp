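#include <Rcpp.h>
#include <vector>
#include <map>
#include <cmath>
#include <utility>
using namespace Rcpp;

static const double BIG = 1e20;

// ---------------------------------------------------------------------------
// Squared Euclidean distance transform with per-axis sample spacing.
// Separable lower-envelope-of-parabolas algorithm; samples along an axis sit
// at physical coordinates i * s (voxel centers).
// ---------------------------------------------------------------------------

static void dt1d(const double* f, double* d, int n, double s,
                 int* v, double* z) {
  if (n == 1) { d[0] = f[0]; return; }
  int k = 0;
  v[0] = 0;
  z[0] = -BIG; z[1] = BIG;
  for (int q = 1; q < n; q++) {
    double xq = q * s;
    for (;;) {
      double xv = v[k] * s;
      double sec = ((f[q] + xq * xq) - (f[v[k]] + xv * xv)) /
                   (2.0 * (xq - xv));
      if (sec <= z[k]) {
        k--;
      } else {
        k++;
        v[k] = q;
        z[k] = sec;
        z[k + 1] = BIG;
        break;
      }
    }
  }
  k = 0;
  for (int q = 0; q < n; q++) {
    double xq = q * s;
    while (z[k + 1] < xq) k++;
    double xv = v[k] * s;
    d[q] = (xq - xv) * (xq - xv) + f[v[k]];
  }
}

// [[Rcpp::export]]
NumericVector cpp_sq_edt(LogicalVector mask, IntegerVector dims,
                         NumericVector spacing) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  const R_xlen_t n = (R_xlen_t)nx * ny * nz;
  NumericVector d2(n);
  for (R_xlen_t i = 0; i < n; i++) d2[i] = mask[i] ? 0.0 : BIG;

  int nmax = std::max(nx, std::max(ny, nz));
  std::vector<double> f(nmax), d(nmax), z(nmax + 1);
  std::vector<int> v(nmax);

  // axis 1 (fastest-varying)
  for (int k = 0; k < nz; k++)
    for (int j = 0; j < ny; j++) {
      R_xlen_t base = (R_xlen_t)k * nx * ny + (R_xlen_t)j * nx;
      for (int i = 0; i < nx; i++) f[i] = d2[base + i];
      dt1d(f.data(), d.data(), nx, spacing[0], v.data(), z.data());
      for (int i = 0; i < nx; i++) d2[base + i] = d[i];
    }
  // axis 2
  for (int k = 0; k < nz; k++)
    for (int i = 0; i < nx; i++) {
      R_xlen_t base = (R_xlen_t)k * nx * ny + i;
      for (int j = 0; j < ny; j++) f[j] = d2[base + (R_xlen_t)j * nx];
      dt1d(f.data(), d.data(), ny, spacing[1], v.data(), z.data());
      for (int j = 0; j < ny; j++) d2[base + (R_xlen_t)j * nx] = d[j];
    }
  // axis 3
  for (int j = 0; j < ny; j++)
    for (int i = 0; i < nx; i++) {
      R_xlen_t base = (R_xlen_t)j * nx + i;
      for (int k = 0; k < nz; k++)
        f[k] = d2[base + (R_xlen_t)k * nx * ny];
      dt1d(f.data(), d.data(), nz, spacing[2], v.data(), z.data());
      for (int k = 0; k < nz; k++)
        d2[base + (R_xlen_t)k * nx * ny] = d[k];
    }
  return d2;
}

// ---------------------------------------------------------------------------
// Quickhull in 3D. Emits the hull's half-space representation: rows of
// (nx, ny, nz, off) with unit normals; x interior  <=>  n . x <= off (+tol).
// Rank-deficient inputs are reported back (rank slot) and handled in R.
// ---------------------------------------------------------------------------

struct Face {
  int a, b, c;
  double n[3], off;
  bool alive;
  std::vector<int> out;
  int far_idx;
  double far_d;
};

static inline void vsub(const double* p, const double* q, double* r) {
  r[0] = p[0] - q[0]; r[1] = p[1] - q[1]; r[2] = p[2] - q[2];
}
static inline void vcross(const double* u, const double* v, double* r) {
  r[0] = u[1] * v[2] - u[2] * v[1];
  r[1] = u[2] * v[0] - u[0] * v[2];
  r[2] = u[0] * v[1] - u[1] * v[0];
}
static inline double vdot(const double* u, const double* v) {
  return u[0] * v[0] + u[1] * v[1] + u[2] * v[2];
}

static bool face_plane(const NumericMatrix& P, Face& F, const double* inner) {
  double u[3], v[3], n[3];
  double A[3] = { P(F.a, 0), P(F.a, 1), P(F.a, 2) };
  double Bp[3] = { P(F.b, 0), P(F.b, 1), P(F.b, 2) };
  double C[3] = { P(F.c, 0), P(F.c, 1), P(F.c, 2) };
  vsub(Bp, A, u); vsub(C, A, v); vcross(u, v, n);
  double nn = std::sqrt(vdot(n, n));
  if (nn < 1e-300) return false;
  n[0] /= nn; n[1] /= nn; n[2] /= nn;
  double off = vdot(n, A);
  if (vdot(n, inner) > off) {      // flip so the interior point is inside
    n[0] = -n[0]; n[1] = -n[1]; n[2] = -n[2];
    off = -off;
    std::swap(F.b, F.c);
  }
  F.n[0] = n[0]; F.n[1] = n[1]; F.n[2] = n[2]; F.off = off;
  return true;
}

static inline double face_dist(const Face& F, const double* p) {
  return F.n[0] * p[0] + F.n[1] * p[1] + F.n[2] * p[2] - F.off;
}

// [[Rcpp::export]]
List cpp_quickhull_planes(NumericMatrix P) {
  const int n = P.nrow();
  double lo[3] = { BIG, BIG, BIG }, hi[3] = { -BIG, -BIG, -BIG };
  int ilo[3] = { 0, 0, 0 }, ihi[3] = { 0, 0, 0 };
  for (int i = 0; i < n; i++)
    for (int a = 0; a < 3; a++) {
      double x = P(i, a);
      if (x < lo[a]) { lo[a] = x; ilo[a] = i; }
      if (x > hi[a]) { hi[a] = x; ihi[a] = i; }
    }
  double extent = std::max(hi[0] - lo[0],
                  std::max(hi[1] - lo[1], hi[2] - lo[2]));
  double eps = 1e-8 * (1.0 + extent);

  // initial segment: farthest apart among the axis extremes
  int p0 = 0, p1 = 0; double best = -1.0;
  int cand[6] = { ilo[0], ihi[0], ilo[1], ihi[1], ilo[2], ihi[2] };
  for (int i = 0; i < 6; i++)
    for (int j = i + 1; j < 6; j++) {
      double d = 0;
      for (int a = 0; a < 3; a++) {
        double t = P(cand[i], a) - P(cand[j], a);
        d += t * t;
      }
      if (d > best) { best = d; p0 = cand[i]; p1 = cand[j]; }
    }
  if (std::sqrt(std::max(best, 0.0)) < eps)
    return List::create(_["rank"] = 0);

  // third point: farthest from the p0-p1 line
  double A[3] = { P(p0, 0), P(p0, 1), P(p0, 2) };
  double u[3]; double Bp[3] = { P(p1, 0), P(p1, 1), P(p1, 2) };
  vsub(Bp, A, u);
  double uu = vdot(u, u);
  int p2 = -1; best = -1.0;
  for (int i = 0; i < n; i++) {
    double w[3] = { P(i, 0) - A[0], P(i, 1) - A[1], P(i, 2) - A[2] };
    double t = vdot(w, u) / uu;
    double d = 0;
    for (int a = 0; a < 3; a++) {
      double r = w[a] - t * u[a];
      d += r * r;
    }
    if (d > best) { best = d; p2 = i; }
  }
  if (std::sqrt(std::max(best, 0.0)) < eps)
    return List::create(_["rank"] = 1);

  // fourth point: farthest from the p0-p1-p2 plane
  double v0[3] = { P(p2, 0) - A[0], P(p2, 1) - A[1], P(p2, 2) - A[2] };
  double nrm[3]; vcross(u, v0, nrm);
  double nn = std::sqrt(vdot(nrm, nrm));
  nrm[0] /= nn; nrm[1] /= nn; nrm[2] /= nn;
  double offA = vdot(nrm, A);
  int p3 = -1; best = -1.0;
  for (int i = 0; i < n; i++) {
    double p[3] = { P(i, 0), P(i, 1), P(i, 2) };
    double d = std::fabs(vdot(nrm, p) - offA);
    if (d > best) { best = d; p3 = i; }
  }
  if (best < eps)
    return List::create(_["rank"] = 2);

  double inner[3];
  for (int a = 0; a < 3; a++)
    inner[a] = (P(p0, a) + P(p1, a) + P(p2, a) + P(p3, a)) / 4.0;

  std::vector<Face> faces;
  int tet[4][3] = { { p0, p1, p2 }, { p0, p1, p3 },
                    { p0, p2, p3 }, { p1, p2, p3 } };
  for (int f = 0; f < 4; f++) {
    Face F; F.a = tet[f][0]; F.b = tet[f][1]; F.c = tet[f][2];
    F.alive = true; F.far_idx = -1; F.far_d = 0;
    if (!face_plane(P, F, inner)) stop("degenerate initial simplex");
    faces.push_back(F);
  }

  // assign each point to the first face it lies outside of
  for (int i = 0; i < n; i++) {
    if (i == p0 || i == p1 || i == p2 || i == p3) continue;
    double p[3] = { P(i, 0), P(i, 1), P(i, 2) };
    for (size_t f = 0; f < faces.size(); f++) {
      double d = face_dist(faces[f], p);
      if (d > eps) {
        faces[f].out.push_back(i);
        if (d > faces[f].far_d) { faces[f].far_d = d; faces[f].far_idx = i; }
        break;
      }
    }
  }

  for (;;) {
    int fi = -1;
    for (size_t f = 0; f < faces.size(); f++)
      if (faces[f].alive && !faces[f].out.empty()) { fi = (int)f; break; }
    if (fi < 0) break;
    int pi = faces[fi].far_idx;
    double p[3] = { P(pi, 0), P(pi, 1), P(pi, 2) };

    std::vector<int> visible;
    for (size_t f = 0; f < faces.size(); f++)
      if (faces[f].alive && face_dist(faces[f], p) > eps)
        visible.push_back((int)f);

    // horizon: undirected edges of visible faces occurring exactly once
    std::map<std::pair<int, int>, std::pair<int, int> > edges;
    for (size_t k = 0; k < visible.size(); k++) {
      const Face& F = faces[visible[k]];
      int e[3][2] = { { F.a, F.b }, { F.b, F.c }, { F.c, F.a } };
      for (int t = 0; t < 3; t++) {
        int a = e[t][0], b = e[t][1];
        std::pair<int, int> key(std::min(a, b), std::max(a, b));
        std::map<std::pair<int, int>, std::pair<int, int> >::iterator it =
          edges.find(key);
        if (it == edges.end()) edges[key] = std::make_pair(a, b);
        else it->second.first = -1;   // shared by two visible faces
      }
    }

    std::vector<int> orphans;
    for (size_t k = 0; k < visible.size(); k++) {
      Face& F = faces[visible[k]];
      F.alive = false;
      for (size_t t = 0; t < F.out.size(); t++)
        if (F.out[t] != pi) orphans.push_back(F.out[t]);
      F.out.clear();
    }

    std::vector<int> fresh;
    for (std::map<std::pair<int, int>, std::pair<int, int> >::iterator it =
           edges.begin(); it != edges.end(); ++it) {
      if (it->second.first < 0) continue;
      Face F; F.a = it->second.first; F.b = it->second.second; F.c = pi;
      F.alive = true; F.far_idx = -1; F.far_d = 0;
      if (!face_plane(P, F, inner)) continue;  // sliver; points fall elsewhere
      faces.push_back(F);
      fresh.push_back((int)faces.size() - 1);
    }

    for (size_t t = 0; t < orphans.size(); t++) {
      int i = orphans[t];
      double q[3] = { P(i, 0), P(i, 1), P(i, 2) };
      for (size_t k = 0; k < fresh.size(); k++) {
        Face& F = faces[fresh[k]];
        double d = face_dist(F, q);
        if (d > eps) {
          F.out.push_back(i);
          if (d > F.far_d) { F.far_d = d; F.far_idx = i; }
          break;
        }
      }
    }
  }

  int nf = 0;
  for (size_t f = 0; f < faces.size(); f++) if (faces[f].alive) nf++;
  NumericMatrix planes(nf, 4);
  int r = 0;
  for (size_t f = 0; f < faces.size(); f++) {
    if (!faces[f].alive) continue;
    planes(r, 0) = faces[f].n[0];
    planes(r, 1) = faces[f].n[1];
    planes(r, 2) = faces[f].n[2];
    planes(r, 3) = faces[f].off;
    r++;
  }
  return List::create(_["rank"] = 3, _["planes"] = planes);
}

// [[Rcpp::export]]
LogicalVector cpp_points_in_planes(NumericMatrix Q, NumericMatrix planes,
                                   double tol) {
  const int k = Q.nrow(), m = planes.nrow();
  LogicalVector inside(k, true);
  for (int i = 0; i < k; i++) {
    double p[3] = { Q(i, 0), Q(i, 1), Q(i, 2) };
    for (int f = 0; f < m; f++) {
      double d = planes(f, 0) * p[0] + planes(f, 1) * p[1] +
                 planes(f, 2) * p[2] - planes(f, 3);
      if (d > tol) { inside[i] = false; break; }
    }
  }
  return inside;
}

// ---------------------------------------------------------------------------
// Reference (oracle) routines: exhaustive supporting-plane hull membership
// and exhaustive nearest-point distances. Deliberately independent of the
// quickhull / distance-transform code paths above.
// ---------------------------------------------------------------------------

// [[Rcpp::export]]
LogicalVector cpp_brute_hull_classify(NumericMatrix S, NumericMatrix Q,
                                      double tol) {
  const int m = S.nrow(), k = Q.nrow();
  LogicalVector inside(k, true);
  std::vector<double> sx(m), sy(m), sz(m);
  for (int i = 0; i < m; i++) { sx[i] = S(i,0); sy[i] = S(i,1); sz[i] = S(i,2); }
  for (int i = 0; i < m; i++)
    for (int j = i + 1; j < m; j++)
      for (int l = j + 1; l < m; l++) {
        double u[3] = { sx[j]-sx[i], sy[j]-sy[i], sz[j]-sz[i] };
        double v[3] = { sx[l]-sx[i], sy[l]-sy[i], sz[l]-sz[i] };
        double nvec[3]; vcross(u, v, nvec);
        double nn = std::sqrt(vdot(nvec, nvec));
        if (nn < 1e-12) continue;
        nvec[0] /= nn; nvec[1] /= nn; nvec[2] /= nn;
        double off = nvec[0]*sx[i] + nvec[1]*sy[i] + nvec[2]*sz[i];
        bool above = false, below = false;
        for (int t = 0; t < m; t++) {
          double d = nvec[0]*sx[t] + nvec[1]*sy[t] + nvec[2]*sz[t] - off;
          if (d > tol) above = true;
          else if (d < -tol) below = true;
          if (above && below) break;
        }
        if (above && below) continue;     // not a supporting plane
        if (!above) {                      // hull lies at n.x <= off
          for (int q = 0; q < k; q++) {
            if (!inside[q]) continue;
            double d = nvec[0]*Q(q,0) + nvec[1]*Q(q,1) + nvec[2]*Q(q,2) - off;
            if (d > tol) inside[q] = false;
          }
        }
        if (!below) {                      // hull lies at n.x >= off
          for (int q = 0; q < k; q++) {
            if (!inside[q]) continue;
            double d = nvec[0]*Q(q,0) + nvec[1]*Q(q,1) + nvec[2]*Q(q,2) - off;
            if (d < -tol) inside[q] = false;
          }
        }
      }
  return inside;
}

// [[Rcpp::export]]
NumericVector cpp_brute_min_dist2(NumericMatrix Q, NumericMatrix S) {
  const int k = Q.nrow(), m = S.nrow();
  NumericVector out(k);
  for (int i = 0; i < k; i++) {
    double qx = Q(i, 0), qy = Q(i, 1), qz = Q(i, 2);
    double best = BIG;
    for (int j = 0; j < m; j++) {
      double dx = qx - S(j, 0), dy = qy - S(j, 1), dz = qz - S(j, 2);
      double d = dx * dx + dy * dy + dz * dz;
      if (d < best) best = d;
    }
    out[i] = best;
  }
  return out;
}
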