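// Computational kernels for the charge-based boundary element method:
// analytic field of a uniformly charged triangle, monopole far-field sums,
// near-pair search on a uniform grid, dense operator assembly, primary coil
// field summation, and a geometry fingerprint.
//
// Conventions: the "unit triangle field" of facet n at point r is
//   F_n(r) = (1/4pi) \int_{t_n} (r - r') / |r - r'|^3 dA',
// i.e. the E-field of the facet carrying unit scaled charge density
// rho* = rho/eps0 = 1. Closed form: decompose into the signed solid angle
// (normal part) and edge line integrals of 1/R (in-plane part).

#include <Rcpp.h>
#include <cmath>
#include <vector>
#include <unordered_map>
#include <cstdint>

using namespace Rcpp;

static const double INV4PI = 1.0 / (4.0 * M_PI);

static inline double dot3(const double* a, const double* b) {
  return a[0] * b[0] + a[1] * b[1] + a[2] * b[2];
}
static inline void cross3(const double* a, const double* b, double* c) {
  c[0] = a[1] * b[2] - a[2] * b[1];
  c[1] = a[2] * b[0] - a[0] * b[2];
  c[2] = a[0] * b[1] - a[1] * b[0];
}

// Analytic PV field of a uniformly charged flat triangle (unit rho*), at p.
// v1,v2,v3 are the vertex coordinates ordered so that (v2-v1)x(v3-v1) points
// along the facet normal nrm (unit). Result added into out[3].
static void tri_field_analytic(const double* v1, const double* v2,
                               const double* v3, const double* nrm,
                               const double* p, double* out) {
  const double* vs[4] = {v1, v2, v3, v1};

  // normal part: signed solid angle (van Oosterom & Strackee)
  double a[3], b[3], c[3];
  for (int k = 0; k < 3; ++k) {
    a[k] = v1[k] - p[k];
    b[k] = v2[k] - p[k];
    c[k] = v3[k] - p[k];
  }
  double ra = std::sqrt(dot3(a, a)), rb = std::sqrt(dot3(b, b)),
         rc = std::sqrt(dot3(c, c));
  double bxc[3];
  cross3(b, c, bxc);
  double triple = dot3(a, bxc);
  double den = ra * rb * rc + dot3(a, b) * rc + dot3(a, c) * rb +
               dot3(b, c) * ra;
  // solid angle subtended; with CCW vertices (right-handed about nrm) the
  // field's normal component on the +nrm side is positive, giving -triple.
  // For a point in the triangle's plane the principal value is zero; guard
  // against the atan2 branch ambiguity of a signed-zero numerator there.
  double omega;
  if (std::fabs(triple) <= 1e-14 * (std::fabs(den) + ra * rb * rc))
    omega = 0.0;
  else
    omega = 2.0 * std::atan2(-triple, den);
  double ex = nrm[0] * omega, ey = nrm[1] * omega, ez = nrm[2] * omega;

  // in-plane part: sum over edges of outward edge normal times int dl/R
  for (int e = 0; e < 3; ++e) {
    const double* va = vs[e];
    const double* vb = vs[e + 1];
    double t[3] = {vb[0] - va[0], vb[1] - va[1], vb[2] - va[2]};
    double L = std::sqrt(dot3(t, t));
    if (L <= 0.0) continue;
    t[0] /= L; t[1] /= L; t[2] /= L;
    double m[3];
    cross3(t, nrm, m);  // outward in-plane edge normal for CCW ordering
    double da[3] = {va[0] - p[0], va[1] - p[1], va[2] - p[2]};
    double db[3] = {vb[0] - p[0], vb[1] - p[1], vb[2] - p[2]};
    double sa = dot3(da, t), sb = dot3(db, t);
    double Ra = std::sqrt(dot3(da, da)), Rb = std::sqrt(dot3(db, db));
    // int_{sa}^{sb} ds / sqrt(s^2 + d^2) = log((sb + Rb)/(sa + Ra));
    // switch to the algebraically equal form when cancellation threatens.
    double I;
    double num1 = sb + Rb, den1 = sa + Ra;
    if (den1 > 1e-14 * (Ra + std::fabs(sa) + 1e-300) && num1 > 0.0) {
      I = std::log(num1 / den1);
    } else {
      double num2 = Ra - sa, den2 = Rb - sb;
      I = (den2 > 0.0 && num2 > 0.0) ? std::log(num2 / den2) : 0.0;
    }
    ex += m[0] * I; ey += m[1] * I; ez += m[2] * I;
  }
  out[0] += INV4PI * ex;
  out[1] += INV4PI * ey;
  out[2] += INV4PI * ez;
}

// [[Rcpp::export(name = ".tri_field_cpp")]]
NumericMatrix tri_field_cpp(NumericMatrix verts, NumericVector normal,
                            NumericMatrix points) {
  if (verts.nrow() != 3 || verts.ncol() != 3)
    stop("verts must be a 3x3 matrix (one vertex per row)");
  double v1[3], v2[3], v3[3], n[3];
  for (int k = 0; k < 3; ++k) {
    v1[k] = verts(0, k); v2[k] = verts(1, k); v3[k] = verts(2, k);
    n[k] = normal[k];
  }
  int np = points.nrow();
  NumericMatrix out(np, 3);
  for (int i = 0; i < np; ++i) {
    double p[3] = {points(i, 0), points(i, 1), points(i, 2)};
    double f[3] = {0.0, 0.0, 0.0};
    tri_field_analytic(v1, v2, v3, n, p, f);
    out(i, 0) = f[0]; out(i, 1) = f[1]; out(i, 2) = f[2];
  }
  return out;
}

// Monopole (centroid point-charge) far-field matvec:
// y_m = n_m . sum_{n != m} A_n x_n (c_m - c_n) / (4 pi |c_m - c_n|^3)
// Symmetric pairwise accumulation halves the sqrt/div count.
// [[Rcpp::export(name = ".matvec_monopole_cpp")]]
NumericVector matvec_monopole_cpp(NumericMatrix centroids,
                                  NumericMatrix normals,
                                  NumericVector areas,
                                  NumericVector x) {
  const int N = centroids.nrow();
  std::vector<double> cx(N), cy(N), cz(N), nx(N), ny(N), nz(N), w(N);
  for (int i = 0; i < N; ++i) {
    cx[i] = centroids(i, 0); cy[i] = centroids(i, 1); cz[i] = centroids(i, 2);
    nx[i] = normals(i, 0);   ny[i] = normals(i, 1);   nz[i] = normals(i, 2);
    w[i] = areas[i] * x[i];
  }
  std::vector<double> y(N, 0.0);
  // Tiled symmetric sweep: for each tile pair the reciprocal cube distances
  // are computed once into a buffer (vectorizable contiguous loops), then
  // reused for the transposed contributions.
  const int B = 160;  // tile size; buffer = B*B doubles ~ 200 KB
  std::vector<double> buf(B * B);
  for (int ib = 0; ib < N; ib += B) {
    const int ie = std::min(ib + B, N);
    for (int jb = ib; jb < N; jb += B) {
      const int je = std::min(jb + B, N);
      const int JW = je - jb;
      // phase 1: fill 1/r^3 buffer, accumulate row contributions y[m]
      for (int m = ib; m < ie; ++m) {
        const double cmx = cx[m], cmy = cy[m], cmz = cz[m];
        const double nmx = nx[m], nmy = ny[m], nmz = nz[m];
        double* bm = &buf[(size_t)(m - ib) * JW];
        const int n0 = (jb == ib) ? std::max(jb, m + 1) : jb;
        double am = 0.0;
        for (int n = n0; n < je; ++n) {
          const double dx = cmx - cx[n], dy = cmy - cy[n], dz = cmz - cz[n];
          const double r2 = dx * dx + dy * dy + dz * dz;
          const double s = 1.0 / (r2 * std::sqrt(r2));
          bm[n - jb] = s;
          am += (nmx * dx + nmy * dy + nmz * dz) * s * w[n];
        }
        y[m] += am;
      }
      // phase 2: transposed contributions y[n], contiguous over n
      for (int m = ib; m < ie; ++m) {
        const double cmx = cx[m], cmy = cy[m], cmz = cz[m];
        const double wm = w[m];
        const double* bm = &buf[(size_t)(m - ib) * JW];
        const int n0 = (jb == ib) ? std::max(jb, m + 1) : jb;
        for (int n = n0; n < je; ++n) {
          const double dx = cmx - cx[n], dy = cmy - cy[n], dz = cmz - cz[n];
          y[n] -= (nx[n] * dx + ny[n] * dy + nz[n] * dz) * bm[n - jb] * wm;
        }
      }
    }
  }
  NumericVector out(N);
  for (int i = 0; i < N; ++i) out[i] = INV4PI * y[i];
  return out;
}

// symmetric barycentric quadrature rules on a triangle
// (1-point centroid; 3-point degree-2 midpoint; 7-point degree-5)
static int quad_rule(int nq, const double** L, const double** W) {
  static const double L1[] = {1.0 / 3, 1.0 / 3, 1.0 / 3};
  static const double W1[] = {1.0};
  static const double L3[] = {0.5, 0.5, 0.0, 0.0, 0.5, 0.5, 0.5, 0.0, 0.5};
  static const double W3[] = {1.0 / 3, 1.0 / 3, 1.0 / 3};
  static const double a1 = 0.059715871789770, b1 = 0.470142064105115;
  static const double a2 = 0.797426985353087, b2 = 0.101286507323456;
  static const double L7[] = {
      1.0 / 3, 1.0 / 3, 1.0 / 3,
      a1, b1, b1,  b1, a1, b1,  b1, b1, a1,
      a2, b2, b2,  b2, a2, b2,  b2, b2, a2};
  static const double w1 = 0.132394152788506, w2 = 0.125939180544827;
  static const double W7[] = {0.225, w1, w1, w1, w2, w2, w2};
  switch (nq) {
    case 1: *L = L1; *W = W1; return 1;
    case 3: *L = L3; *W = W3; return 3;
    default: *L = L7; *W = W7; return 7;
  }
}

struct CellKey {
  int64_t key;
};

static inline int64_t cell_key(int ix, int iy, int iz) {
  // pack three 21-bit signed cell coordinates
  const int64_t off = 1 << 20;
  return (((int64_t)(ix + off)) << 42) | (((int64_t)(iy + off)) << 21) |
         ((int64_t)(iz + off));
}

// Near-pair corrections to the monopole approximation of the operator:
// C[m,n] = n_m . (<F_n^analytic>_m - F_n^monopole(c_m)) for pairs m != n
// with |c_m - c_n| <= thr * sqrt(max(A_m, A_n)), where <.>_m averages the
// analytic inner integral over the collocation facet t_m with an nq-point
// symmetric rule (nq = 1 recovers pure centroid collocation). Returns
// 1-based triplets. thr = Inf yields corrections for every off-diagonal
// pair (brute force).
// [[Rcpp::export(name = ".near_corrections_cpp")]]
List near_corrections_cpp(NumericMatrix vertices, IntegerMatrix tris,
                          NumericMatrix centroids, NumericMatrix normals,
                          NumericVector areas, double thr, int nq) {
  const int N = centroids.nrow();
  std::vector<int> ii, jj;
  std::vector<double> val;

  std::vector<double> sq(N);
  double sqmax = 0.0;
  for (int i = 0; i < N; ++i) {
    sq[i] = std::sqrt(areas[i]);
    if (sq[i] > sqmax) sqmax = sq[i];
  }

  const double* QL; const double* QW;
  int NQ = quad_rule(nq, &QL, &QW);

  auto correction = [&](int m, int n) {
    // facet-averaged analytic field of facet n over facet m, minus the
    // centroid monopole of facet n. The same fixed rule is used at every
    // refinement level so the (small) rule error is a consistent part of
    // the discretization family and cancels in self-convergence studies.
    double v1[3], v2[3], v3[3], nn[3];
    int a = tris(n, 0), b = tris(n, 1), c = tris(n, 2);
    int ma = tris(m, 0), mb = tris(m, 1), mc = tris(m, 2);
    for (int k = 0; k < 3; ++k) {
      v1[k] = vertices(a, k); v2[k] = vertices(b, k); v3[k] = vertices(c, k);
      nn[k] = normals(n, k);
    }
    double f[3] = {0.0, 0.0, 0.0};
    for (int q = 0; q < NQ; ++q) {
      double p[3], fq[3] = {0.0, 0.0, 0.0};
      for (int k = 0; k < 3; ++k)
        p[k] = QL[3 * q] * vertices(ma, k) + QL[3 * q + 1] * vertices(mb, k) +
               QL[3 * q + 2] * vertices(mc, k);
      tri_field_analytic(v1, v2, v3, nn, p, fq);
      f[0] += QW[q] * fq[0]; f[1] += QW[q] * fq[1]; f[2] += QW[q] * fq[2];
    }
    double dx = centroids(m, 0) - centroids(n, 0);
    double dy = centroids(m, 1) - centroids(n, 1);
    double dz = centroids(m, 2) - centroids(n, 2);
    double r2 = dx * dx + dy * dy + dz * dz;
    double s = areas[n] * INV4PI / (r2 * std::sqrt(r2));
    double nm0 = normals(m, 0), nm1 = normals(m, 1), nm2 = normals(m, 2);
    double corr = nm0 * f[0] + nm1 * f[1] + nm2 * f[2] -
                  s * (nm0 * dx + nm1 * dy + nm2 * dz);
    ii.push_back(m + 1);
    jj.push_back(n + 1);
    val.push_back(corr);
  };

  if (!R_finite(thr)) {
    for (int m = 0; m < N; ++m)
      for (int n = 0; n < N; ++n)
        if (m != n) correction(m, n);
  } else {
    double h = thr * sqmax;
    if (h <= 0.0) h = 1.0;
    std::unordered_map<int64_t, std::vector<int> > grid;
    grid.reserve(N * 2);
    for (int i = 0; i < N; ++i) {
      int ix = (int)std::floor(centroids(i, 0) / h);
      int iy = (int)std::floor(centroids(i, 1) / h);
      int iz = (int)std::floor(centroids(i, 2) / h);
      grid[cell_key(ix, iy, iz)].push_back(i);
    }
    for (int m = 0; m < N; ++m) {
      int ix = (int)std::floor(centroids(m, 0) / h);
      int iy = (int)std::floor(centroids(m, 1) / h);
      int iz = (int)std::floor(centroids(m, 2) / h);
      for (int dx = -1; dx <= 1; ++dx)
        for (int dy = -1; dy <= 1; ++dy)
          for (int dz = -1; dz <= 1; ++dz) {
            auto it = grid.find(cell_key(ix + dx, iy + dy, iz + dz));
            if (it == grid.end()) continue;
            for (int n : it->second) {
              if (n == m) continue;
              double ddx = centroids(m, 0) - centroids(n, 0);
              double ddy = centroids(m, 1) - centroids(n, 1);
              double ddz = centroids(m, 2) - centroids(n, 2);
              double r2 = ddx * ddx + ddy * ddy + ddz * ddz;
              double rad = thr * std::max(sq[m], sq[n]);
              if (r2 <= rad * rad) correction(m, n);
            }
          }
    }
  }
  return List::create(_["i"] = wrap(ii), _["j"] = wrap(jj),
                      _["x"] = wrap(val));
}

// Dense G matrix with G[m,n] = n_m . F_n(c_m): monopole everywhere,
// zero diagonal (flat-facet PV self field has no normal component).
// Near corrections are applied on top from R.
// [[Rcpp::export(name = ".dense_monopole_cpp")]]
NumericMatrix dense_monopole_cpp(NumericMatrix centroids,
                                 NumericMatrix normals,
                                 NumericVector areas) {
  const int N = centroids.nrow();
  NumericMatrix G(N, N);
  for (int n = 0; n < N; ++n) {
    double cnx = centroids(n, 0), cny = centroids(n, 1), cnz = centroids(n, 2);
    double an = areas[n] * INV4PI;
    for (int m = 0; m < N; ++m) {
      if (m == n) continue;
      double dx = centroids(m, 0) - cnx;
      double dy = centroids(m, 1) - cny;
      double dz = centroids(m, 2) - cnz;
      double r2 = dx * dx + dy * dy + dz * dz;
      double s = an / (r2 * std::sqrt(r2));
      G(m, n) = s * (normals(m, 0) * dx + normals(m, 1) * dy +
                     normals(m, 2) * dz);
    }
  }
  return G;
}

// Secondary (charge) field at arbitrary points. Facets whose centroid lies
// within thr * sqrt(A_n) of the point use the analytic integral, the rest
// the centroid monopole. exclude[i] (1-based, 0 = none) drops one facet per
// point entirely (used for the one-sided evaluation at a facet's centroid).
// [[Rcpp::export(name = ".field_secondary_cpp")]]
NumericMatrix field_secondary_cpp(NumericMatrix points, IntegerVector exclude,
                                  NumericMatrix vertices, IntegerMatrix tris,
                                  NumericMatrix centroids,
                                  NumericMatrix normals, NumericVector areas,
                                  NumericVector x, double thr) {
  const int P = points.nrow();
  const int N = centroids.nrow();
  std::vector<double> sq(N);
  for (int n = 0; n < N; ++n) sq[n] = std::sqrt(areas[n]);
  NumericMatrix out(P, 3);
  bool allnear = !R_finite(thr);
  for (int i = 0; i < P; ++i) {
    double p[3] = {points(i, 0), points(i, 1), points(i, 2)};
    int ex = exclude[i] - 1;
    double fx = 0.0, fy = 0.0, fz = 0.0;
    for (int n = 0; n < N; ++n) {
      if (n == ex || x[n] == 0.0) continue;
      double dx = p[0] - centroids(n, 0);
      double dy = p[1] - centroids(n, 1);
      double dz = p[2] - centroids(n, 2);
      double r2 = dx * dx + dy * dy + dz * dz;
      double rad = thr * sq[n];
      if (allnear || r2 <= rad * rad) {
        double v1[3], v2[3], v3[3], nn[3];
        int a = tris(n, 0), b = tris(n, 1), c = tris(n, 2);
        for (int k = 0; k < 3; ++k) {
          v1[k] = vertices(a, k); v2[k] = vertices(b, k);
          v3[k] = vertices(c, k); nn[k] = normals(n, k);
        }
        double f[3] = {0.0, 0.0, 0.0};
        tri_field_analytic(v1, v2, v3, nn, p, f);
        fx += x[n] * f[0]; fy += x[n] * f[1]; fz += x[n] * f[2];
      } else {
        double s = x[n] * areas[n] * INV4PI / (r2 * std::sqrt(r2));
        fx += s * dx; fy += s * dy; fz += s * dz;
      }
    }
    out(i, 0) = fx; out(i, 1) = fy; out(i, 2) = fz;
  }
  return out;
}

// Primary coil field E^p(r) = -(mu0/4pi) dI/dt sum_j m_j / |r - r_j|.
// [[Rcpp::export(name = ".primary_field_cpp")]]
NumericMatrix primary_field_cpp(NumericMatrix points, NumericMatrix epos,
                                NumericMatrix emom, double didt) {
  const int P = points.nrow();
  const int M = epos.nrow();
  const double MU0_4PI = 1e-7;  // exact in SI
  NumericMatrix out(P, 3);
  std::vector<double> px(M), py(M), pz(M), mx(M), my(M), mz(M);
  for (int j = 0; j < M; ++j) {
    px[j] = epos(j, 0); py[j] = epos(j, 1); pz[j] = epos(j, 2);
    mx[j] = emom(j, 0); my[j] = emom(j, 1); mz[j] = emom(j, 2);
  }
  for (int i = 0; i < P; ++i) {
    double x = points(i, 0), y = points(i, 1), z = points(i, 2);
    double fx = 0.0, fy = 0.0, fz = 0.0;
    for (int j = 0; j < M; ++j) {
      double dx = x - px[j], dy = y - py[j], dz = z - pz[j];
      double r = std::sqrt(dx * dx + dy * dy + dz * dz);
      if (r < 1e-12) stop("observation point coincides with a coil element");
      double s = 1.0 / r;
      fx += mx[j] * s; fy += my[j] * s; fz += mz[j] * s;
    }
    out(i, 0) = -MU0_4PI * didt * fx;
    out(i, 1) = -MU0_4PI * didt * fy;
    out(i, 2) = -MU0_4PI * didt * fz;
  }
  return out;
}

// FNV-1a 64-bit hash over the bytes of a numeric vector (deterministic
// geometry/conductivity fingerprint).
// [[Rcpp::export(name = ".fnv1a_cpp")]]
CharacterVector fnv1a_cpp(NumericVector v) {
  const unsigned char* bytes =
      reinterpret_cast<const unsigned char*>(REAL(v));
  size_t n = (size_t)v.size() * sizeof(double);
  uint64_t h = 1469598103934665603ULL;
  for (size_t i = 0; i < n; ++i) {
    h ^= (uint64_t)bytes[i];
    h *= 1099511628211ULL;
  }
  char buf[17];
  snprintf(buf, sizeof(buf), "%016llx", (unsigned long long)h);
  return CharacterVector::create(buf);
}
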