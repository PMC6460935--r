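// Boundary-element kernels: analytic solid angles of flat triangles
// (van Oosterom & Strackee), analytic single-layer potentials of uniform
// triangle sources, and infinite-medium dipole potentials.
#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// Signed solid angle of triangle (p1,p2,p3) as seen from o.
// Positive when the triangle's right-handed normal faces away from o.
static inline double tri_solid_angle(const double *p1, const double *p2,
                                     const double *p3, const double *o) {
  double r1[3], r2[3], r3[3];
  for (int c = 0; c < 3; ++c) {
    r1[c] = p1[c] - o[c]; r2[c] = p2[c] - o[c]; r3[c] = p3[c] - o[c];
  }
  double R1 = std::sqrt(r1[0]*r1[0] + r1[1]*r1[1] + r1[2]*r1[2]);
  double R2 = std::sqrt(r2[0]*r2[0] + r2[1]*r2[1] + r2[2]*r2[2]);
  double R3 = std::sqrt(r3[0]*r3[0] + r3[1]*r3[1] + r3[2]*r3[2]);
  double num = r1[0]*(r2[1]*r3[2] - r2[2]*r3[1]) -
               r1[1]*(r2[0]*r3[2] - r2[2]*r3[0]) +
               r1[2]*(r2[0]*r3[1] - r2[1]*r3[0]);
  double d12 = r1[0]*r2[0] + r1[1]*r2[1] + r1[2]*r2[2];
  double d13 = r1[0]*r3[0] + r1[1]*r3[1] + r1[2]*r3[2];
  double d23 = r2[0]*r3[0] + r2[1]*r3[1] + r2[2]*r3[2];
  double den = R1 * R2 * R3 + d12 * R3 + d13 * R2 + d23 * R1;
  if (R1 == 0.0 || R2 == 0.0 || R3 == 0.0) return 0.0;  // observation at a vertex
  return 2.0 * std::atan2(num, den);
}

// [[Rcpp::export(name = ".cpp_solid_angle")]]
NumericMatrix cpp_solid_angle(NumericMatrix verts, IntegerMatrix tris,
                              NumericMatrix obs) {
  const int nt = tris.nrow(), no = obs.nrow();
  NumericMatrix out(no, nt);
  std::vector<double> V(verts.nrow() * 3);
  for (int i = 0; i < verts.nrow(); ++i)
    for (int c = 0; c < 3; ++c) V[i * 3 + c] = verts(i, c);
  for (int t = 0; t < nt; ++t) {
    const double *p1 = &V[(size_t)tris(t, 0) * 3];
    const double *p2 = &V[(size_t)tris(t, 1) * 3];
    const double *p3 = &V[(size_t)tris(t, 2) * 3];
    for (int i = 0; i < no; ++i) {
      double o[3] = {obs(i, 0), obs(i, 1), obs(i, 2)};
      out(i, t) = tri_solid_angle(p1, p2, p3, o);
    }
  }
  return out;
}

// Analytic integral of 1/|r - r'| over a flat triangle with uniform density
// (edge-sum formula; valid for observation points on or off the plane).
static double tri_single_layer(const double *p1, const double *p2,
                               const double *p3, const double *o) {
  // triangle frame
  double e1[3], e2[3], nrm[3];
  for (int c = 0; c < 3; ++c) { e1[c] = p2[c] - p1[c]; e2[c] = p3[c] - p1[c]; }
  nrm[0] = e1[1]*e2[2] - e1[2]*e2[1];
  nrm[1] = e1[2]*e2[0] - e1[0]*e2[2];
  nrm[2] = e1[0]*e2[1] - e1[1]*e2[0];
  double nn = std::sqrt(nrm[0]*nrm[0] + nrm[1]*nrm[1] + nrm[2]*nrm[2]);
  if (nn <= 0.0) return 0.0;  // degenerate triangle: caller validates
  for (int c = 0; c < 3; ++c) nrm[c] /= nn;
  // height of observation point above plane
  double d = (o[0]-p1[0])*nrm[0] + (o[1]-p1[1])*nrm[1] + (o[2]-p1[2])*nrm[2];
  // projection of o onto the plane
  double rho[3];
  for (int c = 0; c < 3; ++c) rho[c] = o[c] - d * nrm[c];

  const double *vv[4] = {p1, p2, p3, p1};
  double I = 0.0;
  for (int e = 0; e < 3; ++e) {
    const double *a = vv[e], *b = vv[e + 1];
    double sh[3], len = 0.0;
    for (int c = 0; c < 3; ++c) { sh[c] = b[c] - a[c]; len += sh[c]*sh[c]; }
    len = std::sqrt(len);
    if (len <= 0.0) continue;
    for (int c = 0; c < 3; ++c) sh[c] /= len;
    // in-plane outward normal of the edge
    double m[3];
    m[0] = sh[1]*nrm[2] - sh[2]*nrm[1];
    m[1] = sh[2]*nrm[0] - sh[0]*nrm[2];
    m[2] = sh[0]*nrm[1] - sh[1]*nrm[0];
    double t0 = (a[0]-rho[0])*m[0] + (a[1]-rho[1])*m[1] + (a[2]-rho[2])*m[2];
    double sm = (a[0]-rho[0])*sh[0] + (a[1]-rho[1])*sh[1] + (a[2]-rho[2])*sh[2];
    double sp = sm + len;
    double Rm = std::sqrt((a[0]-o[0])*(a[0]-o[0]) + (a[1]-o[1])*(a[1]-o[1]) +
                          (a[2]-o[2])*(a[2]-o[2]));
    double Rp = std::sqrt((b[0]-o[0])*(b[0]-o[0]) + (b[1]-o[1])*(b[1]-o[1]) +
                          (b[2]-o[2])*(b[2]-o[2]));
    if (std::fabs(t0) < 1e-12) continue;  // o lies on the edge line: no contribution
    double num = Rp + sp, den = Rm + sm;
    if (den <= 1e-300 || num <= 1e-300) continue;
    I += t0 * std::log(num / den);
  }
  double omega = std::fabs(tri_solid_angle(p1, p2, p3, o));
  I -= std::fabs(d) * omega;
  return I;
}

// [[Rcpp::export(name = ".cpp_single_layer")]]
NumericMatrix cpp_single_layer(NumericMatrix verts, IntegerMatrix tris,
                               NumericMatrix obs) {
  const int nt = tris.nrow(), no = obs.nrow();
  NumericMatrix out(no, nt);
  std::vector<double> V(verts.nrow() * 3);
  for (int i = 0; i < verts.nrow(); ++i)
    for (int c = 0; c < 3; ++c) V[i * 3 + c] = verts(i, c);
  for (int t = 0; t < nt; ++t) {
    const double *p1 = &V[(size_t)tris(t, 0) * 3];
    const double *p2 = &V[(size_t)tris(t, 1) * 3];
    const double *p3 = &V[(size_t)tris(t, 2) * 3];
    for (int i = 0; i < no; ++i) {
      double o[3] = {obs(i, 0), obs(i, 1), obs(i, 2)};
      out(i, t) = tri_single_layer(p1, p2, p3, o);
    }
  }
  return out;
}

// Infinite-medium potential of point dipoles: sum_s p_s.(o - x_s)/(4 pi |o-x_s|^3)
// [[Rcpp::export(name = ".cpp_dipole_potential")]]
NumericVector cpp_dipole_potential(NumericMatrix obs, NumericMatrix src,
                                   NumericMatrix mom) {
  const int no = obs.nrow(), ns = src.nrow();
  if (mom.nrow() != ns) stop("moment rows must match source rows");
  NumericVector out(no);
  const double fourpi = 4.0 * M_PI;
  std::vector<double> S(ns * 3), P(ns * 3);
  for (int s = 0; s < ns; ++s)
    for (int c = 0; c < 3; ++c) { S[s*3+c] = src(s, c); P[s*3+c] = mom(s, c); }
  for (int i = 0; i < no; ++i) {
    double o0 = obs(i, 0), o1 = obs(i, 1), o2 = obs(i, 2);
    double acc = 0.0;
    for (int s = 0; s < ns; ++s) {
      double dx = o0 - S[s*3], dy = o1 - S[s*3+1], dz = o2 - S[s*3+2];
      double r2 = dx*dx + dy*dy + dz*dz;
      double r = std::sqrt(r2);
      double r3 = r2 * r;
      if (r3 < 1e-300) stop("observation point coincides with a source");
      acc += (P[s*3]*dx + P[s*3+1]*dy + P[s*3+2]*dz) / r3;
    }
    out[i] = acc / fourpi;
  }
  return out;
}

// Snapshot-wise dipole potentials: sources fixed, moments given per snapshot
// as a (3*ns) x ntime matrix; returns no x ntime potentials.
// [[Rcpp::export(name = ".cpp_dipole_potential_series")]]
NumericMatrix cpp_dipole_potential_series(NumericMatrix obs, NumericMatrix src,
                                          NumericMatrix mom_series) {
  const int no = obs.nrow(), ns = src.nrow(), ntime = mom_series.ncol();
  if (mom_series.nrow() != 3 * ns) stop("moment series must have 3*ns rows");
  NumericMatrix out(no, ntime);
  // geometry factors are reused across snapshots: precompute unit kernels
  // K[i, 3s..3s+2] = (o - x_s)/(4 pi r^3), then out = K %*% mom_series.
  // Done blockwise to bound memory.
  const double fourpi = 4.0 * M_PI;
  const int block = std::max(1, 4000000 / (3 * std::max(1, ns)));
  std::vector<double> K((size_t)block * 3 * ns);
  for (int i0 = 0; i0 < no; i0 += block) {
    int nb = std::min(block, no - i0);
    for (int b = 0; b < nb; ++b) {
      double o0 = obs(i0 + b, 0), o1 = obs(i0 + b, 1), o2 = obs(i0 + b, 2);
      double *row = &K[(size_t)b * 3 * ns];
      for (int s = 0; s < ns; ++s) {
        double dx = o0 - src(s, 0), dy = o1 - src(s, 1), dz = o2 - src(s, 2);
        double r2 = dx*dx + dy*dy + dz*dz;
        double r3 = r2 * std::sqrt(r2);
        if (r3 < 1e-300) stop("observation point coincides with a source");
        double f = 1.0 / (fourpi * r3);
        row[3*s] = dx * f; row[3*s+1] = dy * f; row[3*s+2] = dz * f;
      }
    }
    for (int tcol = 0; tcol < ntime; ++tcol) {
      for (int b = 0; b < nb; ++b) {
        const double *row = &K[(size_t)b * 3 * ns];
        double acc = 0.0;
        for (int q = 0; q < 3 * ns; ++q) acc += row[q] * mom_series(q, tcol);
        out(i0 + b, tcol) = acc;
      }
    }
  }
  return out;
}
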