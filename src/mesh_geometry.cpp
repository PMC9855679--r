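#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// Closest point on triangle (a,b,c) to p; barycentric coords written to bary.
// Region classification per Ericson, Real-Time Collision Detection, 5.1.5.
static inline void closest_pt_triangle(const double p[3], const double a[3],
                                       const double b[3], const double c[3],
                                       double out[3], double bary[3]) {
  double ab[3], ac[3], ap[3];
  for (int k = 0; k < 3; ++k) {
    ab[k] = b[k] - a[k];
    ac[k] = c[k] - a[k];
    ap[k] = p[k] - a[k];
  }
  double d1 = ab[0]*ap[0] + ab[1]*ap[1] + ab[2]*ap[2];
  double d2 = ac[0]*ap[0] + ac[1]*ap[1] + ac[2]*ap[2];
  if (d1 <= 0.0 && d2 <= 0.0) {  // vertex a
    for (int k = 0; k < 3; ++k) out[k] = a[k];
    bary[0] = 1.0; bary[1] = 0.0; bary[2] = 0.0;
    return;
  }
  double bp[3];
  for (int k = 0; k < 3; ++k) bp[k] = p[k] - b[k];
  double d3 = ab[0]*bp[0] + ab[1]*bp[1] + ab[2]*bp[2];
  double d4 = ac[0]*bp[0] + ac[1]*bp[1] + ac[2]*bp[2];
  if (d3 >= 0.0 && d4 <= d3) {  // vertex b
    for (int k = 0; k < 3; ++k) out[k] = b[k];
    bary[0] = 0.0; bary[1] = 1.0; bary[2] = 0.0;
    return;
  }
  double vc = d1*d4 - d3*d2;
  if (vc <= 0.0 && d1 >= 0.0 && d3 <= 0.0) {  // edge ab
    double v = d1 / (d1 - d3);
    for (int k = 0; k < 3; ++k) out[k] = a[k] + v * ab[k];
    bary[0] = 1.0 - v; bary[1] = v; bary[2] = 0.0;
    return;
  }
  double cp[3];
  for (int k = 0; k < 3; ++k) cp[k] = p[k] - c[k];
  double d5 = ab[0]*cp[0] + ab[1]*cp[1] + ab[2]*cp[2];
  double d6 = ac[0]*cp[0] + ac[1]*cp[1] + ac[2]*cp[2];
  if (d6 >= 0.0 && d5 <= d6) {  // vertex c
    for (int k = 0; k < 3; ++k) out[k] = c[k];
    bary[0] = 0.0; bary[1] = 0.0; bary[2] = 1.0;
    return;
  }
  double vb = d5*d2 - d1*d6;
  if (vb <= 0.0 && d2 >= 0.0 && d6 <= 0.0) {  // edge ac
    double w = d2 / (d2 - d6);
    for (int k = 0; k < 3; ++k) out[k] = a[k] + w * ac[k];
    bary[0] = 1.0 - w; bary[1] = 0.0; bary[2] = w;
    return;
  }
  double va = d3*d6 - d5*d4;
  if (va <= 0.0 && (d4 - d3) >= 0.0 && (d5 - d6) >= 0.0) {  // edge bc
    double w = (d4 - d3) / ((d4 - d3) + (d5 - d6));
    for (int k = 0; k < 3; ++k) out[k] = b[k] + w * (c[k] - b[k]);
    bary[0] = 0.0; bary[1] = 1.0 - w; bary[2] = w;
    return;
  }
  // interior
  double denom = 1.0 / (va + vb + vc);
  double v = vb * denom, w = vc * denom;
  for (int k = 0; k < 3; ++k) out[k] = a[k] + ab[k] * v + ac[k] * w;
  bary[0] = 1.0 - v - w; bary[1] = v; bary[2] = w;
}

// For each query point, the closest point on the triangulated surface (V, F).
// F is 1-based. Ties between faces at identical distance are broken by the
// lowest face index (strict '<' keeps the earliest face scanned).
// [[Rcpp::export]]
List cpp_closest_on_surface(NumericMatrix P, NumericMatrix V, IntegerMatrix F) {
  const int n = P.nrow(), nf = F.nrow();
  if (nf < 1) stop("mesh has no faces");
  NumericMatrix closest(n, 3), bary(n, 3);
  NumericVector dist(n);
  IntegerVector face(n);
  std::vector<double> tv(nf * 9);
  for (int j = 0; j < nf; ++j)
    for (int c = 0; c < 3; ++c) {
      int vi = F(j, c) - 1;
      tv[j*9 + c*3 + 0] = V(vi, 0);
      tv[j*9 + c*3 + 1] = V(vi, 1);
      tv[j*9 + c*3 + 2] = V(vi, 2);
    }
  // bounding spheres for lower-bound pruning:
  // dist(p, triangle j) >= |p - centroid_j| - radius_j
  std::vector<double> cen(nf * 3), rad(nf);
  for (int j = 0; j < nf; ++j) {
    const double *t = &tv[j*9];
    for (int k = 0; k < 3; ++k)
      cen[j*3 + k] = (t[k] + t[3 + k] + t[6 + k]) / 3.0;
    double r2 = 0.0;
    for (int c = 0; c < 3; ++c) {
      double dx = t[c*3] - cen[j*3], dy = t[c*3+1] - cen[j*3+1],
             dz = t[c*3+2] - cen[j*3+2];
      double d2 = dx*dx + dy*dy + dz*dz;
      if (d2 > r2) r2 = d2;
    }
    rad[j] = std::sqrt(r2);
  }
  double q[3], out[3], bc[3];
  std::vector<double> dc(nf);
  for (int i = 0; i < n; ++i) {
    q[0] = P(i, 0); q[1] = P(i, 1); q[2] = P(i, 2);
    int j0 = 0;
    double dmin = R_PosInf;
    for (int j = 0; j < nf; ++j) {
      double dx = q[0]-cen[j*3], dy = q[1]-cen[j*3+1], dz = q[2]-cen[j*3+2];
      dc[j] = std::sqrt(dx*dx + dy*dy + dz*dz);
      if (dc[j] < dmin) { dmin = dc[j]; j0 = j; }
    }
    // seed the search with the triangle whose centroid is nearest
    const double *t0 = &tv[j0*9];
    closest_pt_triangle(q, t0, t0 + 3, t0 + 6, out, bc);
    double dx = q[0]-out[0], dy = q[1]-out[1], dz = q[2]-out[2];
    double best = std::sqrt(dx*dx + dy*dy + dz*dz);
    int bestf = j0;
    double bestpt[3] = {out[0], out[1], out[2]};
    double bestbc[3] = {bc[0], bc[1], bc[2]};
    for (int j = 0; j < nf; ++j) {
      if (j == j0) continue;
      if (dc[j] - rad[j] > best) continue;  // cannot beat or tie -> skip
      const double *t = &tv[j*9];
      closest_pt_triangle(q, t, t + 3, t + 6, out, bc);
      dx = q[0]-out[0]; dy = q[1]-out[1]; dz = q[2]-out[2];
      double d = std::sqrt(dx*dx + dy*dy + dz*dz);
      // strict improvement, or an exact tie from a lower face index
      if (d < best || (d == best && j < bestf)) {
        best = d; bestf = j;
        bestpt[0] = out[0]; bestpt[1] = out[1]; bestpt[2] = out[2];
        bestbc[0] = bc[0]; bestbc[1] = bc[1]; bestbc[2] = bc[2];
      }
    }
    dist[i] = best;
    face[i] = bestf + 1;
    for (int k = 0; k < 3; ++k) {
      closest(i, k) = bestpt[k];
      bary(i, k) = bestbc[k];
    }
  }
  return List::create(_["points"] = closest, _["dist"] = dist,
                      _["face"] = face, _["bary"] = bary);
}

// Moller-Trumbore ray/triangle intersection; returns t along dir or -1.
static inline double ray_tri(const double o[3], const double d[3],
                             const double *a, const double *b, const double *c) {
  const double EPS = 1e-12;
  double e1[3], e2[3];
  for (int k = 0; k < 3; ++k) { e1[k] = b[k] - a[k]; e2[k] = c[k] - a[k]; }
  double pv[3] = { d[1]*e2[2] - d[2]*e2[1],
                   d[2]*e2[0] - d[0]*e2[2],
                   d[0]*e2[1] - d[1]*e2[0] };
  double det = e1[0]*pv[0] + e1[1]*pv[1] + e1[2]*pv[2];
  if (std::fabs(det) < EPS) return -1.0;
  double inv = 1.0 / det;
  double tv[3] = { o[0]-a[0], o[1]-a[1], o[2]-a[2] };
  double u = (tv[0]*pv[0] + tv[1]*pv[1] + tv[2]*pv[2]) * inv;
  if (u < -1e-9 || u > 1.0 + 1e-9) return -1.0;
  double qv[3] = { tv[1]*e1[2] - tv[2]*e1[1],
                   tv[2]*e1[0] - tv[0]*e1[2],
                   tv[0]*e1[1] - tv[1]*e1[0] };
  double v = (d[0]*qv[0] + d[1]*qv[1] + d[2]*qv[2]) * inv;
  if (v < -1e-9 || u + v > 1.0 + 1e-9) return -1.0;
  return (e2[0]*qv[0] + e2[1]*qv[1] + e2[2]*qv[2]) * inv;
}

// Visibility of each face from a set of external viewpoints. A face counts as
// visible if any of its three vertices or its centroid is reached by an
// unobstructed ray from any viewpoint (first hit at the target, not before).
// [[Rcpp::export]]
LogicalVector cpp_visible_faces(NumericMatrix V, IntegerMatrix F,
                                NumericMatrix views) {
  const int nf = F.nrow(), nv = views.nrow();
  LogicalVector vis(nf, false);
  std::vector<double> tv(nf * 9);
  for (int j = 0; j < nf; ++j)
    for (int c = 0; c < 3; ++c) {
      int vi = F(j, c) - 1;
      tv[j*9 + c*3 + 0] = V(vi, 0);
      tv[j*9 + c*3 + 1] = V(vi, 1);
      tv[j*9 + c*3 + 2] = V(vi, 2);
    }
  double o[3], dir[3], tgt[3];
  for (int f = 0; f < nf; ++f) {
    const double *t = &tv[f*9];
    double cen[3] = { (t[0]+t[3]+t[6])/3.0, (t[1]+t[4]+t[7])/3.0,
                      (t[2]+t[5]+t[8])/3.0 };
    for (int w = 0; w < nv && !vis[f]; ++w) {
      o[0] = views(w, 0); o[1] = views(w, 1); o[2] = views(w, 2);
      for (int pt = 0; pt < 4 && !vis[f]; ++pt) {
        if (pt < 3) { tgt[0] = t[pt*3]; tgt[1] = t[pt*3+1]; tgt[2] = t[pt*3+2]; }
        else        { tgt[0] = cen[0];  tgt[1] = cen[1];    tgt[2] = cen[2]; }
        dir[0] = tgt[0]-o[0]; dir[1] = tgt[1]-o[1]; dir[2] = tgt[2]-o[2];
        bool blocked = false;
        for (int j = 0; j < nf; ++j) {
          if (j == f) continue;
          double s = ray_tri(o, dir, &tv[j*9], &tv[j*9+3], &tv[j*9+6]);
          // occluder strictly between the viewpoint and the target
          if (s > 1e-9 && s < 1.0 - 1e-6) { blocked = true; break; }
        }
        if (!blocked) vis[f] = true;
      }
    }
  }
  return vis;
}
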