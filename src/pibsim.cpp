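// Numerical kernels: exact-path (Siddon) cone-beam projection, fixed-step
// reference projection, trilinear rigid resampling, region NCC for the
// registration metric, 3D connected components and ball morphology, and a
// separable Gaussian smoother. All volumes are R arrays in column-major
// (i fastest) order with voxel (0,0,0) centered at `origin` and voxel
// centers at origin + index * spacing (0-based indices), world units mm.
#include <Rcpp.h>
#include <cmath>
#include <vector>
#include <queue>
#include <limits>
using namespace Rcpp;

static inline double trilerp_raw(const double* v, int d1, int d2, int d3,
                                 double xi, double yj, double zk, double fill) {
  if (!(xi >= 0.0) || !(yj >= 0.0) || !(zk >= 0.0) ||
      xi > (double)(d1 - 1) || yj > (double)(d2 - 1) || zk > (double)(d3 - 1))
    return fill;
  int i0 = (int)std::floor(xi);
  int j0 = (int)std::floor(yj);
  int k0 = (int)std::floor(zk);
  if (i0 > d1 - 2) i0 = d1 - 2;
  if (j0 > d2 - 2) j0 = d2 - 2;
  if (k0 > d3 - 2) k0 = d3 - 2;
  double fx = xi - i0, fy = yj - j0, fz = zk - k0;
  const R_xlen_t s1 = 1, s2 = d1, s3 = (R_xlen_t)d1 * d2;
  const double* p = v + i0 * s1 + (R_xlen_t)j0 * s2 + (R_xlen_t)k0 * s3;
  double c00 = p[0] * (1 - fx) + p[s1] * fx;
  double c10 = p[s2] * (1 - fx) + p[s2 + s1] * fx;
  double c01 = p[s3] * (1 - fx) + p[s3 + s1] * fx;
  double c11 = p[s3 + s2] * (1 - fx) + p[s3 + s2 + s1] * fx;
  double c0 = c00 * (1 - fy) + c10 * fy;
  double c1 = c01 * (1 - fy) + c11 * fy;
  return c0 * (1 - fz) + c1 * fz;
}

// like trilerp_raw but valid over the full voxel extent (half-voxel border
// clamped), matching the piecewise-constant voxel model at the boundary;
// used by the dense-sampling reference projector
static inline double trilerp_clamp(const double* v, int d1, int d2, int d3,
                                   double xi, double yj, double zk, double fill) {
  if (!(xi >= -0.5) || !(yj >= -0.5) || !(zk >= -0.5) ||
      xi > d1 - 0.5 || yj > d2 - 0.5 || zk > d3 - 0.5)
    return fill;
  if (xi < 0) xi = 0;
  if (xi > d1 - 1) xi = d1 - 1;
  if (yj < 0) yj = 0;
  if (yj > d2 - 1) yj = d2 - 1;
  if (zk < 0) zk = 0;
  if (zk > d3 - 1) zk = d3 - 1;
  return trilerp_raw(v, d1, d2, d3, xi, yj, zk, fill);
}

static inline double nearest_raw(const double* v, int d1, int d2, int d3,
                                 double xi, double yj, double zk, double fill) {
  if (!(xi >= -0.5) || !(yj >= -0.5) || !(zk >= -0.5) ||
      xi >= d1 - 0.5 || yj >= d2 - 0.5 || zk >= d3 - 0.5)
    return fill;
  int i = (int)std::lround(xi), j = (int)std::lround(yj), k = (int)std::lround(zk);
  if (i < 0) i = 0;
  if (i > d1 - 1) i = d1 - 1;
  if (j < 0) j = 0;
  if (j > d2 - 1) j = d2 - 1;
  if (k < 0) k = 0;
  if (k > d3 - 1) k = d3 - 1;
  return v[i + (R_xlen_t)j * d1 + (R_xlen_t)k * d1 * d2];
}

// Slab (AABB) intersection of the parametric ray p0 + t*(p1-p0) with the
// voxel-boundary box; returns false if the ray misses.
static inline bool ray_box(const double* p0, const double* dir,
                           const double* b0, const double* b1,
                           double& tmin, double& tmax) {
  tmin = 0.0; tmax = 1.0;
  for (int a = 0; a < 3; ++a) {
    if (std::fabs(dir[a]) < 1e-12) {
      if (p0[a] < b0[a] || p0[a] > b1[a]) return false;
    } else {
      double t0 = (b0[a] - p0[a]) / dir[a];
      double t1 = (b1[a] - p0[a]) / dir[a];
      if (t0 > t1) std::swap(t0, t1);
      if (t0 > tmin) tmin = t0;
      if (t1 < tmax) tmax = t1;
    }
  }
  return tmax > tmin;
}

// [[Rcpp::export]]
NumericMatrix cpp_siddon_project(NumericVector vol, IntegerVector dims,
                                 NumericVector spacing, NumericVector origin,
                                 NumericVector src, NumericVector det_center,
                                 NumericVector uhat, NumericVector vhat,
                                 double pitch, int nrow, int ncol) {
  const int d1 = dims[0], d2 = dims[1], d3 = dims[2];
  const double* v = REAL(vol);
  double b0[3], b1[3];
  for (int a = 0; a < 3; ++a) {
    b0[a] = origin[a] - 0.5 * spacing[a];
    b1[a] = origin[a] + (dims[a] - 0.5) * spacing[a];
  }
  NumericMatrix out(nrow, ncol);
  const double rc0 = 0.5 * (nrow + 1), cc0 = 0.5 * (ncol + 1);
  double p0[3] = { src[0], src[1], src[2] };
  for (int c = 1; c <= ncol; ++c) {
    double uu = (c - cc0) * pitch;
    for (int r = 1; r <= nrow; ++r) {
      double vv = (r - rc0) * pitch;
      double p1[3], dir[3];
      for (int a = 0; a < 3; ++a) {
        p1[a] = det_center[a] + uu * uhat[a] + vv * vhat[a];
        dir[a] = p1[a] - p0[a];
      }
      double tmin, tmax;
      if (!ray_box(p0, dir, b0, b1, tmin, tmax)) { out(r - 1, c - 1) = 0.0; continue; }
      double L = std::sqrt(dir[0] * dir[0] + dir[1] * dir[1] + dir[2] * dir[2]);
      // entry voxel from a point just inside the box
      double teps = tmin + 1e-10 * (tmax - tmin);
      int idx[3];
      for (int a = 0; a < 3; ++a) {
        double w = p0[a] + teps * dir[a];
        int i = (int)std::floor((w - b0[a]) / spacing[a]);
        if (i < 0) i = 0;
        if (i > dims[a] - 1) i = dims[a] - 1;
        idx[a] = i;
      }
      int stepv[3];
      double tnext[3], tdelta[3];
      for (int a = 0; a < 3; ++a) {
        if (dir[a] > 1e-12) {
          stepv[a] = 1;
          tdelta[a] = spacing[a] / dir[a];
          tnext[a] = (b0[a] + (idx[a] + 1) * spacing[a] - p0[a]) / dir[a];
        } else if (dir[a] < -1e-12) {
          stepv[a] = -1;
          tdelta[a] = -spacing[a] / dir[a];
          tnext[a] = (b0[a] + idx[a] * spacing[a] - p0[a]) / dir[a];
        } else {
          stepv[a] = 0;
          tdelta[a] = std::numeric_limits<double>::infinity();
          tnext[a] = std::numeric_limits<double>::infinity();
        }
      }
      double t = tmin, acc = 0.0;
      while (t < tmax - 1e-12) {
        int a = 0;
        if (tnext[1] < tnext[a]) a = 1;
        if (tnext[2] < tnext[a]) a = 2;
        double tn = tnext[a];
        if (tn > tmax) tn = tmax;
        double seg = tn - t;
        if (seg > 0)
          acc += seg * v[idx[0] + (R_xlen_t)idx[1] * d1 + (R_xlen_t)idx[2] * d1 * d2];
        t = tn;
        if (tn >= tmax) break;
        idx[a] += stepv[a];
        if (idx[a] < 0 || idx[a] > dims[a] - 1) break;
        tnext[a] += tdelta[a];
      }
      out(r - 1, c - 1) = acc * L;
    }
  }
  return out;
}

// Fixed-step midpoint-rule line integration with trilinear interpolation.
// Reference implementation for cross-checking the exact-path projector.
// [[Rcpp::export]]
NumericMatrix cpp_step_project(NumericVector vol, IntegerVector dims,
                               NumericVector spacing, NumericVector origin,
                               NumericVector src, NumericVector det_center,
                               NumericVector uhat, NumericVector vhat,
                               double pitch, int nrow, int ncol, double step_mm) {
  const int d1 = dims[0], d2 = dims[1], d3 = dims[2];
  const double* v = REAL(vol);
  double b0[3], b1[3];
  for (int a = 0; a < 3; ++a) {
    b0[a] = origin[a] - 0.5 * spacing[a];
    b1[a] = origin[a] + (dims[a] - 0.5) * spacing[a];
  }
  NumericMatrix out(nrow, ncol);
  const double rc0 = 0.5 * (nrow + 1), cc0 = 0.5 * (ncol + 1);
  double p0[3] = { src[0], src[1], src[2] };
  for (int c = 1; c <= ncol; ++c) {
    double uu = (c - cc0) * pitch;
    for (int r = 1; r <= nrow; ++r) {
      double vv = (r - rc0) * pitch;
      double p1[3], dir[3];
      for (int a = 0; a < 3; ++a) {
        p1[a] = det_center[a] + uu * uhat[a] + vv * vhat[a];
        dir[a] = p1[a] - p0[a];
      }
      double tmin, tmax;
      if (!ray_box(p0, dir, b0, b1, tmin, tmax)) { out(r - 1, c - 1) = 0.0; continue; }
      double L = std::sqrt(dir[0] * dir[0] + dir[1] * dir[1] + dir[2] * dir[2]);
      double span = (tmax - tmin) * L;         // mm inside the box
      long n = (long)std::ceil(span / step_mm);
      if (n < 1) n = 1;
      double h = span / n;                     // mm
      double ht = h / L;                       // parameter step
      double acc = 0.0;
      for (long s = 0; s < n; ++s) {
        double t = tmin + (s + 0.5) * ht;
        double xi = (p0[0] + t * dir[0] - origin[0]) / spacing[0];
        double yj = (p0[1] + t * dir[1] - origin[1]) / spacing[1];
        double zk = (p0[2] + t * dir[2] - origin[2]) / spacing[2];
        acc += trilerp_clamp(v, d1, d2, d3, xi, yj, zk, 0.0);
      }
      out(r - 1, c - 1) = acc * h;
    }
  }
  return out;
}

// Resample onto the same grid: out(x) = in(M x), M a 3x4 world->world map
// (the inverse of the rigid motion being applied).
// [[Rcpp::export]]
NumericVector cpp_resample(NumericVector vol, IntegerVector dims,
                           NumericVector spacing, NumericVector origin,
                           NumericMatrix M, double fill, bool nearest) {
  const int d1 = dims[0], d2 = dims[1], d3 = dims[2];
  const double* v = REAL(vol);
  NumericVector out((R_xlen_t)d1 * d2 * d3);
  double* o = REAL(out);
  R_xlen_t q = 0;
  for (int k = 0; k < d3; ++k) {
    double wz = origin[2] + k * spacing[2];
    for (int j = 0; j < d2; ++j) {
      double wy = origin[1] + j * spacing[1];
      for (int i = 0; i < d1; ++i, ++q) {
        double wx = origin[0] + i * spacing[0];
        double sx = M(0, 0) * wx + M(0, 1) * wy + M(0, 2) * wz + M(0, 3);
        double sy = M(1, 0) * wx + M(1, 1) * wy + M(1, 2) * wz + M(1, 3);
        double sz = M(2, 0) * wx + M(2, 1) * wy + M(2, 2) * wz + M(2, 3);
        double xi = (sx - origin[0]) / spacing[0];
        double yj = (sy - origin[1]) / spacing[1];
        double zk = (sz - origin[2]) / spacing[2];
        o[q] = nearest ? nearest_raw(v, d1, d2, d3, xi, yj, zk, fill)
                       : trilerp_raw(v, d1, d2, d3, xi, yj, zk, fill);
      }
    }
  }
  return out;
}

// Normalized cross-correlation between fixed values sampled at world points
// `pts` and the moving volume sampled at M * pts (M = inverse of candidate
// transform). Out-of-volume moving samples read 0 (bone-emphasis background).
// [[Rcpp::export]]
double cpp_ncc_points(NumericVector vol, IntegerVector dims,
                      NumericVector spacing, NumericVector origin,
                      NumericMatrix pts, NumericVector fixedvals,
                      NumericMatrix M) {
  const int d1 = dims[0], d2 = dims[1], d3 = dims[2];
  const double* v = REAL(vol);
  const R_xlen_t n = pts.nrow();
  double sa = 0, sb = 0, saa = 0, sbb = 0, sab = 0;
  for (R_xlen_t q = 0; q < n; ++q) {
    double wx = pts(q, 0), wy = pts(q, 1), wz = pts(q, 2);
    double sx = M(0, 0) * wx + M(0, 1) * wy + M(0, 2) * wz + M(0, 3);
    double sy = M(1, 0) * wx + M(1, 1) * wy + M(1, 2) * wz + M(1, 3);
    double sz = M(2, 0) * wx + M(2, 1) * wy + M(2, 2) * wz + M(2, 3);
    double a = fixedvals[q];
    double b = trilerp_raw(v, d1, d2, d3,
                           (sx - origin[0]) / spacing[0],
                           (sy - origin[1]) / spacing[1],
                           (sz - origin[2]) / spacing[2], 0.0);
    sa += a; sb += b; saa += a * a; sbb += b * b; sab += a * b;
  }
  double va = saa - sa * sa / n, vb = sbb - sb * sb / n;
  if (va <= 0 || vb <= 0) return NA_REAL;
  return (sab - sa * sb / n) / std::sqrt(va * vb);
}

// 6-connected component labelling of a binary volume; labels 1..K, 0 = off.
// [[Rcpp::export]]
IntegerVector cpp_label_components(LogicalVector mask, IntegerVector dims) {
  const int d1 = dims[0], d2 = dims[1], d3 = dims[2];
  const R_xlen_t n = (R_xlen_t)d1 * d2 * d3;
  IntegerVector lab(n, 0);
  const int* m = LOGICAL(mask);
  int* L = INTEGER(lab);
  int next = 0;
  std::vector<R_xlen_t> stack;
  const R_xlen_t s2 = d1, s3 = (R_xlen_t)d1 * d2;
  for (R_xlen_t start = 0; start < n; ++start) {
    if (m[start] != 1 || L[start] != 0) continue;
    ++next;
    stack.push_back(start);
    L[start] = next;
    while (!stack.empty()) {
      R_xlen_t q = stack.back();
      stack.pop_back();
      int i = (int)(q % d1);
      int j = (int)((q / d1) % d2);
      int k = (int)(q / s3);
      R_xlen_t nb[6];
      int nn = 0;
      if (i > 0) nb[nn++] = q - 1;
      if (i < d1 - 1) nb[nn++] = q + 1;
      if (j > 0) nb[nn++] = q - s2;
      if (j < d2 - 1) nb[nn++] = q + s2;
      if (k > 0) nb[nn++] = q - s3;
      if (k < d3 - 1) nb[nn++] = q + s3;
      for (int t = 0; t < nn; ++t) {
        R_xlen_t p = nb[t];
        if (m[p] == 1 && L[p] == 0) { L[p] = next; stack.push_back(p); }
      }
    }
  }
  return lab;
}

// Binary dilation (or erosion) with an explicit offset list (n x 3, voxels).
// [[Rcpp::export]]
LogicalVector cpp_morph(LogicalVector mask, IntegerVector dims,
                        IntegerMatrix offsets, bool dilate) {
  const int d1 = dims[0], d2 = dims[1], d3 = dims[2];
  const R_xlen_t n = (R_xlen_t)d1 * d2 * d3;
  LogicalVector out(n);
  const int* m = LOGICAL(mask);
  int* o = LOGICAL(out);
  const int no = offsets.nrow();
  R_xlen_t q = 0;
  for (int k = 0; k < d3; ++k)
    for (int j = 0; j < d2; ++j)
      for (int i = 0; i < d1; ++i, ++q) {
        bool acc = !dilate;
        for (int t = 0; t < no; ++t) {
          int ii = i + offsets(t, 0), jj = j + offsets(t, 1), kk = k + offsets(t, 2);
          bool val;
          if (ii < 0 || jj < 0 || kk < 0 || ii >= d1 || jj >= d2 || kk >= d3)
            val = false;  // outside counts as background
          else
            val = m[ii + (R_xlen_t)jj * d1 + (R_xlen_t)kk * d1 * d2] == 1;
          if (dilate) { if (val) { acc = true; break; } }
          else { if (!val) { acc = false; break; } }
        }
        o[q] = acc;
      }
  return out;
}

// Separable 1D convolution along one axis (1-based), reflecting at borders.
// [[Rcpp::export]]
NumericVector cpp_conv1d(NumericVector vol, IntegerVector dims,
                         NumericVector kernel, int axis) {
  const int d1 = dims[0], d2 = dims[1], d3 = dims[2];
  const int nk = kernel.size(), half = nk / 2;
  NumericVector out((R_xlen_t)d1 * d2 * d3);
  const double* v = REAL(vol);
  double* o = REAL(out);
  const R_xlen_t s[3] = { 1, d1, (R_xlen_t)d1 * d2 };
  const int dd[3] = { d1, d2, d3 };
  const int ax = axis - 1, na = dd[ax];
  R_xlen_t q = 0;
  for (int k = 0; k < d3; ++k)
    for (int j = 0; j < d2; ++j)
      for (int i = 0; i < d1; ++i, ++q) {
        int pos[3] = { i, j, k };
        double acc = 0.0;
        for (int t = 0; t < nk; ++t) {
          int p = pos[ax] + t - half;
          if (p < 0) p = -p - 1;            // reflect
          if (p > na - 1) p = 2 * na - 1 - p;
          acc += kernel[t] * v[q + ((R_xlen_t)p - pos[ax]) * s[ax]];
        }
        o[q] = acc;
      }
  return out;
}
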