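#include <Rcpp.h>
using namespace Rcpp;

// Shared conventions (see R/geometry.R):
//  - volumes are n x n x n arrays, column-major, x fastest; voxel centers at
//    integer indices; box center at 0-based index c = n/2.
//  - images are n x n matrices with x as the row index.
//  - a volume point q (centered, voxel units) appears in the projection at
//    (R q)_xy + shift; sampling is trilinear, zero outside the grid.

static inline int wrapi(int i, int n) {
  i %= n;
  return i < 0 ? i + n : i;
}

// wrap_z: treat the volume as periodic along z (an effectively infinite
// tube); x/y stay zero outside the grid.
static inline double trilinear(const double *vol, int n, double x, double y,
                               double z, int wrap_z) {
  if (!(x >= 0) || !(y >= 0) || x > n - 1 || y > n - 1) return 0.0;
  if (!std::isfinite(z)) return 0.0;
  if (!wrap_z && (z < 0 || z > n - 1)) return 0.0;
  int x0 = (int)std::floor(x), y0 = (int)std::floor(y), z0 = (int)std::floor(z);
  double fx = x - x0, fy = y - y0, fz = z - z0;
  int x1 = x0 + 1 < n ? x0 + 1 : x0;
  int y1 = y0 + 1 < n ? y0 + 1 : y0;
  int z1;
  if (wrap_z) {
    z0 = wrapi(z0, n);
    z1 = z0 + 1 < n ? z0 + 1 : 0;
  } else {
    z1 = z0 + 1 < n ? z0 + 1 : z0;
  }
  const size_t nn = (size_t)n * n;
  double c00 = vol[x0 + n * y0 + nn * z0] * (1 - fx) +
               vol[x1 + n * y0 + nn * z0] * fx;
  double c10 = vol[x0 + n * y1 + nn * z0] * (1 - fx) +
               vol[x1 + n * y1 + nn * z0] * fx;
  double c01 = vol[x0 + n * y0 + nn * z1] * (1 - fx) +
               vol[x1 + n * y0 + nn * z1] * fx;
  double c11 = vol[x0 + n * y1 + nn * z1] * (1 - fx) +
               vol[x1 + n * y1 + nn * z1] * fx;
  double c0 = c00 * (1 - fy) + c10 * fy;
  double c1 = c01 * (1 - fy) + c11 * fy;
  return c0 * (1 - fz) + c1 * fz;
}

// [[Rcpp::export]]
NumericMatrix cpp_project(NumericVector vol, int n, NumericMatrix R, double sx,
                          double sy, int wrap_z = 1) {
  NumericMatrix out(n, n);
  const double *v = vol.begin();
  const double c = n / 2;
  // rows of R^T are columns of R
  const double r00 = R(0, 0), r10 = R(1, 0), r20 = R(2, 0);
  const double r01 = R(0, 1), r11 = R(1, 1), r21 = R(2, 1);
  const double r02 = R(0, 2), r12 = R(1, 2), r22 = R(2, 2);
  for (int iy = 0; iy < n; ++iy) {
    double yv = iy - c - sy;
    for (int ix = 0; ix < n; ++ix) {
      double xv = ix - c - sx;
      double acc = 0.0;
      // partial sample position independent of depth
      double bx = r00 * xv + r10 * yv;
      double by = r01 * xv + r11 * yv;
      double bz = r02 * xv + r12 * yv;
      for (int iz = 0; iz < n; ++iz) {
        double w = iz - c;
        acc += trilinear(v, n, bx + r20 * w + c, by + r21 * w + c,
                         bz + r22 * w + c, wrap_z);
      }
      out(ix, iy) = acc;
    }
  }
  return out;
}

// Exact adjoint of cpp_project: smears image values back along the rays.
// [[Rcpp::export]]
void cpp_backproject_add(NumericVector vol, int n, NumericMatrix img,
                         NumericMatrix R, double sx, double sy,
                         int wrap_z = 1) {
  double *v = vol.begin();
  const double c = n / 2;
  const size_t nn = (size_t)n * n;
  const double r00 = R(0, 0), r10 = R(1, 0), r20 = R(2, 0);
  const double r01 = R(0, 1), r11 = R(1, 1), r21 = R(2, 1);
  const double r02 = R(0, 2), r12 = R(1, 2), r22 = R(2, 2);
  for (int iy = 0; iy < n; ++iy) {
    double yv = iy - c - sy;
    for (int ix = 0; ix < n; ++ix) {
      double w = img(ix, iy);
      if (w == 0.0) continue;
      double xv = ix - c - sx;
      double bx = r00 * xv + r10 * yv;
      double by = r01 * xv + r11 * yv;
      double bz = r02 * xv + r12 * yv;
      for (int iz = 0; iz < n; ++iz) {
        double d = iz - c;
        double x = bx + r20 * d + c;
        double y = by + r21 * d + c;
        double z = bz + r22 * d + c;
        if (!(x >= 0) || !(y >= 0) || x > n - 1 || y > n - 1) continue;
        if (!std::isfinite(z)) continue;
        if (!wrap_z && (z < 0 || z > n - 1)) continue;
        int x0 = (int)std::floor(x), y0 = (int)std::floor(y),
            z0 = (int)std::floor(z);
        double fx = x - x0, fy = y - y0, fz = z - z0;
        int x1 = x0 + 1 < n ? x0 + 1 : x0;
        int y1 = y0 + 1 < n ? y0 + 1 : y0;
        int z1;
        if (wrap_z) {
          z0 = wrapi(z0, n);
          z1 = z0 + 1 < n ? z0 + 1 : 0;
        } else {
          z1 = z0 + 1 < n ? z0 + 1 : z0;
        }
        v[x0 + n * y0 + nn * z0] += w * (1 - fx) * (1 - fy) * (1 - fz);
        v[x1 + n * y0 + nn * z0] += w * fx * (1 - fy) * (1 - fz);
        v[x0 + n * y1 + nn * z0] += w * (1 - fx) * fy * (1 - fz);
        v[x1 + n * y1 + nn * z0] += w * fx * fy * (1 - fz);
        v[x0 + n * y0 + nn * z1] += w * (1 - fx) * (1 - fy) * fz;
        v[x1 + n * y0 + nn * z1] += w * fx * (1 - fy) * fz;
        v[x0 + n * y1 + nn * z1] += w * (1 - fx) * fy * fz;
        v[x1 + n * y1 + nn * z1] += w * fx * fy * fz;
      }
    }
  }
}

static inline double bilinear_p(const double *img, int n, int m, double x,
                                double y) {
  if (!(x >= 0) || !(y >= 0) || x > n - 1 || y > m - 1) return 0.0;
  int x0 = (int)x, y0 = (int)y;
  int x1 = x0 + 1 < n ? x0 + 1 : x0;
  int y1 = y0 + 1 < m ? y0 + 1 : y0;
  double fx = x - x0, fy = y - y0;
  const double *c0 = img + (size_t)n * y0, *c1 = img + (size_t)n * y1;
  return (c0[x0] * (1 - fx) + c0[x1] * fx) * (1 - fy) +
         (c1[x0] * (1 - fx) + c1[x1] * fx) * fy;
}

// Rotate image content by angle_deg (counterclockwise in (x, y) index space)
// about the box center, bilinear, zero fill.
// [[Rcpp::export]]
NumericMatrix cpp_rotate_image(NumericMatrix img, double angle_deg) {
  int n = img.nrow(), m = img.ncol();
  NumericMatrix out(n, m);
  double a = angle_deg * M_PI / 180.0;
  double ca = std::cos(a), sa = std::sin(a);
  double cx = n / 2, cy = m / 2;
  const double *ip = img.begin();
  for (int iy = 0; iy < m; ++iy) {
    for (int ix = 0; ix < n; ++ix) {
      double x = ix - cx, y = iy - cy;
      // inverse rotation
      double xs = ca * x + sa * y + cx;
      double ys = -sa * x + ca * y + cy;
      out(ix, iy) = bilinear_p(ip, n, m, xs, ys);
    }
  }
  return out;
}

// Across-tube profiles: for each angle a, profile(x) = mean over y of the
// image rotated by -a (so a tube lying at angle a from the y axis becomes
// vertical and collapses onto x).
// [[Rcpp::export]]
NumericMatrix cpp_tube_profiles(NumericMatrix img, NumericVector angles_deg) {
  int n = img.nrow(), m = img.ncol();
  int na = angles_deg.size();
  NumericMatrix out(n, na);
  double cx = n / 2, cy = m / 2;
  for (int k = 0; k < na; ++k) {
    double a = angles_deg[k] * M_PI / 180.0;
    double ca = std::cos(a), sa = std::sin(a);
    const double *ip = img.begin();
    for (int ix = 0; ix < n; ++ix) {
      double acc = 0.0;
      double x = ix - cx;
      // sample original image along the forward rotation of the column
      double bx = ca * x - sa * (0 - cy) + cx;
      double by = sa * x + ca * (0 - cy) + cy;
      for (int iy = 0; iy < m; ++iy) {
        acc += bilinear_p(ip, n, m, bx, by);
        bx -= sa;
        by += ca;
      }
      out(ix, k) = acc / m;
    }
  }
  return out;
}

// Resample volume under the affine map: out(p) = vol(A (p - c) + t + c),
// p in voxel units.  Used for helical lattice self-correlation.
// [[Rcpp::export]]
NumericVector cpp_affine_volume(NumericVector vol, int n, NumericMatrix A,
                                NumericVector t) {
  NumericVector out((R_xlen_t)n * n * n);
  const double *v = vol.begin();
  double *o = out.begin();
  const double c = n / 2;
  const size_t nn = (size_t)n * n;
  for (int iz = 0; iz < n; ++iz) {
    double z = iz - c;
    for (int iy = 0; iy < n; ++iy) {
      double y = iy - c;
      for (int ix = 0; ix < n; ++ix) {
        double x = ix - c;
        double xs = A(0, 0) * x + A(0, 1) * y + A(0, 2) * z + t[0] + c;
        double ys = A(1, 0) * x + A(1, 1) * y + A(1, 2) * z + t[1] + c;
        double zs = A(2, 0) * x + A(2, 1) * y + A(2, 2) * z + t[2] + c;
        o[ix + n * iy + nn * iz] = trilinear(v, n, xs, ys, zs, 0);
      }
    }
  }
  return out;
}

// Add a separable Gaussian blob in place; center in voxel units (0-based).
// [[Rcpp::export]]
void cpp_add_blob(NumericVector vol, int n, double cx, double cy, double cz,
                  double sigma_vox, double amplitude) {
  double *v = vol.begin();
  const size_t nn = (size_t)n * n;
  int h = (int)std::ceil(3.0 * sigma_vox);
  int x0 = std::max(0, (int)std::floor(cx - h)),
      x1 = std::min(n - 1, (int)std::ceil(cx + h));
  int y0 = std::max(0, (int)std::floor(cy - h)),
      y1 = std::min(n - 1, (int)std::ceil(cy + h));
  int z0 = std::max(0, (int)std::floor(cz - h)),
      z1 = std::min(n - 1, (int)std::ceil(cz + h));
  double s2 = 2.0 * sigma_vox * sigma_vox;
  for (int iz = z0; iz <= z1; ++iz) {
    double gz = std::exp(-(iz - cz) * (iz - cz) / s2);
    for (int iy = y0; iy <= y1; ++iy) {
      double gyz = amplitude * gz * std::exp(-(iy - cy) * (iy - cy) / s2);
      for (int ix = x0; ix <= x1; ++ix)
        v[ix + n * iy + nn * iz] += gyz * std::exp(-(ix - cx) * (ix - cx) / s2);
    }
  }
}

// Soft-edged spherical mask: 1 inside (radius - soft), cosine falloff to 0
// at radius; center and radii in voxel units (0-based center).
// [[Rcpp::export]]
NumericVector cpp_sphere_mask(int n, double cx, double cy, double cz,
                              double r_vox, double soft_vox) {
  NumericVector out((R_xlen_t)n * n * n);
  double *o = out.begin();
  const size_t nn = (size_t)n * n;
  double r_in = r_vox - soft_vox;
  for (int iz = 0; iz < n; ++iz) {
    double dz = (iz - cz) * (iz - cz);
    for (int iy = 0; iy < n; ++iy) {
      double dyz = dz + (iy - cy) * (iy - cy);
      for (int ix = 0; ix < n; ++ix) {
        double d = std::sqrt(dyz + (ix - cx) * (ix - cx));
        double v;
        if (d <= r_in) v = 1.0;
        else if (d >= r_vox) v = 0.0;
        else v = 0.5 * (1.0 + std::cos(M_PI * (d - r_in) / soft_vox));
        o[ix + n * iy + nn * iz] = v;
      }
    }
  }
  return out;
}
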