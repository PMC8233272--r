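// Low-level volumetric kernels.
//
// Array convention (shared with the R layer): volumes are R arrays with
// dim = c(nz, ny, nx); the first (fastest-varying) index is z. A voxel
// (z, y, x), 0-based here, sits at linear offset z + nz*(y + ny*x).
// Displacement fields carry a trailing component dimension of length 3
// ordered (z, y, x), i.e. dim = c(nz, ny, nx, 3); component c of voxel i
// is at offset i + c*nvox. Fields are in voxel units of the grid they
// live on and follow the pull-back (resampling) convention:
// out(x) = vol(x + u(x)).

#include <Rcpp.h>
#include <queue>
#include <vector>
#include <array>
#include <cmath>
#include <cstdint>

using namespace Rcpp;

static inline double getv(const double* v, int nz, int ny, int nx,
                          int z, int y, int x) {
  return v[(size_t)z + (size_t)nz * ((size_t)y + (size_t)ny * (size_t)x)];
}

// trilinear with zero value outside the domain
static double sample_lin0(const double* v, int nz, int ny, int nx,
                          double z, double y, double x) {
  int z0 = (int)std::floor(z), y0 = (int)std::floor(y), x0 = (int)std::floor(x);
  double fz = z - z0, fy = y - y0, fx = x - x0;
  double acc = 0.0;
  for (int dz = 0; dz < 2; ++dz) {
    int zz = z0 + dz; if (zz < 0 || zz >= nz) continue;
    double wz = dz ? fz : 1.0 - fz; if (wz == 0.0) continue;
    for (int dy = 0; dy < 2; ++dy) {
      int yy = y0 + dy; if (yy < 0 || yy >= ny) continue;
      double wy = dy ? fy : 1.0 - fy; if (wy == 0.0) continue;
      for (int dx = 0; dx < 2; ++dx) {
        int xx = x0 + dx; if (xx < 0 || xx >= nx) continue;
        double wx = dx ? fx : 1.0 - fx; if (wx == 0.0) continue;
        acc += wz * wy * wx * getv(v, nz, ny, nx, zz, yy, xx);
      }
    }
  }
  return acc;
}

// trilinear with coordinates clamped to the domain (edge extension)
static double sample_linc(const double* v, int nz, int ny, int nx,
                          double z, double y, double x) {
  if (z < 0) z = 0; if (z > nz - 1) z = nz - 1;
  if (y < 0) y = 0; if (y > ny - 1) y = ny - 1;
  if (x < 0) x = 0; if (x > nx - 1) x = nx - 1;
  return sample_lin0(v, nz, ny, nx, z, y, x);
}

static double sample_near0(const double* v, int nz, int ny, int nx,
                           double z, double y, double x) {
  int zz = (int)std::floor(z + 0.5), yy = (int)std::floor(y + 0.5),
      xx = (int)std::floor(x + 0.5);
  if (zz < 0 || zz >= nz || yy < 0 || yy >= ny || xx < 0 || xx >= nx) return 0.0;
  return getv(v, nz, ny, nx, zz, yy, xx);
}

// [[Rcpp::export]]
NumericVector cpp_sample_affine(NumericVector vol, IntegerVector dim,
                                NumericVector A, NumericVector t,
                                IntegerVector odim, int mode) {
  int nz = dim[0], ny = dim[1], nx = dim[2];
  int oz = odim[0], oy = odim[1], ox = odim[2];
  const double* v = vol.begin();
  NumericVector out((size_t)oz * oy * ox);
  double* o = out.begin();
  size_t i = 0;
  for (int x = 0; x < ox; ++x)
    for (int y = 0; y < oy; ++y)
      for (int z = 0; z < oz; ++z) {
        double sz = A[0] * z + A[1] * y + A[2] * x + t[0];
        double sy = A[3] * z + A[4] * y + A[5] * x + t[1];
        double sx = A[6] * z + A[7] * y + A[8] * x + t[2];
        // filled column-major over (z fastest): recompute offset explicitly
        i = (size_t)z + (size_t)oz * ((size_t)y + (size_t)oy * (size_t)x);
        o[i] = (mode == 0) ? sample_lin0(v, nz, ny, nx, sz, sy, sx)
                           : sample_near0(v, nz, ny, nx, sz, sy, sx);
      }
  out.attr("dim") = odim;
  return out;
}

// [[Rcpp::export]]
NumericVector cpp_sample_field(NumericVector vol, IntegerVector dim,
                               NumericVector u, int mode) {
  int nz = dim[0], ny = dim[1], nx = dim[2];
  size_t nvox = (size_t)nz * ny * nx;
  const double* v = vol.begin();
  const double* uu = u.begin();
  NumericVector out(nvox);
  double* o = out.begin();
  for (int x = 0; x < nx; ++x)
    for (int y = 0; y < ny; ++y)
      for (int z = 0; z < nz; ++z) {
        size_t i = (size_t)z + (size_t)nz * ((size_t)y + (size_t)ny * (size_t)x);
        double sz = z + uu[i];
        double sy = y + uu[i + nvox];
        double sx = x + uu[i + 2 * nvox];
        o[i] = (mode == 0) ? sample_lin0(v, nz, ny, nx, sz, sy, sx)
                           : sample_near0(v, nz, ny, nx, sz, sy, sx);
      }
  out.attr("dim") = dim;
  return out;
}

// [[Rcpp::export]]
NumericVector cpp_affine_field(NumericVector A, NumericVector t,
                               IntegerVector dim) {
  int nz = dim[0], ny = dim[1], nx = dim[2];
  size_t nvox = (size_t)nz * ny * nx;
  NumericVector out(nvox * 3);
  double* o = out.begin();
  for (int x = 0; x < nx; ++x)
    for (int y = 0; y < ny; ++y)
      for (int z = 0; z < nz; ++z) {
        size_t i = (size_t)z + (size_t)nz * ((size_t)y + (size_t)ny * (size_t)x);
        o[i]            = A[0] * z + A[1] * y + A[2] * x + t[0] - z;
        o[i + nvox]     = A[3] * z + A[4] * y + A[5] * x + t[1] - y;
        o[i + 2 * nvox] = A[6] * z + A[7] * y + A[8] * x + t[2] - x;
      }
  out.attr("dim") = IntegerVector::create(nz, ny, nx, 3);
  return out;
}

// composition c = a(b(x)): uc(x) = ub(x) + ua(x + ub(x)); ua sampled clamped
// [[Rcpp::export]]
NumericVector cpp_compose_fields(NumericVector ua, NumericVector ub,
                                 IntegerVector dim) {
  int nz = dim[0], ny = dim[1], nx = dim[2];
  size_t nvox = (size_t)nz * ny * nx;
  const double* a = ua.begin();
  const double* b = ub.begin();
  NumericVector out(nvox * 3);
  double* o = out.begin();
  for (int x = 0; x < nx; ++x)
    for (int y = 0; y < ny; ++y)
      for (int z = 0; z < nz; ++z) {
        size_t i = (size_t)z + (size_t)nz * ((size_t)y + (size_t)ny * (size_t)x);
        double sz = z + b[i], sy = y + b[i + nvox], sx = x + b[i + 2 * nvox];
        o[i]            = b[i]            + sample_linc(a,            nz, ny, nx, sz, sy, sx);
        o[i + nvox]     = b[i + nvox]     + sample_linc(a + nvox,     nz, ny, nx, sz, sy, sx);
        o[i + 2 * nvox] = b[i + 2 * nvox] + sample_linc(a + 2 * nvox, nz, ny, nx, sz, sy, sx);
      }
  out.attr("dim") = IntegerVector::create(nz, ny, nx, 3);
  return out;
}

// fixed-point inverse: v(x) = -u(x + v(x))
// [[Rcpp::export]]
List cpp_invert_field(NumericVector u, IntegerVector dim, int iters,
                      double tol) {
  int nz = dim[0], ny = dim[1], nx = dim[2];
  size_t nvox = (size_t)nz * ny * nx;
  const double* uu = u.begin();
  NumericVector v(nvox * 3);
  double* vv = v.begin();
  double maxchg = 0.0;
  for (int it = 0; it < iters; ++it) {
    maxchg = 0.0;
    for (int x = 0; x < nx; ++x)
      for (int y = 0; y < ny; ++y)
        for (int z = 0; z < nz; ++z) {
          size_t i = (size_t)z + (size_t)nz * ((size_t)y + (size_t)ny * (size_t)x);
          double sz = z + vv[i], sy = y + vv[i + nvox], sx = x + vv[i + 2 * nvox];
          double nzv = -sample_linc(uu,            nz, ny, nx, sz, sy, sx);
          double nyv = -sample_linc(uu + nvox,     nz, ny, nx, sz, sy, sx);
          double nxv = -sample_linc(uu + 2 * nvox, nz, ny, nx, sz, sy, sx);
          double chg = std::fabs(nzv - vv[i]) + std::fabs(nyv - vv[i + nvox]) +
                       std::fabs(nxv - vv[i + 2 * nvox]);
          if (chg > maxchg) maxchg = chg;
          vv[i] = nzv; vv[i + nvox] = nyv; vv[i + 2 * nvox] = nxv;
        }
    if (maxchg < tol) break;
  }
  v.attr("dim") = IntegerVector::create(nz, ny, nx, 3);
  return List::create(_["field"] = v, _["max_residual_step"] = maxchg);
}

// separable Gaussian, reflecting boundary; sigma per axis in voxels
static void gauss1d(std::vector<double>& buf, std::vector<double>& tmp,
                    const std::vector<double>& k, int n, int r) {
  for (int i = 0; i < n; ++i) {
    double acc = 0.0;
    for (int j = -r; j <= r; ++j) {
      int p = i + j;
      while (p < 0 || p >= n) {   // repeated reflection for wide kernels
        if (p < 0) p = -p - 1;
        if (p >= n) p = 2 * n - p - 1;
      }
      acc += k[j + r] * buf[p];
    }
    tmp[i] = acc;
  }
  for (int i = 0; i < n; ++i) buf[i] = tmp[i];
}

// [[Rcpp::export]]
NumericVector cpp_gauss3(NumericVector vol, IntegerVector dim,
                         NumericVector sigma) {
  int nz = dim[0], ny = dim[1], nx = dim[2];
  NumericVector out = clone(vol);
  double* o = out.begin();
  int n[3] = {nz, ny, nx};
  for (int ax = 0; ax < 3; ++ax) {
    double s = sigma[ax];
    if (s <= 0) continue;
    int r = (int)std::ceil(3.0 * s);
    if (r < 1) r = 1;
    std::vector<double> k(2 * r + 1);
    double tot = 0.0;
    for (int j = -r; j <= r; ++j) { k[j + r] = std::exp(-0.5 * j * j / (s * s)); tot += k[j + r]; }
    for (auto& w : k) w /= tot;
    std::vector<double> buf(n[ax]), tmp(n[ax]);
    if (ax == 0) {
      for (int x = 0; x < nx; ++x)
        for (int y = 0; y < ny; ++y) {
          size_t base = (size_t)nz * ((size_t)y + (size_t)ny * (size_t)x);
          for (int z = 0; z < nz; ++z) buf[z] = o[base + z];
          gauss1d(buf, tmp, k, nz, r);
          for (int z = 0; z < nz; ++z) o[base + z] = buf[z];
        }
    } else if (ax == 1) {
      for (int x = 0; x < nx; ++x)
        for (int z = 0; z < nz; ++z) {
          size_t base = (size_t)z + (size_t)nz * (size_t)ny * (size_t)x;
          for (int y = 0; y < ny; ++y) buf[y] = o[base + (size_t)nz * y];
          gauss1d(buf, tmp, k, ny, r);
          for (int y = 0; y < ny; ++y) o[base + (size_t)nz * y] = buf[y];
        }
    } else {
      size_t stride = (size_t)nz * ny;
      for (int y = 0; y < ny; ++y)
        for (int z = 0; z < nz; ++z) {
          size_t base = (size_t)z + (size_t)nz * y;
          for (int x = 0; x < nx; ++x) buf[x] = o[base + stride * x];
          gauss1d(buf, tmp, k, nx, r);
          for (int x = 0; x < nx; ++x) o[base + stride * x] = buf[x];
        }
    }
  }
  out.attr("dim") = dim;
  return out;
}

// joint histogram with linear (tent) binning; returns nbins x nbins counts
// [[Rcpp::export]]
NumericMatrix cpp_joint_hist(NumericVector a, NumericVector b, int nbins,
                             double amin, double amax, double bmin,
                             double bmax) {
  NumericMatrix h(nbins, nbins);
  double as = (nbins - 1) / std::max(amax - amin, 1e-12);
  double bs = (nbins - 1) / std::max(bmax - bmin, 1e-12);
  size_t n = a.size();
  for (size_t i = 0; i < n; ++i) {
    double av = (a[i] - amin) * as, bv = (b[i] - bmin) * bs;
    if (av < 0) av = 0; if (av > nbins - 1) av = nbins - 1;
    if (bv < 0) bv = 0; if (bv > nbins - 1) bv = nbins - 1;
    int a0 = (int)av, b0 = (int)bv;
    if (a0 > nbins - 2) a0 = nbins - 2;
    if (b0 > nbins - 2) b0 = nbins - 2;
    double fa = av - a0, fb = bv - b0;
    h(a0, b0)         += (1 - fa) * (1 - fb);
    h(a0 + 1, b0)     += fa * (1 - fb);
    h(a0, b0 + 1)     += (1 - fa) * fb;
    h(a0 + 1, b0 + 1) += fa * fb;
  }
  return h;
}

// MI-ascent force: F(x) = dL/d(moving intensity) * grad(warped moving)(x),
// L = pointwise log p_fm/(p_f p_m) table over (fixed-bin, moving-bin)
// [[Rcpp::export]]
NumericVector cpp_mi_force(NumericVector fixedv, NumericVector warped,
                           IntegerVector dim, NumericMatrix L, double amin,
                           double amax, double bmin, double bmax) {
  int nz = dim[0], ny = dim[1], nx = dim[2];
  size_t nvox = (size_t)nz * ny * nx;
  int nbins = L.nrow();
  double as = (nbins - 1) / std::max(amax - amin, 1e-12);
  double bs = (nbins - 1) / std::max(bmax - bmin, 1e-12);
  const double* f = fixedv.begin();
  const double* w = warped.begin();
  NumericVector out(nvox * 3);
  double* o = out.begin();
  for (int x = 0; x < nx; ++x)
    for (int y = 0; y < ny; ++y)
      for (int z = 0; z < nz; ++z) {
        size_t i = (size_t)z + (size_t)nz * ((size_t)y + (size_t)ny * (size_t)x);
        double av = (f[i] - amin) * as, bv = (w[i] - bmin) * bs;
        if (av < 0) av = 0; if (av > nbins - 1) av = nbins - 1;
        if (bv < 0) bv = 0; if (bv > nbins - 1) bv = nbins - 1;
        int a0 = (int)av; if (a0 > nbins - 2) a0 = nbins - 2;
        int b0 = (int)bv; if (b0 > nbins - 2) b0 = nbins - 2;
        double fa = av - a0;
        // dL/d(bin_b) by forward difference at the two bracketing a-bins
        double d0 = L(a0, b0 + 1) - L(a0, b0);
        double d1 = L(a0 + 1, b0 + 1) - L(a0 + 1, b0);
        double dLdb = ((1 - fa) * d0 + fa * d1) * bs; // per intensity unit
        // central-difference gradient of warped moving, clamped at borders
        int zm = z > 0 ? z - 1 : z, zp = z < nz - 1 ? z + 1 : z;
        int ym = y > 0 ? y - 1 : y, yp = y < ny - 1 ? y + 1 : y;
        int xm = x > 0 ? x - 1 : x, xp = x < nx - 1 ? x + 1 : x;
        double gz = (getv(w, nz, ny, nx, zp, y, x) - getv(w, nz, ny, nx, zm, y, x)) / (zp - zm > 0 ? zp - zm : 1);
        double gy = (getv(w, nz, ny, nx, z, yp, x) - getv(w, nz, ny, nx, z, ym, x)) / (yp - ym > 0 ? yp - ym : 1);
        double gx = (getv(w, nz, ny, nx, z, y, xp) - getv(w, nz, ny, nx, z, y, xm)) / (xp - xm > 0 ? xp - xm : 1);
        o[i] = dLdb * gz;
        o[i + nvox] = dLdb * gy;
        o[i + 2 * nvox] = dLdb * gx;
      }
  out.attr("dim") = IntegerVector::create(nz, ny, nx, 3);
  return out;
}

// cubic B-spline FFD: weights for fractional offset w over 4 support points
static inline void bw4(double w, double* b) {
  double w2 = w * w, w3 = w2 * w;
  b[0] = (1 - 3 * w + 3 * w2 - w3) / 6.0;
  b[1] = (4 - 6 * w2 + 3 * w3) / 6.0;
  b[2] = (1 + 3 * w + 3 * w2 - 3 * w3) / 6.0;
  b[3] = w3 / 6.0;
}

struct BTab {
  std::vector<int> i0;       // first control index per voxel
  std::vector<double> w;     // 4 weights per voxel
};

static BTab btab(int n, double origin, double spacing, int nc) {
  BTab t; t.i0.resize(n); t.w.resize(4 * (size_t)n);
  for (int p = 0; p < n; ++p) {
    double s = (p - origin) / spacing;
    int i = (int)std::floor(s);
    double f = s - i;
    bw4(f, &t.w[4 * (size_t)p]);
    t.i0[p] = i - 1; // support: i-1 .. i+2, clamped at use site
  }
  (void)nc;
  return t;
}

static inline int clampi(int v, int lo, int hi) {
  return v < lo ? lo : (v > hi ? hi : v);
}

// coef: length 3 * ncz*ncy*ncx, component-major like fields
// [[Rcpp::export]]
NumericVector cpp_bspline_densify(NumericVector coef, IntegerVector cdim,
                                  NumericVector origin, NumericVector spacing,
                                  IntegerVector dim) {
  int nz = dim[0], ny = dim[1], nx = dim[2];
  int cz = cdim[0], cy = cdim[1], cx = cdim[2];
  size_t ncp = (size_t)cz * cy * cx;
  size_t nvox = (size_t)nz * ny * nx;
  const double* c = coef.begin();
  BTab tz = btab(nz, origin[0], spacing[0], cz);
  BTab ty = btab(ny, origin[1], spacing[1], cy);
  BTab tx = btab(nx, origin[2], spacing[2], cx);
  NumericVector out(nvox * 3);
  double* o = out.begin();
  for (int x = 0; x < nx; ++x) {
    const double* wx = &tx.w[4 * (size_t)x];
    int xi0 = tx.i0[x];
    for (int y = 0; y < ny; ++y) {
      const double* wy = &ty.w[4 * (size_t)y];
      int yi0 = ty.i0[y];
      for (int z = 0; z < nz; ++z) {
        const double* wz = &tz.w[4 * (size_t)z];
        int zi0 = tz.i0[z];
        double az = 0, ay = 0, axv = 0;
        for (int dx = 0; dx < 4; ++dx) {
          int xc = clampi(xi0 + dx, 0, cx - 1);
          for (int dy = 0; dy < 4; ++dy) {
            int yc = clampi(yi0 + dy, 0, cy - 1);
            double wxy = wx[dx] * wy[dy];
            size_t base = (size_t)cz * ((size_t)yc + (size_t)cy * (size_t)xc);
            for (int dz = 0; dz < 4; ++dz) {
              int zc = clampi(zi0 + dz, 0, cz - 1);
              double wt = wxy * wz[dz];
              size_t ci = base + zc;
              az += wt * c[ci];
              ay += wt * c[ci + ncp];
              axv += wt * c[ci + 2 * ncp];
            }
          }
        }
        size_t i = (size_t)z + (size_t)nz * ((size_t)y + (size_t)ny * (size_t)x);
        o[i] = az; o[i + nvox] = ay; o[i + 2 * nvox] = axv;
      }
    }
  }
  out.attr("dim") = IntegerVector::create(nz, ny, nx, 3);
  return out;
}

// adjoint of densify: project a dense force field onto control-point grads
// [[Rcpp::export]]
NumericVector cpp_bspline_splat(NumericVector force, IntegerVector dim,
                                IntegerVector cdim, NumericVector origin,
                                NumericVector spacing) {
  int nz = dim[0], ny = dim[1], nx = dim[2];
  int cz = cdim[0], cy = cdim[1], cx = cdim[2];
  size_t ncp = (size_t)cz * cy * cx;
  size_t nvox = (size_t)nz * ny * nx;
  const double* f = force.begin();
  BTab tz = btab(nz, origin[0], spacing[0], cz);
  BTab ty = btab(ny, origin[1], spacing[1], cy);
  BTab tx = btab(nx, origin[2], spacing[2], cx);
  NumericVector out(ncp * 3);
  double* o = out.begin();
  for (int x = 0; x < nx; ++x) {
    const double* wx = &tx.w[4 * (size_t)x];
    int xi0 = tx.i0[x];
    for (int y = 0; y < ny; ++y) {
      const double* wy = &ty.w[4 * (size_t)y];
      int yi0 = ty.i0[y];
      for (int z = 0; z < nz; ++z) {
        size_t i = (size_t)z + (size_t)nz * ((size_t)y + (size_t)ny * (size_t)x);
        double fz = f[i], fy = f[i + nvox], fxv = f[i + 2 * nvox];
        if (fz == 0 && fy == 0 && fxv == 0) continue;
        const double* wz = &tz.w[4 * (size_t)z];
        int zi0 = tz.i0[z];
        for (int dx = 0; dx < 4; ++dx) {
          int xc = clampi(xi0 + dx, 0, cx - 1);
          for (int dy = 0; dy < 4; ++dy) {
            int yc = clampi(yi0 + dy, 0, cy - 1);
            double wxy = wx[dx] * wy[dy];
            size_t base = (size_t)cz * ((size_t)yc + (size_t)cy * (size_t)xc);
            for (int dz = 0; dz < 4; ++dz) {
              int zc = clampi(zi0 + dz, 0, cz - 1);
              double wt = wxy * wz[dz];
              size_t ci = base + zc;
              o[ci] += wt * fz;
              o[ci + ncp] += wt * fy;
              o[ci + 2 * ncp] += wt * fxv;
            }
          }
        }
      }
    }
  }
  out.attr("dim") = IntegerVector::create(cz, cy, cx, 3);
  return out;
}

// local maxima of a moving cube filter: a voxel is a seed iff it is > 0,
// equals the cube max (cube truncated at borders), and is the
// lexicographically-first (z, y, x) voxel of its plateau component
// (26-connected equal-valued cube-max voxels)
// [[Rcpp::export]]
IntegerMatrix cpp_local_maxima(NumericVector vol, IntegerVector dim,
                               IntegerVector cube) {
  int nz = dim[0], ny = dim[1], nx = dim[2];
  int rz = cube[0] / 2, ry = cube[1] / 2, rx = cube[2] / 2;
  const double* v = vol.begin();
  size_t nvox = (size_t)nz * ny * nx;
  std::vector<char> cand(nvox, 0);
  for (int x = 0; x < nx; ++x)
    for (int y = 0; y < ny; ++y)
      for (int z = 0; z < nz; ++z) {
        size_t i = (size_t)z + (size_t)nz * ((size_t)y + (size_t)ny * (size_t)x);
        double val = v[i];
        if (val <= 0) continue;
        bool ismax = true;
        for (int dx = -rx; dx <= rx && ismax; ++dx) {
          int xx = x + dx; if (xx < 0 || xx >= nx) continue;
          for (int dy = -ry; dy <= ry && ismax; ++dy) {
            int yy = y + dy; if (yy < 0 || yy >= ny) continue;
            for (int dz = -rz; dz <= rz; ++dz) {
              int zz = z + dz; if (zz < 0 || zz >= nz) continue;
              if (getv(v, nz, ny, nx, zz, yy, xx) > val) { ismax = false; break; }
            }
          }
        }
        if (ismax) cand[i] = 1;
      }
  // lexicographic (z, y, x) scan; BFS over equal-valued candidate plateaus
  std::vector<char> visited(nvox, 0);
  std::vector<std::array<int, 3>> seeds;
  for (int z = 0; z < nz; ++z)
    for (int y = 0; y < ny; ++y)
      for (int x = 0; x < nx; ++x) {
        size_t i = (size_t)z + (size_t)nz * ((size_t)y + (size_t)ny * (size_t)x);
        if (!cand[i] || visited[i]) continue;
        seeds.push_back({z, y, x});
        double val = v[i];
        std::vector<size_t> stack{i};
        visited[i] = 1;
        std::vector<std::array<int, 3>> coords{{z, y, x}};
        while (!stack.empty()) {
          size_t cur = stack.back(); stack.pop_back();
          std::array<int, 3> cc = coords.back(); coords.pop_back();
          (void)cur;
          for (int dx = -1; dx <= 1; ++dx)
            for (int dy = -1; dy <= 1; ++dy)
              for (int dz = -1; dz <= 1; ++dz) {
                if (!dx && !dy && !dz) continue;
                int zz = cc[0] + dz, yy = cc[1] + dy, xx = cc[2] + dx;
                if (zz < 0 || zz >= nz || yy < 0 || yy >= ny || xx < 0 || xx >= nx) continue;
                size_t j = (size_t)zz + (size_t)nz * ((size_t)yy + (size_t)ny * (size_t)xx);
                if (cand[j] && !visited[j] && v[j] == val) {
                  visited[j] = 1;
                  stack.push_back(j);
                  coords.push_back({zz, yy, xx});
                }
              }
        }
      }
  IntegerMatrix out(seeds.size(), 3);
  for (size_t k = 0; k < seeds.size(); ++k) {
    out(k, 0) = seeds[k][0]; out(k, 1) = seeds[k][1]; out(k, 2) = seeds[k][2];
  }
  return out;
}

// seeded watershed by priority flood on inverted intensity, restricted to
// {vol >= cutoff}, 26-connected, FIFO tie-break for determinism
struct QItem {
  double val; uint64_t order; size_t idx; int label;
};
struct QCmp {
  bool operator()(const QItem& a, const QItem& b) const {
    if (a.val != b.val) return a.val < b.val;   // higher intensity first
    return a.order > b.order;                    // then FIFO
  }
};

// [[Rcpp::export]]
IntegerVector cpp_watershed(NumericVector vol, IntegerVector dim,
                            IntegerMatrix seeds, double cutoff) {
  int nz = dim[0], ny = dim[1], nx = dim[2];
  size_t nvox = (size_t)nz * ny * nx;
  const double* v = vol.begin();
  IntegerVector lab(nvox);
  std::priority_queue<QItem, std::vector<QItem>, QCmp> q;
  uint64_t order = 0;
  for (int k = 0; k < seeds.nrow(); ++k) {
    int z = seeds(k, 0), y = seeds(k, 1), x = seeds(k, 2);
    size_t i = (size_t)z + (size_t)nz * ((size_t)y + (size_t)ny * (size_t)x);
    if (v[i] < cutoff) continue;
    if (lab[i] != 0) continue;
    lab[i] = k + 1;
    q.push({v[i], order++, i, k + 1});
  }
  while (!q.empty()) {
    QItem it = q.top(); q.pop();
    int z = (int)(it.idx % nz);
    int rem = (int)(it.idx / nz);
    int y = rem % ny, x = rem / ny;
    for (int dx = -1; dx <= 1; ++dx)
      for (int dy = -1; dy <= 1; ++dy)
        for (int dz = -1; dz <= 1; ++dz) {
          if (!dx && !dy && !dz) continue;
          int zz = z + dz, yy = y + dy, xx = x + dx;
          if (zz < 0 || zz >= nz || yy < 0 || yy >= ny || xx < 0 || xx >= nx) continue;
          size_t j = (size_t)zz + (size_t)nz * ((size_t)yy + (size_t)ny * (size_t)xx);
          if (lab[j] != 0 || v[j] < cutoff) continue;
          lab[j] = it.label;
          q.push({v[j], order++, j, it.label});
        }
  }
  lab.attr("dim") = dim;
  return lab;
}

// [[Rcpp::export]]
NumericVector cpp_block_mean(NumericVector vol, IntegerVector dim,
                             IntegerVector f) {
  int nz = dim[0], ny = dim[1], nx = dim[2];
  int fz = f[0], fy = f[1], fx = f[2];
  int oz = nz / fz, oy = ny / fy, ox = nx / fx;
  const double* v = vol.begin();
  NumericVector out((size_t)oz * oy * ox);
  double* o = out.begin();
  double inv = 1.0 / ((double)fz * fy * fx);
  for (int x = 0; x < ox; ++x)
    for (int y = 0; y < oy; ++y)
      for (int z = 0; z < oz; ++z) {
        double acc = 0;
        for (int dx = 0; dx < fx; ++dx)
          for (int dy = 0; dy < fy; ++dy)
            for (int dz = 0; dz < fz; ++dz)
              acc += getv(v, nz, ny, nx, z * fz + dz, y * fy + dy, x * fx + dx);
        o[(size_t)z + (size_t)oz * ((size_t)y + (size_t)oy * (size_t)x)] = acc * inv;
      }
  out.attr("dim") = IntegerVector::create(oz, oy, ox);
  return out;
}

// add a closed ball of value 1 around each center (voxel-center distance
// <= radius, physical units via spacing); centers outside volume skipped
// [[Rcpp::export]]
List cpp_sphere_splat(NumericMatrix centers, IntegerVector dim,
                      double radius_vox) {
  int nz = dim[0], ny = dim[1], nx = dim[2];
  NumericVector out((size_t)nz * ny * nx);
  double* o = out.begin();
  int r = (int)std::floor(radius_vox + 1.0); // box pad for fractional centers
  int skipped = 0;
  for (int k = 0; k < centers.nrow(); ++k) {
    double cz = centers(k, 0), cy = centers(k, 1), cx = centers(k, 2);
    int iz = (int)std::floor(cz + 0.5), iy = (int)std::floor(cy + 0.5),
        ix = (int)std::floor(cx + 0.5);
    if (iz < 0 || iz >= nz || iy < 0 || iy >= ny || ix < 0 || ix >= nx) {
      ++skipped; continue;
    }
    for (int dx = -r; dx <= r; ++dx)
      for (int dy = -r; dy <= r; ++dy)
        for (int dz = -r; dz <= r; ++dz) {
          int zz = iz + dz, yy = iy + dy, xx = ix + dx;
          if (zz < 0 || zz >= nz || yy < 0 || yy >= ny || xx < 0 || xx >= nx) continue;
          double d2 = (zz - cz) * (zz - cz) + (yy - cy) * (yy - cy) +
                      (xx - cx) * (xx - cx);
          if (d2 <= radius_vox * radius_vox + 1e-9)
            o[(size_t)zz + (size_t)nz * ((size_t)yy + (size_t)ny * (size_t)xx)] += 1.0;
        }
  }
  out.attr("dim") = dim;
  return List::create(_["density"] = out, _["n_skipped"] = skipped);
}

// per-z-slice grayscale opening (erosion then dilation) with a disk
// structuring element of radius r (inclusive, voxel-centre distance),
// truncated at slice borders; slices are independent
// [[Rcpp::export]]
NumericVector cpp_open_disk(NumericVector vol, IntegerVector dim, int r) {
  int nz = dim[0], ny = dim[1], nx = dim[2];
  std::vector<std::pair<int, int>> off;
  for (int dy = -r; dy <= r; ++dy)
    for (int dx = -r; dx <= r; ++dx)
      if (dy * dy + dx * dx <= r * r) off.push_back({dy, dx});
  const double* v = vol.begin();
  size_t nvox = (size_t)nz * ny * nx;
  std::vector<double> ero(nvox);
  NumericVector out(nvox);
  double* o = out.begin();
  for (int z = 0; z < nz; ++z) {
    for (int x = 0; x < nx; ++x)
      for (int y = 0; y < ny; ++y) {
        double mn = R_PosInf;
        for (auto& d : off) {
          int yy = y + d.first, xx = x + d.second;
          if (yy < 0 || yy >= ny || xx < 0 || xx >= nx) continue;
          double val = getv(v, nz, ny, nx, z, yy, xx);
          if (val < mn) mn = val;
        }
        ero[(size_t)z + (size_t)nz * ((size_t)y + (size_t)ny * (size_t)x)] = mn;
      }
    for (int x = 0; x < nx; ++x)
      for (int y = 0; y < ny; ++y) {
        double mx = R_NegInf;
        for (auto& d : off) {
          int yy = y + d.first, xx = x + d.second;
          if (yy < 0 || yy >= ny || xx < 0 || xx >= nx) continue;
          double val = ero[(size_t)z + (size_t)nz * ((size_t)yy + (size_t)ny * (size_t)xx)];
          if (val > mx) mx = val;
        }
        o[(size_t)z + (size_t)nz * ((size_t)y + (size_t)ny * (size_t)x)] = mx;
      }
  }
  out.attr("dim") = dim;
  return out;
}

// for each query voxel (linear 0-based index), find the label of the
// nearest claimed voxel (Euclidean distance, ties broken by smaller
// label); claimed = labels > 0. Expanding-box search, exact.
// [[Rcpp::export]]
IntegerVector cpp_nearest_label(IntegerVector labels, IntegerVector dim,
                                IntegerVector queries) {
  int nz = dim[0], ny = dim[1], nx = dim[2];
  const int* lab = labels.begin();
  int nq = queries.size();
  IntegerVector out(nq);
  int rmaxall = nz + ny + nx;
  for (int q = 0; q < nq; ++q) {
    size_t qi = (size_t)queries[q];
    int z = (int)(qi % nz);
    int rem = (int)(qi / nz);
    int y = rem % ny, x = rem / ny;
    double bestd2 = R_PosInf;
    int bestlab = 0;
    for (int r = 0; r <= rmaxall; ++r) {
      if (bestd2 < (double)r * r) break; // no closer voxel can appear
      // scan the chebyshev shell at radius r
      for (int dz = -r; dz <= r; ++dz) {
        int zz = z + dz; if (zz < 0 || zz >= nz) continue;
        for (int dy = -r; dy <= r; ++dy) {
          int yy = y + dy; if (yy < 0 || yy >= ny) continue;
          bool edgezy = (std::abs(dz) == r) || (std::abs(dy) == r);
          int step = edgezy ? 1 : 2 * r;
          if (r == 0) step = 1;
          for (int dx = -r; dx <= r; dx += (step > 0 ? step : 1)) {
            int xx = x + dx; if (xx < 0 || xx >= nx) continue;
            size_t j = (size_t)zz + (size_t)nz * ((size_t)yy + (size_t)ny * (size_t)xx);
            int lv = lab[j];
            if (lv <= 0) continue;
            double d2 = (double)dz * dz + (double)dy * dy + (double)dx * dx;
            if (d2 < bestd2 || (d2 == bestd2 && lv < bestlab)) {
              bestd2 = d2; bestlab = lv;
            }
          }
          if (r == 0) break;
        }
      }
    }
    out[q] = bestlab;
  }
  return out;
}
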