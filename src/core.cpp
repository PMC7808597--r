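#include <Rcpp.h>
#include <cmath>
#include <vector>
#include <queue>
#include <limits>

using namespace Rcpp;

// Linear index for (i,j,k) on a column-major (nx,ny,nz) grid.
static inline R_xlen_t lidx(int i, int j, int k, int nx, int ny) {
  return (R_xlen_t)i + (R_xlen_t)nx * ((R_xlen_t)j + (R_xlen_t)ny * (R_xlen_t)k);
}

struct Geom {
  int nx, ny, nz;
  double sp[3];
  double org[3];
  double dir[9];   // column-major 3x3, orthonormal
  void load(IntegerVector dims, NumericVector spacing, NumericVector origin,
            NumericVector direction) {
    nx = dims[0]; ny = dims[1]; nz = dims[2];
    for (int a = 0; a < 3; ++a) { sp[a] = spacing[a]; org[a] = origin[a]; }
    for (int a = 0; a < 9; ++a) dir[a] = direction[a];
  }
  // physical point of voxel (i,j,k)
  inline void point(double i, double j, double k, double *p) const {
    double u = i * sp[0], v = j * sp[1], w = k * sp[2];
    p[0] = org[0] + dir[0] * u + dir[3] * v + dir[6] * w;
    p[1] = org[1] + dir[1] * u + dir[4] * v + dir[7] * w;
    p[2] = org[2] + dir[2] * u + dir[5] * v + dir[8] * w;
  }
  // continuous index of physical point (direction orthonormal: inverse = transpose)
  inline void cindex(const double *p, double *c) const {
    double q0 = p[0] - org[0], q1 = p[1] - org[1], q2 = p[2] - org[2];
    c[0] = (dir[0] * q0 + dir[1] * q1 + dir[2] * q2) / sp[0];
    c[1] = (dir[3] * q0 + dir[4] * q1 + dir[5] * q2) / sp[1];
    c[2] = (dir[6] * q0 + dir[7] * q1 + dir[8] * q2) / sp[2];
  }
};

// Trilinear sample with out-of-support fill.
static inline double sample_linear(const double *vals, const Geom &g,
                                   const double *c, double fill) {
  double x = c[0], y = c[1], z = c[2];
  if (x < -0.5 || y < -0.5 || z < -0.5 ||
      x > g.nx - 0.5 || y > g.ny - 0.5 || z > g.nz - 0.5) return fill;
  int i0 = (int)std::floor(x), j0 = (int)std::floor(y), k0 = (int)std::floor(z);
  double fx = x - i0, fy = y - j0, fz = z - k0;
  double acc = 0.0;
  for (int dk = 0; dk <= 1; ++dk) {
    int k = k0 + dk; double wz = dk ? fz : 1.0 - fz;
    if (wz == 0.0) continue;
    int kc = k < 0 ? 0 : (k >= g.nz ? g.nz - 1 : k);
    for (int dj = 0; dj <= 1; ++dj) {
      int j = j0 + dj; double wy = dj ? fy : 1.0 - fy;
      if (wy == 0.0) continue;
      int jc = j < 0 ? 0 : (j >= g.ny ? g.ny - 1 : j);
      for (int di = 0; di <= 1; ++di) {
        int i = i0 + di; double wx = di ? fx : 1.0 - fx;
        if (wx == 0.0) continue;
        int ic = i < 0 ? 0 : (i >= g.nx ? g.nx - 1 : i);
        acc += wx * wy * wz * vals[lidx(ic, jc, kc, g.nx, g.ny)];
      }
    }
  }
  return acc;
}

static inline double sample_nearest(const double *vals, const Geom &g,
                                    const double *c, double fill) {
  int i = (int)std::lround(c[0]);
  int j = (int)std::lround(c[1]);
  int k = (int)std::lround(c[2]);
  if (i < 0 || j < 0 || k < 0 || i >= g.nx || j >= g.ny || k >= g.nz) return fill;
  return vals[lidx(i, j, k, g.nx, g.ny)];
}

// Resample src onto ref grid; sample point for output voxel at physical x is
// p = M x + t (M,t encode an optional rigid map; identity for plain resampling).
// [[Rcpp::export]]
NumericVector cpp_resample(NumericVector src,
                           IntegerVector sdim, NumericVector sspac,
                           NumericVector sorig, NumericVector sdir,
                           IntegerVector rdim, NumericVector rspac,
                           NumericVector rorig, NumericVector rdir,
                           NumericVector M, NumericVector t,
                           bool nearest, double fill) {
  Geom gs, gr;
  gs.load(sdim, sspac, sorig, sdir);
  gr.load(rdim, rspac, rorig, rdir);
  R_xlen_t n = (R_xlen_t)gr.nx * gr.ny * gr.nz;
  NumericVector out(n);
  const double *sv = REAL(src);
  double *ov = REAL(out);
  double p[3], q[3], c[3];
  for (int k = 0; k < gr.nz; ++k)
    for (int j = 0; j < gr.ny; ++j)
      for (int i = 0; i < gr.nx; ++i) {
        gr.point(i, j, k, p);
        q[0] = M[0] * p[0] + M[3] * p[1] + M[6] * p[2] + t[0];
        q[1] = M[1] * p[0] + M[4] * p[1] + M[7] * p[2] + t[1];
        q[2] = M[2] * p[0] + M[5] * p[1] + M[8] * p[2] + t[2];
        gs.cindex(q, c);
        ov[lidx(i, j, k, gr.nx, gr.ny)] =
          nearest ? sample_nearest(sv, gs, c, fill)
                  : sample_linear(sv, gs, c, fill);
      }
  return out;
}

// Warp src by a dense displacement field living on the ref grid:
// out(v) = src(x_v + u(v)), u in mm.
// [[Rcpp::export]]
NumericVector cpp_warp(NumericVector src,
                       IntegerVector sdim, NumericVector sspac,
                       NumericVector sorig, NumericVector sdir,
                       NumericMatrix field,
                       IntegerVector rdim, NumericVector rspac,
                       NumericVector rorig, NumericVector rdir,
                       bool nearest, double fill) {
  Geom gs, gr;
  gs.load(sdim, sspac, sorig, sdir);
  gr.load(rdim, rspac, rorig, rdir);
  R_xlen_t n = (R_xlen_t)gr.nx * gr.ny * gr.nz;
  if (field.nrow() != n) stop("field size does not match reference grid");
  NumericVector out(n);
  const double *sv = REAL(src);
  double *ov = REAL(out);
  const double *ux = &field(0, 0), *uy = &field(0, 1), *uz = &field(0, 2);
  double p[3], c[3];
  R_xlen_t v = 0;
  for (int k = 0; k < gr.nz; ++k)
    for (int j = 0; j < gr.ny; ++j)
      for (int i = 0; i < gr.nx; ++i, ++v) {
        gr.point(i, j, k, p);
        p[0] += ux[v]; p[1] += uy[v]; p[2] += uz[v];
        gs.cindex(p, c);
        ov[v] = nearest ? sample_nearest(sv, gs, c, fill)
                        : sample_linear(sv, gs, c, fill);
      }
  return out;
}

// Separable Gaussian smoothing, sigma per axis in voxels, reflected boundary.
static void smooth_axis(std::vector<double> &buf, double *vals,
                        int nx, int ny, int nz, int axis, double sigma) {
  if (sigma <= 0.05) return;
  int r = (int)std::ceil(3.0 * sigma);
  if (r < 1) r = 1;
  std::vector<double> kern(2 * r + 1);
  double s = 0.0;
  for (int d = -r; d <= r; ++d) {
    kern[d + r] = std::exp(-0.5 * d * d / (sigma * sigma));
    s += kern[d + r];
  }
  for (double &w : kern) w /= s;
  int len = axis == 0 ? nx : (axis == 1 ? ny : nz);
  R_xlen_t stride = axis == 0 ? 1 : (axis == 1 ? nx : (R_xlen_t)nx * ny);
  std::vector<double> line(len);
  // enumerate line base offsets
  int n1, n2;
  R_xlen_t s1, s2;
  if (axis == 0)      { n1 = ny; s1 = nx; n2 = nz; s2 = (R_xlen_t)nx * ny; }
  else if (axis == 1) { n1 = nx; s1 = 1;  n2 = nz; s2 = (R_xlen_t)nx * ny; }
  else                { n1 = nx; s1 = 1;  n2 = ny; s2 = nx; }
  for (int b = 0; b < n2; ++b)
    for (int a = 0; a < n1; ++a) {
      double *base = vals + (R_xlen_t)a * s1 + (R_xlen_t)b * s2;
      {
        double *p = base;
        for (int q = 0; q < len; ++q, p += stride) line[q] = *p;
      }
      int lo = std::min(r, len), hi = std::max(len - r, lo);
      for (int q = 0; q < lo; ++q) {          // left boundary (reflect)
        double acc = 0.0;
        for (int d = -r; d <= r; ++d) {
          int u = q + d;
          if (u < 0) u = -u - 1;
          if (u >= len) u = 2 * len - u - 1;
          acc += kern[d + r] * line[u];
        }
        buf[q] = acc;
      }
      for (int q = lo; q < hi; ++q) {         // interior, no checks
        double acc = 0.0;
        const double *lp = &line[q - r];
        for (int d = 0; d <= 2 * r; ++d) acc += kern[d] * lp[d];
        buf[q] = acc;
      }
      for (int q = hi; q < len; ++q) {        // right boundary (reflect)
        double acc = 0.0;
        for (int d = -r; d <= r; ++d) {
          int u = q + d;
          if (u < 0) u = -u - 1;
          if (u >= len) u = 2 * len - u - 1;
          acc += kern[d + r] * line[u];
        }
        buf[q] = acc;
      }
      {
        double *p = base;
        for (int q = 0; q < len; ++q, p += stride) *p = buf[q];
      }
    }
}

static void gauss3_raw(double *v, int nx, int ny, int nz,
                       const double *sig) {
  int mx = std::max(nx, std::max(ny, nz));
  std::vector<double> buf(mx);
  smooth_axis(buf, v, nx, ny, nz, 0, sig[0]);
  smooth_axis(buf, v, nx, ny, nz, 1, sig[1]);
  smooth_axis(buf, v, nx, ny, nz, 2, sig[2]);
}

// [[Rcpp::export]]
NumericVector cpp_gaussian3(NumericVector values, IntegerVector dim,
                            NumericVector sigma_vox) {
  NumericVector out = clone(values);
  double sig[3] = { sigma_vox[0], sigma_vox[1], sigma_vox[2] };
  gauss3_raw(REAL(out), dim[0], dim[1], dim[2], sig);
  return out;
}

// Central-difference gradient rotated into physical space, units value/mm.
// [[Rcpp::export]]
NumericMatrix cpp_gradient(NumericVector values, IntegerVector dim,
                           NumericVector spacing, NumericVector direction) {
  int nx = dim[0], ny = dim[1], nz = dim[2];
  R_xlen_t n = (R_xlen_t)nx * ny * nz;
  NumericMatrix out(n, 3);
  const double *v = REAL(values);
  const double *D = REAL(direction);
  R_xlen_t p = 0;
  for (int k = 0; k < nz; ++k)
    for (int j = 0; j < ny; ++j)
      for (int i = 0; i < nx; ++i, ++p) {
        int ip = i + 1 < nx ? i + 1 : i, im = i > 0 ? i - 1 : i;
        int jp = j + 1 < ny ? j + 1 : j, jm = j > 0 ? j - 1 : j;
        int kp = k + 1 < nz ? k + 1 : k, km = k > 0 ? k - 1 : k;
        double gi = (v[lidx(ip, j, k, nx, ny)] - v[lidx(im, j, k, nx, ny)]) /
                    ((ip - im) * spacing[0]);
        double gj = (v[lidx(i, jp, k, nx, ny)] - v[lidx(i, jm, k, nx, ny)]) /
                    ((jp - jm) * spacing[1]);
        double gk = (v[lidx(i, j, kp, nx, ny)] - v[lidx(i, j, km, nx, ny)]) /
                    ((kp - km) * spacing[2]);
        out(p, 0) = D[0] * gi + D[3] * gj + D[6] * gk;
        out(p, 1) = D[1] * gi + D[4] * gj + D[7] * gk;
        out(p, 2) = D[2] * gi + D[5] * gj + D[8] * gk;
      }
  return out;
}

// Mean squared intensity difference between fixed and moving sampled at
// p = M x + t for every fixed voxel (out-of-support -> fill).
// [[Rcpp::export]]
double cpp_msd_affine(NumericVector fixed,
                      IntegerVector fdim, NumericVector fspac,
                      NumericVector forig, NumericVector fdir,
                      NumericVector moving,
                      IntegerVector mdim, NumericVector mspac,
                      NumericVector morig, NumericVector mdir,
                      NumericVector M, NumericVector t, double fill,
                      int stride) {
  Geom gf, gm;
  gf.load(fdim, fspac, forig, fdir);
  gm.load(mdim, mspac, morig, mdir);
  if (stride < 1) stride = 1;
  const double *fv = REAL(fixed);
  const double *mv = REAL(moving);
  double p[3], q[3], c[3], acc = 0.0;
  R_xlen_t cnt = 0;
  for (int k = 0; k < gf.nz; k += stride)
    for (int j = 0; j < gf.ny; j += stride)
      for (int i = 0; i < gf.nx; i += stride) {
        gf.point(i, j, k, p);
        q[0] = M[0] * p[0] + M[3] * p[1] + M[6] * p[2] + t[0];
        q[1] = M[1] * p[0] + M[4] * p[1] + M[7] * p[2] + t[1];
        q[2] = M[2] * p[0] + M[5] * p[1] + M[8] * p[2] + t[2];
        gm.cindex(q, c);
        double d = sample_linear(mv, gm, c, fill) -
          fv[lidx(i, j, k, gf.nx, gf.ny)];
        acc += d * d;
        ++cnt;
      }
  return acc / (double)cnt;
}

// Thirion demons iterations on a single resolution level. The displacement
// field lives on the fixed grid (mm, fixed-space point -> moving-space sample
// point, i.e. moving is sampled at x + u(x)). The update uses the fixed-image
// gradient: du = (f - m) grad_f / (|grad_f|^2 + (f - m)^2), capped at
// max_step mm, and the accumulated field is Gaussian-smoothed each iteration.
// [[Rcpp::export]]
List cpp_demons(NumericVector fixed,
                IntegerVector fdim, NumericVector fspac,
                NumericVector forig, NumericVector fdir,
                NumericVector moving,
                IntegerVector mdim, NumericVector mspac,
                NumericVector morig, NumericVector mdir,
                NumericMatrix field_init,
                int iterations, NumericVector sigma_update_vox,
                NumericVector sigma_field_vox,
                double max_step, double eps, double fill) {
  Geom gf, gm;
  gf.load(fdim, fspac, forig, fdir);
  gm.load(mdim, mspac, morig, mdir);
  R_xlen_t n = (R_xlen_t)gf.nx * gf.ny * gf.nz;
  if (field_init.nrow() != n) stop("initial field does not match fixed grid");
  NumericMatrix field = clone(field_init);
  NumericMatrix grad = cpp_gradient(fixed, fdim, fspac, fdir);
  const double *fv = REAL(fixed);
  const double *mv = REAL(moving);
  double p[3], c[3];
  double msd0 = NA_REAL, msd1 = NA_REAL;
  double sigu[3] = { sigma_update_vox[0], sigma_update_vox[1],
                     sigma_update_vox[2] };
  double sigf[3] = { sigma_field_vox[0], sigma_field_vox[1],
                     sigma_field_vox[2] };
  bool smooth_update = sigu[0] > 0.05 || sigu[1] > 0.05 || sigu[2] > 0.05;
  bool smooth_field = sigf[0] > 0.05 || sigf[1] > 0.05 || sigf[2] > 0.05;
  std::vector<double> upd(smooth_update ? 3 * n : 0);
  // the best-metric field seen so far is returned, so weak forces can never
  // leave the result worse than its initialization
  std::vector<double> best(3 * n);
  double best_msd = R_PosInf;
  for (int it = 0; it <= iterations; ++it) {
    double acc = 0.0;
    bool last = (it == iterations);
    R_xlen_t v = 0;
    for (int k = 0; k < gf.nz; ++k)
      for (int j = 0; j < gf.ny; ++j)
        for (int i = 0; i < gf.nx; ++i, ++v) {
          gf.point(i, j, k, p);
          p[0] += field(v, 0); p[1] += field(v, 1); p[2] += field(v, 2);
          gm.cindex(p, c);
          double m = sample_linear(mv, gm, c, fill);
          double diff = fv[v] - m;
          acc += diff * diff;
          if (last) continue;
          double gx = grad(v, 0), gy = grad(v, 1), gz = grad(v, 2);
          double den = gx * gx + gy * gy + gz * gz + diff * diff;
          double ux = 0.0, uy = 0.0, uz = 0.0;
          if (den >= eps) {
            double s = diff / den;
            ux = s * gx; uy = s * gy; uz = s * gz;
            double mag = std::sqrt(ux * ux + uy * uy + uz * uz);
            if (mag > max_step) {
              double sc = max_step / mag;
              ux *= sc; uy *= sc; uz *= sc;
            }
          }
          if (smooth_update) {
            upd[v] = ux; upd[n + v] = uy; upd[2 * n + v] = uz;
          } else {
            field(v, 0) += ux; field(v, 1) += uy; field(v, 2) += uz;
          }
        }
    double cur = acc / (double)n;
    if (it == 0) msd0 = cur;
    if (cur < best_msd) {
      best_msd = cur;
      for (int comp = 0; comp < 3; ++comp)
        for (R_xlen_t v2 = 0; v2 < n; ++v2)
          best[(R_xlen_t)comp * n + v2] = field(v2, comp);
    }
    if (last) { msd1 = cur; break; }
    if (smooth_update) {
      for (int comp = 0; comp < 3; ++comp) {
        gauss3_raw(&upd[(R_xlen_t)comp * n], gf.nx, gf.ny, gf.nz, sigu);
        for (R_xlen_t v2 = 0; v2 < n; ++v2)
          field(v2, comp) += upd[(R_xlen_t)comp * n + v2];
      }
    }
    if (smooth_field)
      for (int comp = 0; comp < 3; ++comp)
        gauss3_raw(&field(0, comp), gf.nx, gf.ny, gf.nz, sigf);
  }
  if (best_msd < msd1) {
    for (int comp = 0; comp < 3; ++comp)
      for (R_xlen_t v2 = 0; v2 < n; ++v2)
        field(v2, comp) = best[(R_xlen_t)comp * n + v2];
    msd1 = best_msd;
  }
  return List::create(_["field"] = field, _["msd_initial"] = msd0,
                      _["msd_final"] = msd1);
}

// 1D exact squared-distance transform (Felzenszwalb-Huttenlocher) with
// arbitrary sample coordinates x (strictly increasing).
static void dt1d(const std::vector<double> &f, const std::vector<double> &x,
                 std::vector<double> &out) {
  int n = (int)f.size();
  const double INF = std::numeric_limits<double>::infinity();
  std::vector<int> sites;
  sites.reserve(n);
  for (int q = 0; q < n; ++q)
    if (f[q] < INF) sites.push_back(q);
  if (sites.empty()) {
    for (int q = 0; q < n; ++q) out[q] = INF;
    return;
  }
  int ns = (int)sites.size();
  std::vector<int> v(ns);
  std::vector<double> z(ns + 1);
  int k = 0;
  v[0] = sites[0];
  z[0] = -INF; z[1] = INF;
  for (int si = 1; si < ns; ++si) {
    int q = sites[si];
    double s;
    while (true) {
      int p = v[k];
      s = (f[q] + x[q] * x[q] - f[p] - x[p] * x[p]) / (2 * x[q] - 2 * x[p]);
      if (s <= z[k]) --k; else break;
    }
    ++k;
    v[k] = q; z[k] = s; z[k + 1] = INF;
  }
  for (int q = 0, kk = 0; q < n; ++q) {
    while (z[kk + 1] < x[q]) ++kk;
    double d = x[q] - x[v[kk]];
    out[q] = f[v[kk]] + d * d;
  }
}

// Exact Euclidean distance (mm) from every voxel center to the nearest
// 1-voxel center, anisotropic spacing.
// [[Rcpp::export]]
NumericVector cpp_edt(IntegerVector mask, IntegerVector dim,
                      NumericVector spacing) {
  int nx = dim[0], ny = dim[1], nz = dim[2];
  R_xlen_t n = (R_xlen_t)nx * ny * nz;
  const double INF = std::numeric_limits<double>::infinity();
  std::vector<double> d(n);
  for (R_xlen_t v = 0; v < n; ++v) d[v] = mask[v] ? 0.0 : INF;
  int mx = std::max(nx, std::max(ny, nz));
  std::vector<double> f(mx), xs(mx), o(mx);
  // pass along x
  for (int q = 0; q < nx; ++q) xs[q] = q * spacing[0];
  for (int k = 0; k < nz; ++k)
    for (int j = 0; j < ny; ++j) {
      std::vector<double> fl(nx), ol(nx);
      bool any = false;
      for (int i = 0; i < nx; ++i) { fl[i] = d[lidx(i, j, k, nx, ny)]; if (fl[i] < INF) any = true; }
      if (!any) continue;
      std::vector<double> xl(xs.begin(), xs.begin() + nx);
      dt1d(fl, xl, ol);
      for (int i = 0; i < nx; ++i) d[lidx(i, j, k, nx, ny)] = ol[i];
    }
  // pass along y
  for (int q = 0; q < ny; ++q) xs[q] = q * spacing[1];
  for (int k = 0; k < nz; ++k)
    for (int i = 0; i < nx; ++i) {
      std::vector<double> fl(ny), ol(ny);
      bool any = false;
      for (int j = 0; j < ny; ++j) { fl[j] = d[lidx(i, j, k, nx, ny)]; if (fl[j] < INF) any = true; }
      if (!any) continue;
      std::vector<double> xl(xs.begin(), xs.begin() + ny);
      dt1d(fl, xl, ol);
      for (int j = 0; j < ny; ++j) d[lidx(i, j, k, nx, ny)] = ol[j];
    }
  // pass along z
  for (int q = 0; q < nz; ++q) xs[q] = q * spacing[2];
  for (int j = 0; j < ny; ++j)
    for (int i = 0; i < nx; ++i) {
      std::vector<double> fl(nz), ol(nz);
      bool any = false;
      for (int k = 0; k < nz; ++k) { fl[k] = d[lidx(i, j, k, nx, ny)]; if (fl[k] < INF) any = true; }
      if (!any) continue;
      std::vector<double> xl(xs.begin(), xs.begin() + nz);
      dt1d(fl, xl, ol);
      for (int k = 0; k < nz; ++k) d[lidx(i, j, k, nx, ny)] = ol[k];
    }
  NumericVector out(n);
  for (R_xlen_t v = 0; v < n; ++v)
    out[v] = d[v] == INF ? R_PosInf : std::sqrt(d[v]);
  return out;
}

// Mean absolute difference |a-b| over the clipped cubic patch of per-axis
// voxel radius r centered at each voxel (separable box sums over values and
// counts).
// [[Rcpp::export]]
NumericVector cpp_patch_mad(NumericVector a, NumericVector b,
                            IntegerVector dim, IntegerVector rvox) {
  int nx = dim[0], ny = dim[1], nz = dim[2];
  R_xlen_t n = (R_xlen_t)nx * ny * nz;
  std::vector<double> s(n), cnt(n, 1.0), tmp(n), tmpc(n);
  for (R_xlen_t v = 0; v < n; ++v) s[v] = std::fabs(a[v] - b[v]);
  int rs[3] = { rvox[0], rvox[1], rvox[2] };
  for (int axis = 0; axis < 3; ++axis) {
    int r = rs[axis];
    if (r <= 0) continue;
    int len = axis == 0 ? nx : (axis == 1 ? ny : nz);
    for (int k = 0; k < nz; ++k)
      for (int j = 0; j < ny; ++j)
        for (int i = 0; i < nx; ++i) {
          int q = axis == 0 ? i : (axis == 1 ? j : k);
          double av = 0.0, cv = 0.0;
          int lo = std::max(0, q - r), hi = std::min(len - 1, q + r);
          for (int u = lo; u <= hi; ++u) {
            R_xlen_t w;
            if (axis == 0) w = lidx(u, j, k, nx, ny);
            else if (axis == 1) w = lidx(i, u, k, nx, ny);
            else w = lidx(i, j, u, nx, ny);
            av += s[w]; cv += cnt[w];
          }
          R_xlen_t v = lidx(i, j, k, nx, ny);
          tmp[v] = av; tmpc[v] = cv;
        }
    s.swap(tmp); cnt.swap(tmpc);
  }
  NumericVector out(n);
  for (R_xlen_t v = 0; v < n; ++v) out[v] = s[v] / cnt[v];
  return out;
}

// 6-connected component labelling (labels 1..L in first-encounter order).
// [[Rcpp::export]]
IntegerVector cpp_label6(IntegerVector mask, IntegerVector dim) {
  int nx = dim[0], ny = dim[1], nz = dim[2];
  R_xlen_t n = (R_xlen_t)nx * ny * nz;
  IntegerVector lab(n, 0);
  int next = 0;
  std::vector<R_xlen_t> stack;
  const int off[6][3] = { {1,0,0},{-1,0,0},{0,1,0},{0,-1,0},{0,0,1},{0,0,-1} };
  for (R_xlen_t v0 = 0; v0 < n; ++v0) {
    if (!mask[v0] || lab[v0]) continue;
    ++next;
    lab[v0] = next;
    stack.clear();
    stack.push_back(v0);
    while (!stack.empty()) {
      R_xlen_t v = stack.back(); stack.pop_back();
      int i = (int)(v % nx);
      int j = (int)((v / nx) % ny);
      int k = (int)(v / ((R_xlen_t)nx * ny));
      for (int d = 0; d < 6; ++d) {
        int ii = i + off[d][0], jj = j + off[d][1], kk = k + off[d][2];
        if (ii < 0 || jj < 0 || kk < 0 || ii >= nx || jj >= ny || kk >= nz) continue;
        R_xlen_t w = lidx(ii, jj, kk, nx, ny);
        if (mask[w] && !lab[w]) { lab[w] = next; stack.push_back(w); }
      }
    }
  }
  return lab;
}

// Boundary voxels: mask voxels with a 6-connected background neighbour
// (outside the grid counts as background).
// [[Rcpp::export]]
LogicalVector cpp_surface6(IntegerVector mask, IntegerVector dim) {
  int nx = dim[0], ny = dim[1], nz = dim[2];
  R_xlen_t n = (R_xlen_t)nx * ny * nz;
  LogicalVector out(n, false);
  const int off[6][3] = { {1,0,0},{-1,0,0},{0,1,0},{0,-1,0},{0,0,1},{0,0,-1} };
  R_xlen_t v = 0;
  for (int k = 0; k < nz; ++k)
    for (int j = 0; j < ny; ++j)
      for (int i = 0; i < nx; ++i, ++v) {
        if (!mask[v]) continue;
        bool surf = false;
        for (int d = 0; d < 6 && !surf; ++d) {
          int ii = i + off[d][0], jj = j + off[d][1], kk = k + off[d][2];
          if (ii < 0 || jj < 0 || kk < 0 || ii >= nx || jj >= ny || kk >= nz)
            surf = true;
          else if (!mask[lidx(ii, jj, kk, nx, ny)])
            surf = true;
        }
        out[v] = surf;
      }
  return out;
}

// Determinant of the Jacobian of (identity + field) by finite differences,
// used to check for folding in recovered deformations.
// [[Rcpp::export]]
NumericVector cpp_jacobian_det(NumericMatrix field, IntegerVector dim,
                               NumericVector spacing) {
  int nx = dim[0], ny = dim[1], nz = dim[2];
  R_xlen_t n = (R_xlen_t)nx * ny * nz;
  NumericVector out(n);
  double J[9];
  R_xlen_t v = 0;
  for (int k = 0; k < nz; ++k)
    for (int j = 0; j < ny; ++j)
      for (int i = 0; i < nx; ++i, ++v) {
        int ip = i + 1 < nx ? i + 1 : i, im = i > 0 ? i - 1 : i;
        int jp = j + 1 < ny ? j + 1 : j, jm = j > 0 ? j - 1 : j;
        int kp = k + 1 < nz ? k + 1 : k, km = k > 0 ? k - 1 : k;
        double hx = (ip - im) * spacing[0];
        double hy = (jp - jm) * spacing[1];
        double hz = (kp - km) * spacing[2];
        for (int c = 0; c < 3; ++c) {
          J[c]     = (field(lidx(ip, j, k, nx, ny), c) - field(lidx(im, j, k, nx, ny), c)) / hx;
          J[3 + c] = (field(lidx(i, jp, k, nx, ny), c) - field(lidx(i, jm, k, nx, ny), c)) / hy;
          J[6 + c] = (field(lidx(i, j, kp, nx, ny), c) - field(lidx(i, j, km, nx, ny), c)) / hz;
        }
        J[0] += 1.0; J[4] += 1.0; J[8] += 1.0;
        out[v] = J[0] * (J[4] * J[8] - J[5] * J[7])
               - J[3] * (J[1] * J[8] - J[2] * J[7])
               + J[6] * (J[1] * J[5] - J[2] * J[4]);
      }
  return out;
}
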