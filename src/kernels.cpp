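#include <Rcpp.h>
#include <cmath>
#include <vector>
#include <queue>
using namespace Rcpp;

// Volume arrays are column-major (nx, ny, nz); `origin` is the mm coordinate of
// the centre of voxel (0,0,0); the gantry rotates about z (superior-inferior).
// At angle a (radians) the source sits at (SID sin a, -SID cos a, 0), the
// detector u-axis is (cos a, sin a, 0) and its v-axis is +z.

static inline double tri_sample(const double *v, int nx, int ny, int nz,
                                double gx, double gy, double gz) {
  // clamp-to-edge sampling in voxel coordinates
  if (gx < 0) gx = 0; if (gx > nx - 1) gx = nx - 1;
  if (gy < 0) gy = 0; if (gy > ny - 1) gy = ny - 1;
  if (gz < 0) gz = 0; if (gz > nz - 1) gz = nz - 1;
  int x0 = (int)std::floor(gx); if (x0 > nx - 2) x0 = nx - 2; if (nx == 1) x0 = 0;
  int y0 = (int)std::floor(gy); if (y0 > ny - 2) y0 = ny - 2; if (ny == 1) y0 = 0;
  int z0 = (int)std::floor(gz); if (z0 > nz - 2) z0 = nz - 2; if (nz == 1) z0 = 0;
  double fx = gx - x0, fy = gy - y0, fz = gz - z0;
  int x1 = (nx == 1) ? x0 : x0 + 1, y1 = (ny == 1) ? y0 : y0 + 1, z1 = (nz == 1) ? z0 : z0 + 1;
  size_t sxy = (size_t)nx * ny;
  const double c000 = v[x0 + nx * y0 + sxy * z0], c100 = v[x1 + nx * y0 + sxy * z0];
  const double c010 = v[x0 + nx * y1 + sxy * z0], c110 = v[x1 + nx * y1 + sxy * z0];
  const double c001 = v[x0 + nx * y0 + sxy * z1], c101 = v[x1 + nx * y0 + sxy * z1];
  const double c011 = v[x0 + nx * y1 + sxy * z1], c111 = v[x1 + nx * y1 + sxy * z1];
  double c00 = c000 * (1 - fx) + c100 * fx, c10 = c010 * (1 - fx) + c110 * fx;
  double c01 = c001 * (1 - fx) + c101 * fx, c11 = c011 * (1 - fx) + c111 * fx;
  double c0 = c00 * (1 - fy) + c10 * fy, c1 = c01 * (1 - fy) + c11 * fy;
  return c0 * (1 - fz) + c1 * fz;
}

static inline void tri_scatter(double *v, int nx, int ny, int nz,
                               double gx, double gy, double gz, double val) {
  if (gx < 0) gx = 0; if (gx > nx - 1) gx = nx - 1;
  if (gy < 0) gy = 0; if (gy > ny - 1) gy = ny - 1;
  if (gz < 0) gz = 0; if (gz > nz - 1) gz = nz - 1;
  int x0 = (int)std::floor(gx); if (x0 > nx - 2) x0 = nx - 2; if (nx == 1) x0 = 0;
  int y0 = (int)std::floor(gy); if (y0 > ny - 2) y0 = ny - 2; if (ny == 1) y0 = 0;
  int z0 = (int)std::floor(gz); if (z0 > nz - 2) z0 = nz - 2; if (nz == 1) z0 = 0;
  double fx = gx - x0, fy = gy - y0, fz = gz - z0;
  int x1 = (nx == 1) ? x0 : x0 + 1, y1 = (ny == 1) ? y0 : y0 + 1, z1 = (nz == 1) ? z0 : z0 + 1;
  size_t sxy = (size_t)nx * ny;
  v[x0 + nx * y0 + sxy * z0] += val * (1 - fx) * (1 - fy) * (1 - fz);
  v[x1 + nx * y0 + sxy * z0] += val * fx * (1 - fy) * (1 - fz);
  v[x0 + nx * y1 + sxy * z0] += val * (1 - fx) * fy * (1 - fz);
  v[x1 + nx * y1 + sxy * z0] += val * fx * fy * (1 - fz);
  v[x0 + nx * y0 + sxy * z1] += val * (1 - fx) * (1 - fy) * fz;
  v[x1 + nx * y0 + sxy * z1] += val * fx * (1 - fy) * fz;
  v[x0 + nx * y1 + sxy * z1] += val * (1 - fx) * fy * fz;
  v[x1 + nx * y1 + sxy * z1] += val * fx * fy * fz;
}

// slab-method intersection of a ray p(t) = s + t d with the volume bounding box
static inline bool ray_box(const double s[3], const double d[3],
                           const double bmin[3], const double bmax[3],
                           double &t0, double &t1) {
  t0 = 0.0; t1 = 1e30;
  for (int k = 0; k < 3; ++k) {
    if (std::fabs(d[k]) < 1e-12) {
      if (s[k] < bmin[k] || s[k] > bmax[k]) return false;
    } else {
      double inv = 1.0 / d[k];
      double ta = (bmin[k] - s[k]) * inv, tb = (bmax[k] - s[k]) * inv;
      if (ta > tb) std::swap(ta, tb);
      if (ta > t0) t0 = ta;
      if (tb < t1) t1 = tb;
      if (t0 > t1) return false;
    }
  }
  return t1 > t0;
}

struct Geom {
  double sid, sdd, pu, pv; int nu, nv;
};

// core traversal shared by A and A^T so the pair is an exact transpose
template <bool FORWARD>
static void project_views(double *vol, double *proj,
                          int nx, int ny, int nz,
                          const double spacing[3], const double origin[3],
                          const NumericVector &angles_rad, const Geom &g,
                          double step) {
  double bmin[3], bmax[3];
  for (int k = 0; k < 3; ++k) {
    double n = (k == 0) ? nx : (k == 1) ? ny : nz;
    bmin[k] = origin[k] - 0.5 * spacing[k];
    bmax[k] = origin[k] + (n - 0.5) * spacing[k];
  }
  int nviews = angles_rad.size();
  size_t npix = (size_t)g.nu * g.nv;
  for (int a = 0; a < nviews; ++a) {
    double ca = std::cos(angles_rad[a]), sa = std::sin(angles_rad[a]);
    double S[3] = {g.sid * sa, -g.sid * ca, 0.0};
    double C[3] = {(g.sid - g.sdd) * sa, (g.sdd - g.sid) * ca, 0.0};
    double U[3] = {ca, sa, 0.0};
    for (int iv = 0; iv < g.nv; ++iv) {
      double vv = (iv - (g.nv - 1) / 2.0) * g.pv;
      for (int iu = 0; iu < g.nu; ++iu) {
        double uu = (iu - (g.nu - 1) / 2.0) * g.pu;
        double P[3] = {C[0] + U[0] * uu, C[1] + U[1] * uu, vv};
        double d[3] = {P[0] - S[0], P[1] - S[1], P[2] - S[2]};
        double nrm = std::sqrt(d[0] * d[0] + d[1] * d[1] + d[2] * d[2]);
        d[0] /= nrm; d[1] /= nrm; d[2] /= nrm;
        double t0, t1;
        if (!ray_box(S, d, bmin, bmax, t0, t1)) continue;
        int nstep = (int)std::ceil((t1 - t0) / step);
        if (nstep < 1) nstep = 1;
        double dt = (t1 - t0) / nstep;
        size_t pidx = (size_t)a * npix + (size_t)iv * g.nu + iu;
        double acc = 0.0;
        double pval = FORWARD ? 0.0 : proj[pidx] * dt;
        for (int m = 0; m < nstep; ++m) {
          double t = t0 + (m + 0.5) * dt;
          double gx = (S[0] + t * d[0] - origin[0]) / spacing[0];
          double gy = (S[1] + t * d[1] - origin[1]) / spacing[1];
          double gz = (S[2] + t * d[2] - origin[2]) / spacing[2];
          if (FORWARD) acc += tri_sample(vol, nx, ny, nz, gx, gy, gz);
          else tri_scatter(vol, nx, ny, nz, gx, gy, gz, pval);
        }
        if (FORWARD) proj[pidx] = acc * dt;
      }
    }
  }
}

// [[Rcpp::export]]
NumericVector cpp_forward_project(NumericVector vol, IntegerVector dims,
                                  NumericVector spacing, NumericVector origin,
                                  NumericVector angles_rad,
                                  int nu, int nv, double pu, double pv,
                                  double sid, double sdd, double step) {
  Geom g{sid, sdd, pu, pv, nu, nv};
  NumericVector proj((size_t)nu * nv * angles_rad.size());
  double sp[3] = {spacing[0], spacing[1], spacing[2]};
  double orig[3] = {origin[0], origin[1], origin[2]};
  project_views<true>(vol.begin(), proj.begin(), dims[0], dims[1], dims[2],
                      sp, orig, angles_rad, g, step);
  proj.attr("dim") = IntegerVector::create(nu, nv, angles_rad.size());
  return proj;
}

// [[Rcpp::export]]
NumericVector cpp_backproject(NumericVector proj, IntegerVector dims,
                              NumericVector spacing, NumericVector origin,
                              NumericVector angles_rad,
                              int nu, int nv, double pu, double pv,
                              double sid, double sdd, double step) {
  Geom g{sid, sdd, pu, pv, nu, nv};
  NumericVector vol((size_t)dims[0] * dims[1] * dims[2]);
  double sp[3] = {spacing[0], spacing[1], spacing[2]};
  double orig[3] = {origin[0], origin[1], origin[2]};
  NumericVector p = clone(proj);
  project_views<false>(vol.begin(), p.begin(), dims[0], dims[1], dims[2],
                       sp, orig, angles_rad, g, step);
  vol.attr("dim") = dims;
  return vol;
}

// voxel-driven weighted backprojection of filtered projections (FDK).
// `q` must already be cosine-weighted and ramp-filtered, sampled on the
// virtual detector at the isocentre plane (pitch pu_iso, pv_iso).
// [[Rcpp::export]]
NumericVector cpp_fdk_backproject(NumericVector q, IntegerVector dims,
                                  NumericVector spacing, NumericVector origin,
                                  NumericVector angles_rad,
                                  int nu, int nv, double pu_iso, double pv_iso,
                                  double sid) {
  int nx = dims[0], ny = dims[1], nz = dims[2];
  int nviews = angles_rad.size();
  size_t npix = (size_t)nu * nv;
  NumericVector vol((size_t)nx * ny * nz);
  std::vector<double> cs(nviews), sn(nviews);
  for (int a = 0; a < nviews; ++a) { cs[a] = std::cos(angles_rad[a]); sn[a] = std::sin(angles_rad[a]); }
  for (int iz = 0; iz < nz; ++iz) {
    double z = origin[2] + iz * spacing[2];
    for (int iy = 0; iy < ny; ++iy) {
      double y = origin[1] + iy * spacing[1];
      for (int ix = 0; ix < nx; ++ix) {
        double x = origin[0] + ix * spacing[0];
        double acc = 0.0;
        for (int a = 0; a < nviews; ++a) {
          // w = source->isocentre direction; u = in-plane detector axis
          double Uw = sid + (-sn[a] * x + cs[a] * y);
          if (Uw < 1e-3) continue;
          double ucoord = sid * (cs[a] * x + sn[a] * y) / Uw;
          double vcoord = sid * z / Uw;
          double gu = ucoord / pu_iso + (nu - 1) / 2.0;
          double gv = vcoord / pv_iso + (nv - 1) / 2.0;
          if (gu < 0 || gu > nu - 1 || gv < 0 || gv > nv - 1) continue;
          int u0 = (int)std::floor(gu); if (u0 > nu - 2) u0 = nu - 2;
          int v0 = (int)std::floor(gv); if (v0 > nv - 2) v0 = nv - 2;
          double fu = gu - u0, fv = gv - v0;
          const double *pq = q.begin() + (size_t)a * npix;
          double q00 = pq[u0 + nu * v0], q10 = pq[u0 + 1 + nu * v0];
          double q01 = pq[u0 + nu * (v0 + 1)], q11 = pq[u0 + 1 + nu * (v0 + 1)];
          double val = (q00 * (1 - fu) + q10 * fu) * (1 - fv) +
                       (q01 * (1 - fu) + q11 * fu) * fv;
          acc += val * sid * sid / (Uw * Uw);
        }
        vol[ix + (size_t)nx * iy + (size_t)nx * ny * iz] = acc;
      }
    }
  }
  vol.attr("dim") = dims;
  return vol;
}

// backward warp: out(x) = in(x + D(x)), D in mm on the output grid
// [[Rcpp::export]]
NumericVector cpp_warp(NumericVector vol, IntegerVector dims,
                       NumericVector spacing, NumericVector dvf) {
  int nx = dims[0], ny = dims[1], nz = dims[2];
  size_t n = (size_t)nx * ny * nz;
  NumericVector out(n);
  const double *dx = dvf.begin(), *dy = dvf.begin() + n, *dz = dvf.begin() + 2 * n;
  size_t i = 0;
  for (int iz = 0; iz < nz; ++iz)
    for (int iy = 0; iy < ny; ++iy)
      for (int ix = 0; ix < nx; ++ix, ++i) {
        double gx = ix + dx[i] / spacing[0];
        double gy = iy + dy[i] / spacing[1];
        double gz = iz + dz[i] / spacing[2];
        out[i] = tri_sample(vol.begin(), nx, ny, nz, gx, gy, gz);
      }
  out.attr("dim") = dims;
  return out;
}

// adjoint of cpp_warp with respect to the input volume (scatter of gradients)
// [[Rcpp::export]]
NumericVector cpp_warp_adjoint(NumericVector grad_out, IntegerVector dims,
                               NumericVector spacing, NumericVector dvf) {
  int nx = dims[0], ny = dims[1], nz = dims[2];
  size_t n = (size_t)nx * ny * nz;
  NumericVector gin(n);
  const double *dx = dvf.begin(), *dy = dvf.begin() + n, *dz = dvf.begin() + 2 * n;
  size_t i = 0;
  for (int iz = 0; iz < nz; ++iz)
    for (int iy = 0; iy < ny; ++iy)
      for (int ix = 0; ix < nx; ++ix, ++i) {
        double gx = ix + dx[i] / spacing[0];
        double gy = iy + dy[i] / spacing[1];
        double gz = iz + dz[i] / spacing[2];
        tri_scatter(gin.begin(), nx, ny, nz, gx, gy, gz, grad_out[i]);
      }
  gin.attr("dim") = dims;
  return gin;
}

// gradient of the warp output with respect to the displacement field (mm^-1
// chain factor applied): returns (n,3) matrix d out(x) / d D(x) * grad_out(x)
// [[Rcpp::export]]
NumericMatrix cpp_warp_grad_dvf(NumericVector vol, IntegerVector dims,
                                NumericVector spacing, NumericVector dvf,
                                NumericVector grad_out) {
  int nx = dims[0], ny = dims[1], nz = dims[2];
  size_t n = (size_t)nx * ny * nz;
  NumericMatrix g(n, 3);
  const double *dxp = dvf.begin(), *dyp = dvf.begin() + n, *dzp = dvf.begin() + 2 * n;
  const double *v = vol.begin();
  size_t sxy = (size_t)nx * ny;
  size_t i = 0;
  for (int iz = 0; iz < nz; ++iz)
    for (int iy = 0; iy < ny; ++iy)
      for (int ix = 0; ix < nx; ++ix, ++i) {
        double gx = ix + dxp[i] / spacing[0];
        double gy = iy + dyp[i] / spacing[1];
        double gz = iz + dzp[i] / spacing[2];
        // clamped coordinates have zero derivative along the clamped axis
        bool inx = gx > 0 && gx < nx - 1, iny = gy > 0 && gy < ny - 1, inz = gz > 0 && gz < nz - 1;
        if (gx < 0) gx = 0; if (gx > nx - 1) gx = nx - 1;
        if (gy < 0) gy = 0; if (gy > ny - 1) gy = ny - 1;
        if (gz < 0) gz = 0; if (gz > nz - 1) gz = nz - 1;
        int x0 = (int)std::floor(gx); if (x0 > nx - 2) x0 = nx - 2;
        int y0 = (int)std::floor(gy); if (y0 > ny - 2) y0 = ny - 2;
        int z0 = (int)std::floor(gz); if (z0 > nz - 2) z0 = nz - 2;
        double fx = gx - x0, fy = gy - y0, fz = gz - z0;
        const double c000 = v[x0 + nx * y0 + sxy * z0], c100 = v[x0 + 1 + nx * y0 + sxy * z0];
        const double c010 = v[x0 + nx * (y0 + 1) + sxy * z0], c110 = v[x0 + 1 + nx * (y0 + 1) + sxy * z0];
        const double c001 = v[x0 + nx * y0 + sxy * (z0 + 1)], c101 = v[x0 + 1 + nx * y0 + sxy * (z0 + 1)];
        const double c011 = v[x0 + nx * (y0 + 1) + sxy * (z0 + 1)], c111 = v[x0 + 1 + nx * (y0 + 1) + sxy * (z0 + 1)];
        double ddx = (c100 - c000) * (1 - fy) * (1 - fz) + (c110 - c010) * fy * (1 - fz) +
                     (c101 - c001) * (1 - fy) * fz + (c111 - c011) * fy * fz;
        double ddy = (c010 - c000) * (1 - fx) * (1 - fz) + (c110 - c100) * fx * (1 - fz) +
                     (c011 - c001) * (1 - fx) * fz + (c111 - c101) * fx * fz;
        double c00 = c000 * (1 - fx) + c100 * fx, c10 = c010 * (1 - fx) + c110 * fx;
        double c01 = c001 * (1 - fx) + c101 * fx, c11 = c011 * (1 - fx) + c111 * fx;
        double ddz = (c01 - c00) * (1 - fy) + (c11 - c10) * fy;
        g(i, 0) = inx ? grad_out[i] * ddx / spacing[0] : 0.0;
        g(i, 1) = iny ? grad_out[i] * ddy / spacing[1] : 0.0;
        g(i, 2) = inz ? grad_out[i] * ddz / spacing[2] : 0.0;
      }
  return g;
}

// 6-connectivity connected-component labelling of a logical 3-D array
// [[Rcpp::export]]
IntegerVector cpp_label_components(LogicalVector mask, IntegerVector dims) {
  int nx = dims[0], ny = dims[1], nz = dims[2];
  size_t n = (size_t)nx * ny * nz;
  IntegerVector lab(n, 0);
  int next = 0;
  std::queue<size_t> q;
  for (size_t s = 0; s < n; ++s) {
    if (!mask[s] || lab[s]) continue;
    lab[s] = ++next;
    q.push(s);
    while (!q.empty()) {
      size_t c = q.front(); q.pop();
      int iz = c / ((size_t)nx * ny);
      int rem = c % ((size_t)nx * ny);
      int iy = rem / nx, ix = rem % nx;
      const int off[6][3] = {{1,0,0},{-1,0,0},{0,1,0},{0,-1,0},{0,0,1},{0,0,-1}};
      for (int k = 0; k < 6; ++k) {
        int jx = ix + off[k][0], jy = iy + off[k][1], jz = iz + off[k][2];
        if (jx < 0 || jx >= nx || jy < 0 || jy >= ny || jz < 0 || jz >= nz) continue;
        size_t j = jx + (size_t)nx * jy + (size_t)nx * ny * jz;
        if (mask[j] && !lab[j]) { lab[j] = next; q.push(j); }
      }
    }
  }
  lab.attr("dim") = dims;
  return lab;
}

// separable Gaussian smoothing (voxel-unit sigma, truncated at 3 sigma)
// [[Rcpp::export]]
NumericVector cpp_gauss_smooth(NumericVector vol, IntegerVector dims, NumericVector sigma) {
  int nx = dims[0], ny = dims[1], nz = dims[2];
  size_t n = (size_t)nx * ny * nz;
  std::vector<double> a(vol.begin(), vol.end()), b(n);
  int nn[3] = {nx, ny, nz};
  size_t stride[3] = {1, (size_t)nx, (size_t)nx * ny};
  for (int ax = 0; ax < 3; ++ax) {
    double s = sigma[ax];
    if (s <= 0) continue;
    int r = (int)std::ceil(3 * s);
    std::vector<double> k(2 * r + 1);
    double ksum = 0;
    for (int m = -r; m <= r; ++m) { k[m + r] = std::exp(-0.5 * m * m / (s * s)); ksum += k[m + r]; }
    for (auto &kk : k) kk /= ksum;
    int len = nn[ax];
    size_t st = stride[ax];
    // iterate over all lines along axis ax
    for (size_t base = 0; base < n; ++base) {
      // base must be the first element of its line
      size_t pos_along = (base / st) % len;
      if (pos_along != 0) continue;
      for (int m = 0; m < len; ++m) {
        double acc = 0;
        for (int t = -r; t <= r; ++t) {
          int mm = m + t;
          if (mm < 0) mm = 0; if (mm > len - 1) mm = len - 1;
          acc += k[t + r] * a[base + (size_t)mm * st];
        }
        b[base + (size_t)m * st] = acc;
      }
    }
    std::swap(a, b);
  }
  NumericVector out(a.begin(), a.end());
  out.attr("dim") = dims;
  return out;
}

// resample a volume onto a new grid (world-aligned, trilinear, clamp-to-edge)
// [[Rcpp::export]]
NumericVector cpp_resample(NumericVector vol, IntegerVector dims_in,
                           NumericVector spacing_in, NumericVector origin_in,
                           IntegerVector dims_out, NumericVector spacing_out,
                           NumericVector origin_out) {
  int nx = dims_out[0], ny = dims_out[1], nz = dims_out[2];
  NumericVector out((size_t)nx * ny * nz);
  size_t i = 0;
  for (int iz = 0; iz < nz; ++iz) {
    double z = origin_out[2] + iz * spacing_out[2];
    double gz = (z - origin_in[2]) / spacing_in[2];
    for (int iy = 0; iy < ny; ++iy) {
      double y = origin_out[1] + iy * spacing_out[1];
      double gy = (y - origin_in[1]) / spacing_in[1];
      for (int ix = 0; ix < nx; ++ix, ++i) {
        double x = origin_out[0] + ix * spacing_out[0];
        double gx = (x - origin_in[0]) / spacing_in[0];
        out[i] = tri_sample(vol.begin(), dims_in[0], dims_in[1], dims_in[2], gx, gy, gz);
      }
    }
  }
  out.attr("dim") = dims_out;
  return out;
}
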