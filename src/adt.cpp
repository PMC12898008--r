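#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

// Exact Euclidean distance transform on an anisotropic voxel lattice.
// Separable lower-envelope (parabola) passes over squared distances, one per
// axis, with spacing^2 weights; exact up to floating point, not a chamfer
// approximation.

static const double DT_INF = 1e30;

// 1D squared-distance transform of sampled function f at sample pitch s.
static void dt1d(const double* f, double* d, int n, double s,
                 std::vector<int>& v, std::vector<double>& z) {
  double s2 = s * s;
  int k = 0;
  v[0] = 0;
  z[0] = -DT_INF;
  z[1] = DT_INF;
  for (int q = 1; q < n; q++) {
    double fq = (double)q * q * s2 + f[q];
    double inter;
    for (;;) {
      int p = v[k];
      inter = (fq - ((double)p * p * s2 + f[p])) / (2.0 * s2 * (double)(q - p));
      if (inter <= z[k]) {
        k--;
      } else {
        break;
      }
    }
    k++;
    v[k] = q;
    z[k] = inter;
    z[k + 1] = DT_INF;
  }
  k = 0;
  for (int q = 0; q < n; q++) {
    while (z[k + 1] < (double)q) k++;
    double dq = (double)(q - v[k]);
    d[q] = dq * dq * s2 + f[v[k]];
  }
}

// [[Rcpp::export]]
NumericVector cpp_edt(LogicalVector mask, IntegerVector dim, NumericVector spacing) {
  const int nx = dim[0], ny = dim[1], nz = dim[2];
  const R_xlen_t n = (R_xlen_t)nx * ny * nz;
  NumericVector out(n);
  double* d = REAL(out);
  for (R_xlen_t i = 0; i < n; i++) d[i] = mask[i] ? 0.0 : DT_INF;

  int nmax = std::max(nx, std::max(ny, nz));
  std::vector<double> f(nmax), g(nmax);
  std::vector<int> v(nmax);
  std::vector<double> z(nmax + 1);

  // axis 1 (stride 1)
  for (int kz = 0; kz < nz; kz++)
    for (int jy = 0; jy < ny; jy++) {
      double* line = d + (R_xlen_t)nx * (jy + (R_xlen_t)ny * kz);
      dt1d(line, g.data(), nx, spacing[0], v, z);
      std::copy(g.begin(), g.begin() + nx, line);
    }
  // axis 2 (stride nx)
  for (int kz = 0; kz < nz; kz++)
    for (int ix = 0; ix < nx; ix++) {
      double* base = d + ix + (R_xlen_t)nx * ny * kz;
      for (int jy = 0; jy < ny; jy++) f[jy] = base[(R_xlen_t)nx * jy];
      dt1d(f.data(), g.data(), ny, spacing[1], v, z);
      for (int jy = 0; jy < ny; jy++) base[(R_xlen_t)nx * jy] = g[jy];
    }
  // axis 3 (stride nx*ny)
  const R_xlen_t sxy = (R_xlen_t)nx * ny;
  for (int jy = 0; jy < ny; jy++)
    for (int ix = 0; ix < nx; ix++) {
      double* base = d + ix + (R_xlen_t)nx * jy;
      for (int kz = 0; kz < nz; kz++) f[kz] = base[sxy * kz];
      dt1d(f.data(), g.data(), nz, spacing[2], v, z);
      for (int kz = 0; kz < nz; kz++) base[sxy * kz] = g[kz];
    }

  for (R_xlen_t i = 0; i < n; i++) d[i] = std::sqrt(d[i]);
  return out;
}

// Trilinear interpolation of a scalar field sampled at voxel centers of the
// input grid, evaluated at voxel centers of an output grid sharing the same
// origin (first voxel centers coincide). Positions outside the input
// center lattice see an implicit zero background.
// [[Rcpp::export]]
NumericVector cpp_trilinear(NumericVector values, IntegerVector dim,
                            NumericVector spacing, IntegerVector out_dim,
                            NumericVector out_spacing) {
  const int nx = dim[0], ny = dim[1], nz = dim[2];
  const int mx = out_dim[0], my = out_dim[1], mz = out_dim[2];
  const double* src = REAL(values);
  NumericVector out((R_xlen_t)mx * my * mz);
  double* dst = REAL(out);
  const R_xlen_t sxy = (R_xlen_t)nx * ny;

  std::vector<int> i0x(mx), i0y(my), i0z(mz);
  std::vector<double> fx(mx), fy(my), fz(mz);
  for (int i = 0; i < mx; i++) {
    double u = i * out_spacing[0] / spacing[0];
    double fl = std::floor(u);
    i0x[i] = (int)fl; fx[i] = u - fl;
  }
  for (int j = 0; j < my; j++) {
    double u = j * out_spacing[1] / spacing[1];
    double fl = std::floor(u);
    i0y[j] = (int)fl; fy[j] = u - fl;
  }
  for (int k = 0; k < mz; k++) {
    double u = k * out_spacing[2] / spacing[2];
    double fl = std::floor(u);
    i0z[k] = (int)fl; fz[k] = u - fl;
  }

  R_xlen_t q = 0;
  for (int k = 0; k < mz; k++) {
    int kz0 = i0z[k]; double wz = fz[k];
    for (int j = 0; j < my; j++) {
      int jy0 = i0y[j]; double wy = fy[j];
      for (int i = 0; i < mx; i++, q++) {
        int ix0 = i0x[i]; double wx = fx[i];
        double acc = 0.0;
        for (int dz = 0; dz < 2; dz++) {
          int kk = kz0 + dz;
          if (kk < 0 || kk >= nz) continue;
          double wwz = dz ? wz : 1.0 - wz;
          if (wwz == 0.0) continue;
          for (int dy = 0; dy < 2; dy++) {
            int jj = jy0 + dy;
            if (jj < 0 || jj >= ny) continue;
            double wwy = dy ? wy : 1.0 - wy;
            if (wwy == 0.0) continue;
            double w2 = wwz * wwy;
            for (int dx = 0; dx < 2; dx++) {
              int ii = ix0 + dx;
              if (ii < 0 || ii >= nx) continue;
              double wwx = dx ? wx : 1.0 - wx;
              if (wwx == 0.0) continue;
              acc += w2 * wwx * src[ii + (R_xlen_t)nx * jj + sxy * kk];
            }
          }
        }
        dst[q] = acc;
      }
    }
  }
  return out;
}
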