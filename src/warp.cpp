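#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// Tri-linear pull (sampling) and raw push (splatting) warp kernels, plus the
// derivative of the pulled value with respect to the displacement, which the
// analytic gradient of the projection-space motion loss needs.
//
// Displacements are stored in mm (world space) and converted to voxel units
// per axis inside the kernels, so anisotropic voxels stay correct. Samples
// that fall outside the grid read as 0 (air); splats that fall outside are
// dropped. push_raw uses the identical corner weights as pull, making it the
// exact linear adjoint.

static inline void corner_setup(double q, int n, int &i0, double &f) {
  i0 = (int)std::floor(q);
  f = q - i0;
}

// [[Rcpp::export(name = ".cpp_pull")]]
NumericVector cpp_pull(NumericVector img, IntegerVector dim,
                       NumericVector disp, NumericVector voxel_mm) {
  const int nx = dim[0], ny = dim[1], nz = dim[2];
  const R_xlen_t nvox = (R_xlen_t)nx * ny * nz;
  NumericVector out(nvox);
  const double *im = REAL(img), *dd = REAL(disp);
  double *op = REAL(out);
  const double ivx = 1.0 / voxel_mm[0], ivy = 1.0 / voxel_mm[1],
               ivz = 1.0 / voxel_mm[2];
  R_xlen_t idx = 0;
  for (int k = 0; k < nz; ++k)
    for (int j = 0; j < ny; ++j)
      for (int i = 0; i < nx; ++i, ++idx) {
        double qx = i + dd[idx] * ivx;
        double qy = j + dd[idx + nvox] * ivy;
        double qz = k + dd[idx + 2 * nvox] * ivz;
        int ix, iy, iz; double fx, fy, fz;
        corner_setup(qx, nx, ix, fx);
        corner_setup(qy, ny, iy, fy);
        corner_setup(qz, nz, iz, fz);
        double acc = 0.0;
        for (int dz = 0; dz <= 1; ++dz) {
          int kz = iz + dz;
          if (kz < 0 || kz >= nz) continue;
          double wz = dz ? fz : 1.0 - fz;
          if (wz == 0.0) continue;
          for (int dy = 0; dy <= 1; ++dy) {
            int ky = iy + dy;
            if (ky < 0 || ky >= ny) continue;
            double wy = dy ? fy : 1.0 - fy;
            if (wy == 0.0) continue;
            double wzy = wz * wy;
            for (int dx = 0; dx <= 1; ++dx) {
              int kx = ix + dx;
              if (kx < 0 || kx >= nx) continue;
              double wx = dx ? fx : 1.0 - fx;
              if (wx == 0.0) continue;
              acc += wzy * wx *
                im[kx + (R_xlen_t)nx * (ky + (R_xlen_t)ny * kz)];
            }
          }
        }
        op[idx] = acc;
      }
  return out;
}

// [[Rcpp::export(name = ".cpp_push_raw")]]
NumericVector cpp_push_raw(NumericVector img, IntegerVector dim,
                           NumericVector disp, NumericVector voxel_mm) {
  const int nx = dim[0], ny = dim[1], nz = dim[2];
  const R_xlen_t nvox = (R_xlen_t)nx * ny * nz;
  NumericVector out(nvox);
  const double *im = REAL(img), *dd = REAL(disp);
  double *op = REAL(out);
  const double ivx = 1.0 / voxel_mm[0], ivy = 1.0 / voxel_mm[1],
               ivz = 1.0 / voxel_mm[2];
  R_xlen_t idx = 0;
  for (int k = 0; k < nz; ++k)
    for (int j = 0; j < ny; ++j)
      for (int i = 0; i < nx; ++i, ++idx) {
        double val = im[idx];
        if (val == 0.0) continue;
        double qx = i + dd[idx] * ivx;
        double qy = j + dd[idx + nvox] * ivy;
        double qz = k + dd[idx + 2 * nvox] * ivz;
        int ix, iy, iz; double fx, fy, fz;
        corner_setup(qx, nx, ix, fx);
        corner_setup(qy, ny, iy, fy);
        corner_setup(qz, nz, iz, fz);
        for (int dz = 0; dz <= 1; ++dz) {
          int kz = iz + dz;
          if (kz < 0 || kz >= nz) continue;
          double wz = dz ? fz : 1.0 - fz;
          if (wz == 0.0) continue;
          for (int dy = 0; dy <= 1; ++dy) {
            int ky = iy + dy;
            if (ky < 0 || ky >= ny) continue;
            double wy = dy ? fy : 1.0 - fy;
            if (wy == 0.0) continue;
            double wzy = wz * wy;
            for (int dx = 0; dx <= 1; ++dx) {
              int kx = ix + dx;
              if (kx < 0 || kx >= nx) continue;
              double wx = dx ? fx : 1.0 - fx;
              if (wx == 0.0) continue;
              op[kx + (R_xlen_t)nx * (ky + (R_xlen_t)ny * kz)] +=
                val * wzy * wx;
            }
          }
        }
      }
  return out;
}

// d(pulled value)/d(displacement in mm), evaluated at the current field:
// spatial derivative of the tri-linear interpolant at the sample position,
// divided by the voxel size per axis. Returned as a (nvox x 3) layout.
// [[Rcpp::export(name = ".cpp_pull_grad")]]
NumericVector cpp_pull_grad(NumericVector img, IntegerVector dim,
                            NumericVector disp, NumericVector voxel_mm) {
  const int nx = dim[0], ny = dim[1], nz = dim[2];
  const R_xlen_t nvox = (R_xlen_t)nx * ny * nz;
  NumericVector out(3 * nvox);
  const double *im = REAL(img), *dd = REAL(disp);
  double *op = REAL(out);
  const double iv[3] = {1.0 / voxel_mm[0], 1.0 / voxel_mm[1],
                        1.0 / voxel_mm[2]};
  R_xlen_t idx = 0;
  for (int k = 0; k < nz; ++k)
    for (int j = 0; j < ny; ++j)
      for (int i = 0; i < nx; ++i, ++idx) {
        double qx = i + dd[idx] * iv[0];
        double qy = j + dd[idx + nvox] * iv[1];
        double qz = k + dd[idx + 2 * nvox] * iv[2];
        int ix, iy, iz; double fx, fy, fz;
        corner_setup(qx, nx, ix, fx);
        corner_setup(qy, ny, iy, fy);
        corner_setup(qz, nz, iz, fz);
        double gx = 0.0, gy = 0.0, gz = 0.0;
        for (int dz = 0; dz <= 1; ++dz) {
          int kz = iz + dz;
          if (kz < 0 || kz >= nz) continue;
          double wz = dz ? fz : 1.0 - fz;
          double sz = dz ? 1.0 : -1.0;
          for (int dy = 0; dy <= 1; ++dy) {
            int ky = iy + dy;
            if (ky < 0 || ky >= ny) continue;
            double wy = dy ? fy : 1.0 - fy;
            double sy = dy ? 1.0 : -1.0;
            for (int dx = 0; dx <= 1; ++dx) {
              int kx = ix + dx;
              if (kx < 0 || kx >= nx) continue;
              double wx = dx ? fx : 1.0 - fx;
              double sx = dx ? 1.0 : -1.0;
              double v = im[kx + (R_xlen_t)nx * (ky + (R_xlen_t)ny * kz)];
              gx += sx * wy * wz * v;
              gy += wx * sy * wz * v;
              gz += wx * wy * sz * v;
            }
          }
        }
        op[idx] = gx * iv[0];
        op[idx + nvox] = gy * iv[1];
        op[idx + 2 * nvox] = gz * iv[2];
      }
  return out;
}
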