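#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// Joseph (slice-interpolated) cone-beam projector and its exact transpose.
//
// Geometry convention: world coordinates in mm, rotation axis = z (third array
// dimension). At gantry angle 0 the source sits on the +y axis at distance
// `sad` from the isocenter; angles increase counter-clockwise seen from +z.
// The flat detector is centered on the central ray at distance (sdd - sad)
// behind the isocenter; detector columns run along the rotated +x axis,
// detector rows along +z. A voxel value is the attenuation (per mm) at the
// voxel center; line integrals are in attenuation * mm.
//
// For each source->pixel ray the dominant volume axis is selected and the
// volume is traversed slice by slice along it, bilinearly interpolating in
// the two transverse axes. The backprojector scatters with the identical
// weights, so <A x, p> == <x, A^T p> to rounding error, which the
// projection-space motion optimization relies on.

struct RayGeom {
  double src[3];     // source position, voxel coords
  double dir[3];     // pixel - source, voxel coords
  double len_mm;     // ray length in mm
};

static inline void pixel_ray(int row, int col,
                             double sad, double sdd,
                             double du, double dv,
                             int nrow, int ncol,
                             double ca, double sa,
                             const double *origin, const double *vox,
                             RayGeom &rg) {
  // source and pixel in world mm
  double sx = -sad * sa, sy = sad * ca, sz = 0.0;
  double dcx = (sdd - sad) * sa, dcy = -(sdd - sad) * ca, dcz = 0.0;
  double u = (col - 0.5 * (ncol - 1)) * du;
  double v = (row - 0.5 * (nrow - 1)) * dv;
  double px = dcx + u * ca, py = dcy + u * sa, pz = dcz + v;
  double wx = px - sx, wy = py - sy, wz = pz - sz;
  rg.len_mm = std::sqrt(wx * wx + wy * wy + wz * wz);
  rg.src[0] = (sx - origin[0]) / vox[0];
  rg.src[1] = (sy - origin[1]) / vox[1];
  rg.src[2] = (sz - origin[2]) / vox[2];
  rg.dir[0] = wx / vox[0];
  rg.dir[1] = wy / vox[1];
  rg.dir[2] = wz / vox[2];
}

// Traverse one ray; if `forward`, accumulate into *acc from vol; else scatter
// val into vol. Template keeps one copy of the traversal logic.
template <bool FORWARD>
static inline void trace_ray(const RayGeom &rg,
                             double *vol, const int *n,
                             double *acc, double val) {
  // dominant axis in voxel coordinates
  int a = 0;
  double ad = std::fabs(rg.dir[0]);
  if (std::fabs(rg.dir[1]) > ad) { a = 1; ad = std::fabs(rg.dir[1]); }
  if (std::fabs(rg.dir[2]) > ad) { a = 2; ad = std::fabs(rg.dir[2]); }
  if (ad <= 0.0) return;
  int b = (a + 1) % 3, c = (a + 2) % 3;
  // arc length in mm advanced per unit slice step along axis a
  double step_mm = rg.len_mm / ad;
  const int na = n[a], nb = n[b], nc = n[c];
  // strides for column-major (nx fastest) layout
  int stride[3] = {1, n[0], n[0] * n[1]};
  const int sa_ = stride[a], sb_ = stride[b], sc_ = stride[c];
  double inv_da = 1.0 / rg.dir[a];
  double sum = 0.0;
  for (int m = 0; m < na; ++m) {
    double t = (m - rg.src[a]) * inv_da;
    if (t <= 0.0) continue;  // behind the source
    double qb = rg.src[b] + t * rg.dir[b];
    double qc = rg.src[c] + t * rg.dir[c];
    int ib = (int)std::floor(qb);
    int ic = (int)std::floor(qc);
    double fb = qb - ib, fc = qc - ic;
    // bilinear corners; samples outside the grid contribute zero (air)
    for (int db = 0; db <= 1; ++db) {
      int jb = ib + db;
      if (jb < 0 || jb >= nb) continue;
      double wb = db ? fb : 1.0 - fb;
      if (wb == 0.0) continue;
      for (int dc = 0; dc <= 1; ++dc) {
        int jc = ic + dc;
        if (jc < 0 || jc >= nc) continue;
        double wc = dc ? fc : 1.0 - fc;
        if (wc == 0.0) continue;
        int idx = m * sa_ + jb * sb_ + jc * sc_;
        double w = wb * wc * step_mm;
        if (FORWARD) sum += vol[idx] * w;
        else vol[idx] += val * w;
      }
    }
  }
  if (FORWARD) *acc = sum;
}

// [[Rcpp::export(name = ".cpp_forward_project")]]
NumericMatrix cpp_forward_project(NumericVector vol, IntegerVector dim,
                                  NumericVector voxel_mm, NumericVector origin_mm,
                                  double sad, double sdd,
                                  int det_rows, int det_cols,
                                  double pix_row_mm, double pix_col_mm,
                                  double angle_deg) {
  int n[3] = {dim[0], dim[1], dim[2]};
  double vox[3] = {voxel_mm[0], voxel_mm[1], voxel_mm[2]};
  double org[3] = {origin_mm[0], origin_mm[1], origin_mm[2]};
  double th = angle_deg * M_PI / 180.0;
  double ca = std::cos(th), sa = std::sin(th);
  NumericMatrix out(det_rows, det_cols);
  double *volp = REAL(vol);
  RayGeom rg;
  for (int col = 0; col < det_cols; ++col) {
    for (int row = 0; row < det_rows; ++row) {
      pixel_ray(row, col, sad, sdd, pix_col_mm, pix_row_mm,
                det_rows, det_cols, ca, sa, org, vox, rg);
      double acc = 0.0;
      trace_ray<true>(rg, volp, n, &acc, 0.0);
      out(row, col) = acc;
    }
  }
  return out;
}

// [[Rcpp::export(name = ".cpp_back_project")]]
NumericVector cpp_back_project(NumericMatrix proj, IntegerVector dim,
                               NumericVector voxel_mm, NumericVector origin_mm,
                               double sad, double sdd,
                               double pix_row_mm, double pix_col_mm,
                               double angle_deg) {
  int n[3] = {dim[0], dim[1], dim[2]};
  double vox[3] = {voxel_mm[0], voxel_mm[1], voxel_mm[2]};
  double org[3] = {origin_mm[0], origin_mm[1], origin_mm[2]};
  double th = angle_deg * M_PI / 180.0;
  double ca = std::cos(th), sa = std::sin(th);
  int det_rows = proj.nrow(), det_cols = proj.ncol();
  NumericVector vol(n[0] * n[1] * n[2]);
  double *volp = REAL(vol);
  RayGeom rg;
  for (int col = 0; col < det_cols; ++col) {
    for (int row = 0; row < det_rows; ++row) {
      double val = proj(row, col);
      if (val == 0.0) continue;
      pixel_ray(row, col, sad, sdd, pix_col_mm, pix_row_mm,
                det_rows, det_cols, ca, sa, org, vox, rg);
      trace_ray<false>(rg, volp, n, (double *)0, val);
    }
  }
  return vol;
}
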