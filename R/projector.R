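#' Forward project a volume for one gantry angle
#'
#' Computes the cone-beam line integrals `y_t = A_t x` of an attenuation
#' volume for the geometry of one acquisition frame, using Joseph
#' (slice-interpolated) ray tracing. The operator is linear in the volume;
#' output units are attenuation times mm.
#'
#' @param vol a [volume()].
#' @param geom a [scan_geometry()].
#' @param frame 1-based frame index.
#' @return matrix `detector_rows x detector_cols` of line integrals.
#' @seealso [back_project()] for the exact transpose.
#' @export
forward_project <- function(vol, geom, frame) {
  stopifnot(inherits(vol, "cbct_volume"), inherits(geom, "scan_geometry"))
  if (frame < 1L || frame > geom$n_frames) {
    stop(sprintf("frame %d out of range [1, %d]", frame, geom$n_frames))
  }
  if (!all(is.finite(vol$values))) stop("volume must be finite")
  .cpp_forward_project(
    as.numeric(vol$values), vol$grid$shape,
    vol$grid$voxel_size_mm, vol$grid$origin_mm,
    geom$source_to_isocenter_mm, geom$source_to_detector_mm,
    geom$detector_rows, geom$detector_cols,
    geom$pixel_spacing_mm[1], geom$pixel_spacing_mm[2],
    geom$angles_deg[frame])
}

#' Back project one detector image into a volume
#'
#' Applies `A_t^T`, the exact adjoint of [forward_project()] under the
#' standard Euclidean inner products: each detector value is scattered back
#' along its ray with the same interpolation weights the forward pass used.
#'
#' @param proj matrix `detector_rows x detector_cols`.
#' @param geom a [scan_geometry()].
#' @param frame 1-based frame index.
#' @param grid the target [volume_grid()].
#' @return a [volume()] holding `A_t^T proj`.
#' @export
back_project <- function(proj, geom, frame, grid) {
  stopifnot(inherits(geom, "scan_geometry"), inherits(grid, "volume_grid"))
  proj <- as.matrix(proj)
  if (nrow(proj) != geom$detector_rows || ncol(proj) != geom$detector_cols) {
    stop("projection shape does not match detector grid")
  }
  if (frame < 1L || frame > geom$n_frames) {
    stop(sprintf("frame %d out of range [1, %d]", frame, geom$n_frames))
  }
  v <- .cpp_back_project(
    proj, grid$shape, grid$voxel_size_mm, grid$origin_mm,
    geom$source_to_isocenter_mm, geom$source_to_detector_mm,
    geom$pixel_spacing_mm[1], geom$pixel_spacing_mm[2],
    geom$angles_deg[frame])
  volume(grid, array(v, dim = grid$shape))
}

#' Log-transform photon counts to line integrals
#'
#' Converts a counts-domain projection set to the linear (line-integral)
#' domain via `y = -ln(max(s, floor) / s0)`, inverting the Beer-Lambert
#' model `s = s0 exp(-y)`. Counts are clamped at `floor_counts` before the
#' log so that detector zeros under heavy noise do not produce infinities.
#'
#' @param s a counts-domain [projection_set()].
#' @param s0 source intensity (unattenuated counts), positive.
#' @param floor_counts clamp applied to counts before the log (default 1).
#' @return a line-integral [projection_set()].
#' @export
log_transform <- function(s, s0, floor_counts = 1) {
  stopifnot(inherits(s, "projection_set"))
  if (s$domain != "counts") stop("log_transform expects counts-domain data")
  if (!(s0 > 0)) stop("s0 must be positive")
  y <- -log(pmax(s$values, floor_counts) / s0)
  projection_set(s$geometry, array(y, dim = dim(s$values)), "line_integral")
}

#' Estimate the source intensity from background pixels
#'
#' Mean detector counts over a region that no object shadows, pooled across
#' all frames; the standard flat-field estimate of `s0` when the bare-beam
#' intensity was not recorded.
#'
#' @param s a counts-domain [projection_set()].
#' @param background_region list with integer vectors `rows` and `cols`
#'   (1-based detector indices) delimiting the background ROI.
#' @return scalar intensity estimate.
#' @export
estimate_source_intensity <- function(s, background_region) {
  stopifnot(inherits(s, "projection_set"))
  if (s$domain != "counts") stop("expects counts-domain data")
  rows <- as.integer(background_region$rows)
  cols <- as.integer(background_region$cols)
  if (length(rows) == 0L || length(cols) == 0L) stop("ROI must be non-empty")
  if (any(rows < 1L) || any(rows > s$geometry$detector_rows) ||
      any(cols < 1L) || any(cols > s$geometry$detector_cols)) {
    stop("ROI extends outside the detector")
  }
  mean(s$values[rows, cols, , drop = FALSE])
}
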