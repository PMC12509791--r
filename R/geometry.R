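#' Cone-beam scan geometry
#'
#' Describes a circular cone-beam acquisition: a point source and a flat
#' detector panel rotating about the z (superior-inferior) axis, one 2D
#' projection per gantry angle. At angle 0 the source lies on the +y axis;
#' angles increase counter-clockwise viewed from +z. All lengths are in mm,
#' times in seconds, angles in degrees.
#'
#' @param source_to_isocenter_mm distance from source to rotation axis (SAD).
#' @param source_to_detector_mm distance from source to detector plane (SDD);
#'   must exceed the SAD.
#' @param detector_rows,detector_cols detector grid size; rows run along z.
#' @param pixel_spacing_mm length-2 vector `c(row, col)` of pixel pitch.
#' @param angles_deg per-frame gantry angles.
#' @param timestamps_s per-frame acquisition times, strictly increasing.
#' @return A `scan_geometry` object.
#' @export
scan_geometry <- function(source_to_isocenter_mm,
                          source_to_detector_mm,
                          detector_rows, detector_cols,
                          pixel_spacing_mm,
                          angles_deg, timestamps_s) {
  if (length(pixel_spacing_mm) == 1L) {
    pixel_spacing_mm <- rep(pixel_spacing_mm, 2L)
  }
  if (!(source_to_isocenter_mm > 0)) {
    stop("source_to_isocenter_mm must be positive")
  }
  if (!(source_to_detector_mm > source_to_isocenter_mm)) {
    stop("source_to_detector_mm must exceed source_to_isocenter_mm")
  }
  if (length(angles_deg) != length(timestamps_s)) {
    stop("angles_deg and timestamps_s must have equal length")
  }
  if (length(timestamps_s) > 1L && any(diff(timestamps_s) <= 0)) {
    stop("timestamps_s must be strictly increasing")
  }
  structure(list(
    source_to_isocenter_mm = as.numeric(source_to_isocenter_mm),
    source_to_detector_mm = as.numeric(source_to_detector_mm),
    detector_rows = as.integer(detector_rows),
    detector_cols = as.integer(detector_cols),
    pixel_spacing_mm = as.numeric(pixel_spacing_mm),
    angles_deg = as.numeric(angles_deg),
    timestamps_s = as.numeric(timestamps_s),
    n_frames = length(angles_deg)
  ), class = "scan_geometry")
}

#' Uniform 3D voxel grid
#'
#' @param shape voxel counts `c(nx, ny, nz)`.
#' @param voxel_size_mm voxel edge lengths; scalar recycled to 3.
#' @param origin_mm world position of the center of voxel (0,0,0); defaults
#'   to placing the grid center at the isocenter.
#' @return A `volume_grid` object.
#' @export
volume_grid <- function(shape, voxel_size_mm, origin_mm = NULL) {
  shape <- as.integer(shape)
  if (length(shape) != 3L || any(shape < 1L)) {
    stop("shape must be three voxel counts >= 1")
  }
  if (length(voxel_size_mm) == 1L) voxel_size_mm <- rep(voxel_size_mm, 3L)
  if (any(voxel_size_mm <= 0)) stop("voxel sizes must be positive")
  if (is.null(origin_mm)) {
    origin_mm <- -(shape - 1) / 2 * voxel_size_mm
  }
  structure(list(
    shape = shape,
    voxel_size_mm = as.numeric(voxel_size_mm),
    origin_mm = as.numeric(origin_mm)
  ), class = "volume_grid")
}

#' Attenuation volume on a grid
#'
#' @param grid a [volume_grid()].
#' @param values 3D array of attenuation (per mm), or a scalar to fill.
#' @return A `cbct_volume` object.
#' @export
volume <- function(grid, values = 0) {
  stopifnot(inherits(grid, "volume_grid"))
  if (length(values) == 1L) {
    values <- array(values, dim = grid$shape)
  }
  values <- as.array(values)
  if (!identical(dim(values), as.integer(grid$shape))) {
    stop("values shape does not match grid")
  }
  if (!all(is.finite(values))) stop("volume values must be finite")
  structure(list(grid = grid, values = values), class = "cbct_volume")
}

#' Per-frame detector data
#'
#' @param geometry a [scan_geometry()].
#' @param values array `detector_rows x detector_cols x n_frames`.
#' @param domain `"counts"` (photon counts) or `"line_integral"`
#'   (log-transformed attenuation line integrals).
#' @return A `projection_set` object.
#' @export
projection_set <- function(geometry, values, domain = c("line_integral", "counts")) {
  stopifnot(inherits(geometry, "scan_geometry"))
  domain <- match.arg(domain)
  values <- as.array(values)
  expect_dim <- c(geometry$detector_rows, geometry$detector_cols,
                  geometry$n_frames)
  if (length(dim(values)) != 3L || !identical(dim(values), as.integer(expect_dim))) {
    stop("projection array must be detector_rows x detector_cols x n_frames")
  }
  if (domain == "counts" && any(values < 0)) {
    stop("counts-domain projections must be non-negative")
  }
  structure(list(geometry = geometry, values = values, domain = domain),
            class = "projection_set")
}

#' @export
print.scan_geometry <- function(x, ...) {
  cat(sprintf(
    "scan_geometry: %d frames, SAD %.0f mm, SDD %.0f mm, detector %dx%d @ %.2fx%.2f mm\n",
    x$n_frames, x$source_to_isocenter_mm, x$source_to_detector_mm,
    x$detector_rows, x$detector_cols,
    x$pixel_spacing_mm[1], x$pixel_spacing_mm[2]))
  invisible(x)
}

#' @export
print.cbct_volume <- function(x, ...) {
  cat(sprintf("cbct_volume: %s voxels @ %s mm, range [%.4g, %.4g]\n",
              paste(x$grid$shape, collapse = "x"),
              paste(signif(x$grid$voxel_size_mm, 3), collapse = "x"),
              min(x$values), max(x$values)))
  invisible(x)
}

#' @export
print.projection_set <- function(x, ...) {
  cat(sprintf("projection_set (%s): %d frames of %dx%d\n", x$domain,
              x$geometry$n_frames, x$geometry$detector_rows,
              x$geometry$detector_cols))
  invisible(x)
}

# world coordinates (mm) of voxel centers along one axis
grid_axis_mm <- function(grid, axis) {
  grid$origin_mm[axis] + (seq_len(grid$shape[axis]) - 1) * grid$voxel_size_mm[axis]
}
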