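#' Spline configuration for the low-rank motion model
#'
#' The deformation model is a free-form deformation on uniformly spaced cubic
#' B-spline control points, factorized into spatial components scaled by
#' temporal components (a low-rank spatio-temporal model). This object fixes
#' the basis resolution: the number of spatial control points per dimension
#' and the temporal control-point rate in control points per second of scan
#' time.
#'
#' @param spatial_control_points control points per spatial dimension;
#'   scalar recycled to 3. At least 4 (cubic support).
#' @param temporal_rate_hz temporal control points per second, positive.
#' @return A `spline_config` object (degree is fixed cubic).
#' @export
spline_config <- function(spatial_control_points = 32, temporal_rate_hz = 2.0) {
  if (length(spatial_control_points) == 1L) {
    spatial_control_points <- rep(spatial_control_points, 3L)
  }
  spatial_control_points <- as.integer(spatial_control_points)
  if (any(spatial_control_points < 4L)) {
    stop("cubic B-splines need at least 4 control points per dimension")
  }
  if (!(temporal_rate_hz > 0)) stop("temporal_rate_hz must be positive")
  structure(list(
    spatial_control_points = spatial_control_points,
    temporal_rate_hz = as.numeric(temporal_rate_hz),
    degree = 3L
  ), class = "spline_config")
}

# clamped uniform knot vector giving n_basis cubic basis functions on [a, b]
clamped_knots <- function(a, b, n_basis) {
  n_intervals <- n_basis - 3L
  if (n_intervals < 1L) stop("need at least 4 basis functions")
  breaks <- seq(a, b, length.out = n_intervals + 1L)
  c(rep(a, 3L), breaks, rep(b, 3L))
}

# evaluate the clamped cubic basis (or a derivative) at points x; rows for x
# outside [a, b] are zero (no spline support there)
basis_matrix <- function(knots, x, deriv = 0L) {
  a <- knots[4L]; b <- knots[length(knots) - 3L]
  inside <- x >= a & x <= b
  n_basis <- length(knots) - 4L
  out <- matrix(0, length(x), n_basis)
  if (any(inside)) {
    out[inside, ] <- splines::splineDesign(
      knots, x[inside], ord = 4L, derivs = rep(deriv, sum(inside)))
  }
  out
}

#' Per-axis spatial B-spline basis tables
#'
#' Evaluates the 1D clamped cubic B-spline basis of each spatial axis at
#' every voxel-center coordinate of `grid`. The 3D spatial basis is the
#' tensor product of these tables; downstream code expands coefficient
#' arrays with them separably. The control grid spans the grid extent
#' exactly, with clamped (replicated) boundary knots.
#'
#' @param config a [spline_config()].
#' @param grid a [volume_grid()].
#' @param deriv derivative order per axis (0, 1 or 2), recycled to 3.
#' @return list of matrices `Bx` (`nx x n1`), `By`, `Bz` plus the knot
#'   vectors used.
#' @export
spatial_basis <- function(config, grid, deriv = 0L) {
  stopifnot(inherits(config, "spline_config"), inherits(grid, "volume_grid"))
  if (length(deriv) == 1L) deriv <- rep(deriv, 3L)
  ax <- lapply(1:3, function(a) grid_axis_mm(grid, a))
  kn <- lapply(1:3, function(a) {
    clamped_knots(ax[[a]][1], ax[[a]][grid$shape[a]],
                  config$spatial_control_points[a])
  })
  B <- lapply(1:3, function(a) basis_matrix(kn[[a]], ax[[a]], deriv[a]))
  list(Bx = B[[1]], By = B[[2]], Bz = B[[3]], knots = kn)
}

#' Temporal B-spline basis matrix
#'
#' One row per frame time, one column per temporal control point. The knot
#' density is `temporal_rate_hz` control points per second over
#' `time_range`, clamped at the boundaries so the basis spans the full scan;
#' rows sum to 1 on the interior (partition of unity).
#'
#' @param config a [spline_config()].
#' @param timestamps frame times in seconds.
#' @param time_range length-2 span of the basis; defaults to the range of
#'   `timestamps`.
#' @return matrix `length(timestamps) x n_temporal`; attribute
#'   `n_interior` holds the interior control-point count (rate x duration)
#'   before boundary padding, attribute `knots` the knot vector.
#' @export
temporal_basis <- function(config, timestamps, time_range = range(timestamps)) {
  stopifnot(inherits(config, "spline_config"))
  if (length(timestamps) == 0L) stop("timestamps must be non-empty")
  duration <- diff(time_range)
  if (!(duration > 0)) stop("time_range must have positive length")
  n_interior <- max(1L, as.integer(round(config$temporal_rate_hz * duration)))
  n_basis <- n_interior + 3L
  kn <- clamped_knots(time_range[1], time_range[2], n_basis)
  B <- basis_matrix(kn, timestamps)
  attr(B, "n_interior") <- n_interior
  attr(B, "knots") <- kn
  B
}

#' Low-rank spatio-temporal motion parameters
#'
#' Holds, per spatio-temporal component, one scalar coefficient per spatial
#' control point for each displacement axis (units mm) and one unitless
#' coefficient per temporal control point. The displacement at voxel r and
#' time t is the sum over components of the spatial expansion scaled by the
#' temporal expansion; zero coefficients give identity motion exactly.
#'
#' @param config a [spline_config()].
#' @param grid the [volume_grid()] whose extent the spatial basis spans.
#' @param time_range_s length-2 scan time span in seconds.
#' @param n_components model rank, at least 1.
#' @param components optional list (length `n_components`) of lists with 3D
#'   arrays `cx`, `cy`, `cz` and vector `ct`; defaults to all zeros.
#' @return A `motion_parameters` object.
#' @export
motion_parameters <- function(config, grid, time_range_s, n_components = 1L,
                              components = NULL) {
  stopifnot(inherits(config, "spline_config"), inherits(grid, "volume_grid"))
  n_components <- as.integer(n_components)
  if (n_components < 1L) stop("n_components must be at least 1")
  ncp <- config$spatial_control_points
  tb <- temporal_basis(config, time_range_s, time_range_s)
  n_temporal <- ncol(tb)
  zero_comp <- function() list(
    cx = array(0, ncp), cy = array(0, ncp), cz = array(0, ncp),
    ct = numeric(n_temporal))
  if (is.null(components)) {
    components <- replicate(n_components, zero_comp(), simplify = FALSE)
  }
  if (length(components) != n_components) {
    stop("components list length must equal n_components")
  }
  for (cmp in components) {
    for (f in c("cx", "cy", "cz")) {
      if (!identical(dim(as.array(cmp[[f]])), as.integer(ncp))) {
        stop("spatial coefficient array shape does not match config")
      }
      if (!all(is.finite(cmp[[f]]))) stop("coefficients must be finite")
    }
    if (length(cmp$ct) != n_temporal || !all(is.finite(cmp$ct))) {
      stop("temporal coefficient length does not match config")
    }
  }
  spatial_knots <- lapply(1:3, function(a) {
    ax <- grid_axis_mm(grid, a)
    clamped_knots(ax[1], ax[grid$shape[a]], ncp[a])
  })
  structure(list(
    config = config,
    grid = grid,
    spatial_knots = spatial_knots,
    time_range_s = as.numeric(time_range_s),
    n_components = n_components,
    n_temporal = n_temporal,
    components = components
  ), class = "motion_parameters")
}

#' Total number of free parameters of a motion model
#' @param params a [motion_parameters()].
#' @return integer count `n_components * (3 * prod(spatial) + n_temporal)`.
#' @export
n_parameters <- function(params) {
  stopifnot(inherits(params, "motion_parameters"))
  params$n_components *
    (3L * prod(params$config$spatial_control_points) + params$n_temporal)
}

#' Dense displacement field at one time point
#'
#' @param grid a [volume_grid()].
#' @param displacement 4D array `nx x ny x nz x 3` of per-voxel displacement
#'   in mm (x, y, z components), or scalar 0 for the identity field.
#' @param time_s frame time.
#' @return A `motion_field` object.
#' @export
motion_field <- function(grid, displacement = 0, time_s = 0) {
  stopifnot(inherits(grid, "volume_grid"))
  if (length(displacement) == 1L) {
    displacement <- array(displacement, c(grid$shape, 3L))
  }
  if (!identical(dim(displacement), as.integer(c(grid$shape, 3L)))) {
    stop("displacement must be nx x ny x nz x 3")
  }
  if (!all(is.finite(displacement))) stop("displacement must be finite")
  structure(list(grid = grid, displacement = displacement,
                 time_s = as.numeric(time_s)),
            class = "motion_field")
}

# separable tensor-product expansion: coef [n1,n2,n3] -> field [nx,ny,nz]
expand3 <- function(coef, Bx, By, Bz) {
  n <- dim(coef)
  nx <- nrow(Bx); ny <- nrow(By); nz <- nrow(Bz)
  a <- Bx %*% matrix(coef, n[1], n[2] * n[3])
  a <- aperm(array(a, c(nx, n[2], n[3])), c(2, 1, 3))
  b <- By %*% matrix(a, n[2], nx * n[3])
  b <- aperm(array(b, c(ny, nx, n[3])), c(2, 1, 3))
  array(matrix(b, nx * ny, n[3]) %*% t(Bz), c(nx, ny, nz))
}

# adjoint of expand3: field [nx,ny,nz] -> coefficient-space array [n1,n2,n3]
contract3 <- function(field, Bx, By, Bz) {
  expand3(field, t(Bx), t(By), t(Bz))
}

# basis tables of a parameter set's (fixed) spatial knots, evaluated on an
# arbitrary grid; voxels outside the knot span get zero rows
params_spatial_basis <- function(params, grid, deriv = 0L) {
  if (length(deriv) == 1L) deriv <- rep(deriv, 3L)
  B <- lapply(1:3, function(a) {
    basis_matrix(params$spatial_knots[[a]], grid_axis_mm(grid, a), deriv[a])
  })
  list(Bx = B[[1]], By = B[[2]], Bz = B[[3]], knots = params$spatial_knots)
}

# spatial component fields sigma_c: list over components of [nx,ny,nz,3]
spatial_component_fields <- function(params, grid, basis = NULL) {
  if (is.null(basis)) basis <- params_spatial_basis(params, grid)
  lapply(params$components, function(cmp) {
    arr <- array(0, c(grid$shape, 3L))
    arr[, , , 1] <- expand3(cmp$cx, basis$Bx, basis$By, basis$Bz)
    arr[, , , 2] <- expand3(cmp$cy, basis$Bx, basis$By, basis$Bz)
    arr[, , , 3] <- expand3(cmp$cz, basis$Bx, basis$By, basis$Bz)
    arr
  })
}

# temporal component values tau_c(t) for arbitrary times: matrix [T, n_comp]
temporal_component_values <- function(params, times) {
  B <- temporal_basis(params$config, times, params$time_range_s)
  out <- vapply(params$components, function(cmp) as.numeric(B %*% cmp$ct),
                numeric(length(times)))
  matrix(out, nrow = length(times))
}

#' Evaluate the motion model as a dense displacement field
#'
#' Expands the low-rank spline coefficients into the per-voxel displacement
#' at one frame time: the sum over components of the spatial B-spline
#' expansion of `cx`, `cy`, `cz` scaled by the temporal spline value.
#'
#' @param params a [motion_parameters()].
#' @param grid evaluation [volume_grid()] (voxels outside the spatial spline
#'   support get zero displacement).
#' @param frame_time time in seconds.
#' @return a [motion_field()].
#' @export
evaluate_motion_field <- function(params, grid, frame_time) {
  stopifnot(inherits(params, "motion_parameters"), inherits(grid, "volume_grid"))
  sig <- spatial_component_fields(params, grid)
  tau <- temporal_component_values(params, frame_time)
  disp <- array(0, c(grid$shape, 3L))
  for (ci in seq_len(params$n_components)) {
    disp <- disp + sig[[ci]] * tau[1, ci]
  }
  motion_field(grid, disp, frame_time)
}

#' Spatial Jacobian of the displacement field
#'
#' Analytic per-voxel displacement-gradient tensor, from the B-spline
#' derivative expansion: entry `[.., p, d]` is the derivative of
#' displacement component p with respect to world direction d (unitless,
#' mm per mm).
#'
#' @inheritParams evaluate_motion_field
#' @return 5D array `nx x ny x nz x 3 x 3`.
#' @export
motion_jacobian <- function(params, grid, frame_time) {
  stopifnot(inherits(params, "motion_parameters"), inherits(grid, "volume_grid"))
  bd <- list(
    params_spatial_basis(params, grid, deriv = c(1L, 0L, 0L)),
    params_spatial_basis(params, grid, deriv = c(0L, 1L, 0L)),
    params_spatial_basis(params, grid, deriv = c(0L, 0L, 1L)))
  tau <- temporal_component_values(params, frame_time)
  J <- array(0, c(grid$shape, 3L, 3L))
  coef_names <- c("cx", "cy", "cz")
  for (ci in seq_len(params$n_components)) {
    cmp <- params$components[[ci]]
    for (p in 1:3) {
      for (d in 1:3) {
        B <- bd[[d]]
        J[, , , p, d] <- J[, , , p, d] +
          expand3(cmp[[coef_names[p]]], B$Bx, B$By, B$Bz) * tau[1, ci]
      }
    }
  }
  J
}

#' Displacement trajectory of one voxel over time
#'
#' Evaluates the model displacement at a single voxel for a set of frame
#' times — the "motion profile" used to compare estimated motion with
#' ground truth at a probe point (e.g., on the lung-diaphragm interface).
#'
#' @param params a [motion_parameters()].
#' @param grid evaluation [volume_grid()].
#' @param voxel 1-based voxel index triple.
#' @param times frame times in seconds.
#' @return matrix `length(times) x 3` of displacements in mm (x, y, z).
#' @export
motion_profile_at <- function(params, grid, voxel, times) {
  stopifnot(inherits(params, "motion_parameters"))
  basis <- params_spatial_basis(params, grid)
  tau <- temporal_component_values(params, times)
  out <- matrix(0, length(times), 3)
  bx <- basis$Bx[voxel[1], , drop = FALSE]
  by <- basis$By[voxel[2], , drop = FALSE]
  bz <- basis$Bz[voxel[3], , drop = FALSE]
  coef_names <- c("cx", "cy", "cz")
  for (ci in seq_len(params$n_components)) {
    cmp <- params$components[[ci]]
    for (p in 1:3) {
      s <- expand3(cmp[[coef_names[p]]], bx, by, bz)[1, 1, 1]
      out[, p] <- out[, p] + s * tau[, ci]
    }
  }
  out
}

# flatten coefficients to one numeric vector (optimizer order: per component
# cx, cy, cz, ct) and back
params_to_vector <- function(params) {
  unlist(lapply(params$components, function(cmp) {
    c(as.numeric(cmp$cx), as.numeric(cmp$cy), as.numeric(cmp$cz), cmp$ct)
  }), use.names = FALSE)
}

vector_to_params <- function(v, template) {
  ncp <- template$config$spatial_control_points
  ns <- prod(ncp)
  nt <- template$n_temporal
  per <- 3L * ns + nt
  comps <- vector("list", template$n_components)
  for (ci in seq_len(template$n_components)) {
    off <- (ci - 1L) * per
    comps[[ci]] <- list(
      cx = array(v[off + seq_len(ns)], ncp),
      cy = array(v[off + ns + seq_len(ns)], ncp),
      cz = array(v[off + 2L * ns + seq_len(ns)], ncp),
      ct = v[off + 3L * ns + seq_len(nt)])
  }
  out <- template
  out$components <- comps
  out
}
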