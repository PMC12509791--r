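#' SIRT reconstruction settings
#'
#' @param n_iterations number of SIRT iterations (default 200).
#' @param nonnegativity clamp the image at zero after each iteration
#'   (default on; attenuation is physically non-negative).
#' @param extended_domain_margin transverse padding of the reconstruction
#'   domain, as a fraction per side (default 0.25), so that anatomy moving
#'   partly outside the field of view can still be represented.
#' @param normalization_floor relative coverage cutoff: rows (rays) and
#'   columns (voxels) whose normalization sums fall below this fraction of
#'   the positive median get zero update weight instead of an amplified
#'   reciprocal (default 0.05). Barely-sampled voxels at the cone edge
#'   otherwise destabilize the warped update.
#' @return A `sirt_config` object.
#' @export
sirt_config <- function(n_iterations = 200, nonnegativity = TRUE,
                        extended_domain_margin = 0.25,
                        normalization_floor = 0.05) {
  if (n_iterations < 1) stop("n_iterations must be at least 1")
  if (extended_domain_margin < 0) stop("margin must be non-negative")
  structure(list(n_iterations = as.integer(n_iterations),
                 nonnegativity = isTRUE(nonnegativity),
                 extended_domain_margin = as.numeric(extended_domain_margin),
                 normalization_floor = as.numeric(normalization_floor)),
            class = "sirt_config")
}

#' Pad a reconstruction grid transversely
#'
#' @param grid a [volume_grid()].
#' @param margin fraction added per side in x and y (rotation-plane axes).
#' @return the extended [volume_grid()], centered like the input.
#' @export
extend_grid <- function(grid, margin) {
  pad <- ceiling(grid$shape[1:2] * margin)
  shape <- c(grid$shape[1:2] + 2L * as.integer(pad), grid$shape[3])
  volume_grid(shape, grid$voxel_size_mm)
}

#' Centered crop of a volume to a smaller grid
#'
#' Extracts the central region of an (extended-domain) reconstruction so it
#' can be compared voxel-for-voxel with a volume on the original grid; both
#' grids must share voxel size and parity of the shape difference.
#'
#' @param vol a [volume()].
#' @param grid the target [volume_grid()] (not larger in any dimension).
#' @return a [volume()] on `grid`.
#' @export
crop_volume <- function(vol, grid) {
  stopifnot(inherits(vol, "cbct_volume"), inherits(grid, "volume_grid"))
  d <- vol$grid$shape - grid$shape
  if (any(d < 0L) || any(d %% 2L != 0L)) {
    stop("target grid must be centrally nested in the volume grid")
  }
  off <- d %/% 2L
  idx <- lapply(1:3, function(a) off[a] + seq_len(grid$shape[a]))
  volume(grid, vol$values[idx[[1]], idx[[2]], idx[[3]], drop = FALSE])
}

# reciprocal normalization weights with a coverage cutoff: entries below
# `frac` of the positive median contribute no update (weight 0)
normalization_weights <- function(v, frac) {
  pos <- v[v > 0]
  if (!length(pos)) return(v * 0)
  cut <- frac * stats::median(pos)
  ifelse(v > cut, 1 / pmax(v, cut), 0)
}

#' Motion-compensated SIRT reconstruction
#'
#' Simultaneous iterative reconstruction with per-frame motion
#' compensation:
#' `x <- x + C * sum_t Winv_t{ A_t^T R_t (y_t - A_t W_t{x}) }`,
#' with column normalization `C = 1 / sum_t A_t^T 1_P`, row normalization
#' `R_t = 1 / (A_t 1_I)` (elementwise, with a coverage cutoff), `W_t` the pull warp into
#' frame t's motion state and `Winv_t` the normalized push back to the
#' reference state. With identity motion the warps drop out and the update
#' is plain SIRT. A non-negativity clamp is applied after each iteration
#' when configured.
#'
#' @param projections line-integral [projection_set()] covering all frames.
#' @param geom a [scan_geometry()].
#' @param motion a [motion_parameters()] model, or `NULL` for identity
#'   motion (no compensation).
#' @param config a [sirt_config()].
#' @param grid reconstruction [volume_grid()].
#' @param init optional warm-start [volume()]; defaults to zero.
#' @param trace optional environment; if supplied, the operation order of
#'   the first frame of the first iteration is appended to `trace$steps`.
#' @return a [volume()]; attribute `residual_norms` holds the per-iteration
#'   total squared residual.
#' @export
sirt_reconstruct <- function(projections, geom, motion = NULL,
                             config = sirt_config(), grid,
                             init = NULL, trace = NULL) {
  stopifnot(inherits(projections, "projection_set"),
            inherits(grid, "volume_grid"))
  if (projections$domain != "line_integral") {
    stop("sirt_reconstruct expects line-integral projections")
  }
  T_ <- geom$n_frames
  ones_vol <- volume(grid, 1)
  # row normalizations R_t = 1 / (A_t 1_I)
  Rt <- vector("list", T_)
  for (t in seq_len(T_)) {
    Rt[[t]] <- normalization_weights(forward_project(ones_vol, geom, t),
                                     config$normalization_floor)
  }
  # column normalization C = 1 / (sum_t A_t^T 1_P)
  ones_proj <- matrix(1, geom$detector_rows, geom$detector_cols)
  csum <- array(0, grid$shape)
  for (t in seq_len(T_)) {
    csum <- csum + back_project(ones_proj, geom, t, grid)$values
  }
  Cn <- normalization_weights(csum, config$normalization_floor)

  # precompute low-rank motion pieces once; per-frame field is a cheap scale
  use_motion <- !is.null(motion)
  if (use_motion) {
    stopifnot(inherits(motion, "motion_parameters"))
    sig_vec <- unlist(lapply(spatial_component_fields(motion, grid),
                             as.numeric), use.names = FALSE)
    tau <- temporal_component_values(motion, geom$timestamps_s)
  }

  xv <- if (is.null(init)) array(0, grid$shape) else {
    stopifnot(identical(init$grid$shape, grid$shape))
    init$values
  }
  xv <- as.numeric(xv)
  fwd <- function(vals, t) {
    .cpp_forward_project(vals, grid$shape, grid$voxel_size_mm,
                         grid$origin_mm, geom$source_to_isocenter_mm,
                         geom$source_to_detector_mm, geom$detector_rows,
                         geom$detector_cols, geom$pixel_spacing_mm[1],
                         geom$pixel_spacing_mm[2], geom$angles_deg[t])
  }
  bwd <- function(p, t) {
    .cpp_back_project(p, grid$shape, grid$voxel_size_mm, grid$origin_mm,
                      geom$source_to_isocenter_mm,
                      geom$source_to_detector_mm, geom$pixel_spacing_mm[1],
                      geom$pixel_spacing_mm[2], geom$angles_deg[t])
  }
  residual_norms <- numeric(config$n_iterations)
  for (it in seq_len(config$n_iterations)) {
    upd <- 0
    rsum <- 0
    for (t in seq_len(T_)) {
      record <- !is.null(trace) && it == 1L && t == 1L
      if (use_motion) {
        xt <- .cpp_pull_lowrank(xv, grid$shape, sig_vec, tau[t, ],
                                grid$voxel_size_mm)
        if (record) trace$steps <- c(trace$steps, "pull")
      } else xt <- xv
      p <- fwd(xt, t)
      if (record) trace$steps <- c(trace$steps, "forward_project")
      r <- projections$values[, , t] - p
      if (record) trace$steps <- c(trace$steps, "compare")
      rsum <- rsum + sum(r^2)
      bp <- bwd(Rt[[t]] * r, t)
      if (record) trace$steps <- c(trace$steps, "back_project")
      if (use_motion) {
        bp <- .cpp_push_lowrank(bp, grid$shape, sig_vec, tau[t, ],
                                grid$voxel_size_mm, TRUE)
        if (record) trace$steps <- c(trace$steps, "push")
      }
      upd <- upd + bp
    }
    if (!all(is.finite(upd))) {
      stop(sprintf("non-finite SIRT update at iteration %d", it))
    }
    xv <- xv + as.numeric(Cn) * upd
    if (config$nonnegativity) xv <- pmax(xv, 0)
    residual_norms[it] <- rsum
  }
  x <- volume(grid, array(xv, grid$shape))
  attr(x, "residual_norms") <- residual_norms
  x
}

#' Motion-corrupted reconstruction
#'
#' Plain SIRT with no motion compensation; the initial reference image of
#' the alternation loop.
#'
#' @inheritParams sirt_reconstruct
#' @return a [volume()].
#' @export
motion_corrupted_reconstruct <- function(projections, geom,
                                         config = sirt_config(), grid) {
  sirt_reconstruct(projections, geom, motion = NULL, config = config,
                   grid = grid)
}
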