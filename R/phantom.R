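#' Deformable digital thorax phantom specification
#'
#' A parametric ellipsoid phantom with the features projection-space motion
#' estimation needs: a high-contrast lung-diaphragm-style interface (the
#' liver dome protruding into a low-attenuation lung), a homogeneous
#' liver-like region where motion is weakly encoded, and optional rib-like
#' high-contrast inclusions near the body surface. Attenuations are in
#' 1/mm; water-like soft tissue is about 0.02/mm at CBCT energies.
#'
#' @param grid a [volume_grid()].
#' @param structures list of structures, each a list with `center` (mm),
#'   `semi_axes` (mm) and `delta` (additive attenuation inside the
#'   ellipsoid). Defaults to a thorax-like arrangement scaled to the grid.
#' @return A `phantom_spec` object.
#' @export
phantom_spec <- function(grid, structures = NULL) {
  stopifnot(inherits(grid, "volume_grid"))
  if (is.null(structures)) {
    ext <- grid$shape * grid$voxel_size_mm   # physical extent, mm
    s <- function(f) f * ext / 2             # fractions of the half-extent
    structures <- list(
      body  = list(center = c(0, 0, 0), semi_axes = s(c(0.85, 0.70, 0.95)),
                   delta = 0.019),
      lung_r = list(center = s(c(0.38, 0, 0.22)),
                    semi_axes = s(c(0.34, 0.42, 0.55)), delta = -0.015),
      lung_l = list(center = s(c(-0.38, 0, 0.22)),
                    semi_axes = s(c(0.34, 0.42, 0.55)), delta = -0.015),
      # liver dome protrudes into the right lung: sharp axial interface
      liver = list(center = s(c(0.38, 0, -0.45)),
                   semi_axes = s(c(0.40, 0.48, 0.50)), delta = 0.015),
      tumor = list(center = s(c(-0.38, 0.1, 0.35)),
                   semi_axes = s(c(0.08, 0.08, 0.08)), delta = 0.012),
      rib_r = list(center = s(c(0.72, -0.40, 0.30)),
                   semi_axes = s(c(0.06, 0.06, 0.25)), delta = 0.020),
      rib_l = list(center = s(c(-0.72, -0.40, 0.30)),
                   semi_axes = s(c(0.06, 0.06, 0.25)), delta = 0.020))
  }
  structure(list(grid = grid, structures = structures),
            class = "phantom_spec")
}

#' Respiratory motion specification
#'
#' Semi-periodic superior-inferior breathing of sub-diaphragm anatomy:
#' cycle-wise sinusoidal-squared displacement whose amplitude and period
#' vary per cycle. Zero jitter gives exactly periodic motion with peaks one
#' mean period apart. Defaults follow clinically observed respiration: a
#' 5 s mean period, and an amplitude within the 5.2-30.6 mm range reported
#' for patient breathing.
#'
#' @param mean_period_s mean respiratory period (default 5).
#' @param period_jitter_fraction per-cycle relative period spread
#'   (default 0.1).
#' @param amplitude_mm peak displacement (default 15).
#' @param amplitude_jitter_fraction per-cycle relative amplitude spread
#'   (default 0.1).
#' @param axis_weights length-3 direction of the translation (default pure
#'   z, superior-inferior).
#' @param rng_seed seed for the jitter draws.
#' @return A `respiratory_spec` object.
#' @export
respiratory_spec <- function(mean_period_s = 5, period_jitter_fraction = 0.1,
                             amplitude_mm = 15,
                             amplitude_jitter_fraction = 0.1,
                             axis_weights = c(0, 0, 1), rng_seed = 0L) {
  if (!(mean_period_s > 0)) stop("mean_period_s must be positive")
  if (amplitude_mm < 0) stop("amplitude_mm must be non-negative")
  structure(list(mean_period_s = mean_period_s,
                 period_jitter_fraction = period_jitter_fraction,
                 amplitude_mm = amplitude_mm,
                 amplitude_jitter_fraction = amplitude_jitter_fraction,
                 axis_weights = axis_weights,
                 rng_seed = as.integer(rng_seed)),
            class = "respiratory_spec")
}

#' Acquisition noise specification
#'
#' @param s0 source intensity in counts (default 1e5).
#' @param sigma2_electronic additive Gaussian electronic-noise variance
#'   (default 10).
#' @param rng_seed seed for the noise draws.
#' @return A `noise_spec` object.
#' @export
noise_spec <- function(s0 = 1e5, sigma2_electronic = 10, rng_seed = 0L) {
  if (!(s0 > 0)) stop("s0 must be positive")
  if (sigma2_electronic < 0) stop("variance must be non-negative")
  structure(list(s0 = s0, sigma2_electronic = sigma2_electronic,
                 rng_seed = as.integer(rng_seed)),
            class = "noise_spec")
}

#' Build the phantom attenuation volume
#'
#' Deterministic additive ellipsoid map: every structure adds its `delta`
#' inside its ellipsoid. The resulting attenuation must be non-negative
#' everywhere.
#'
#' @param spec a [phantom_spec()].
#' @return a [volume()].
#' @export
make_phantom <- function(spec) {
  stopifnot(inherits(spec, "phantom_spec"))
  grid <- spec$grid
  vals <- array(0, grid$shape)
  ax <- lapply(1:3, function(a) grid_axis_mm(grid, a))
  for (st in spec$structures) {
    dx2 <- ((ax[[1]] - st$center[1]) / st$semi_axes[1])^2
    dy2 <- ((ax[[2]] - st$center[2]) / st$semi_axes[2])^2
    dz2 <- ((ax[[3]] - st$center[3]) / st$semi_axes[3])^2
    inside <- outer(outer(dx2, dy2, `+`), dz2, `+`) <= 1
    vals <- vals + st$delta * inside
  }
  if (any(vals < 0)) {
    stop("overlapping negative regions give negative attenuation")
  }
  volume(grid, vals)
}

# cycle-wise breathing amplitude profile a(t) (mm), C1-smooth:
# within cycle i of period P_i, displacement = A_i * sin^2(pi * s / P_i)
breathing_profile <- function(times, spec) {
  t_end <- max(times)
  set.seed(spec$rng_seed)
  starts <- 0
  periods <- numeric(0)
  amps <- numeric(0)
  while (starts[length(starts)] < t_end + spec$mean_period_s) {
    P <- spec$mean_period_s *
      max(0.2, 1 + spec$period_jitter_fraction * stats::rnorm(1))
    A <- spec$amplitude_mm *
      max(0, 1 + spec$amplitude_jitter_fraction * stats::rnorm(1))
    periods <- c(periods, P)
    amps <- c(amps, A)
    starts <- c(starts, starts[length(starts)] + P)
  }
  a <- numeric(length(times))
  for (i in seq_along(times)) {
    ci <- findInterval(times[i], starts)
    ci <- min(max(ci, 1L), length(periods))
    s <- times[i] - starts[ci]
    a[i] <- amps[ci] * sin(pi * s / periods[ci])^2
  }
  list(values = a, cycle_starts = starts[seq_along(periods)],
       periods = periods, amplitudes = amps)
}

# smooth spatial weight: 1 well below the diaphragm plane, cosine taper to
# 0 above it over `taper_mm`
diaphragm_weight <- function(grid, z_plane_mm = NULL, taper_mm = NULL) {
  zax <- grid_axis_mm(grid, 3)
  if (is.null(z_plane_mm)) z_plane_mm <- 0
  if (is.null(taper_mm)) taper_mm <- 0.6 * diff(range(zax))
  w1 <- ifelse(zax <= z_plane_mm - taper_mm, 1,
               ifelse(zax >= z_plane_mm + taper_mm, 0,
                      0.5 * (1 + cos(pi * (zax - (z_plane_mm - taper_mm)) /
                                       (2 * taper_mm)))))
  array(rep(w1, each = grid$shape[1] * grid$shape[2]), grid$shape)
}

#' Generate ground-truth respiratory motion
#'
#' Produces the per-frame ground-truth displacement for the simulator:
#' superior-inferior translation of sub-diaphragm structures with smooth
#' spatial falloff, following the cycle-wise breathing profile of `spec`.
#' Two forms are available: dense per-frame [motion_field()]s, or an exact
#' rank-1 instance of the low-rank spline model (useful for recovery tests
#' with no model mismatch; the dense fields of that instance are the model
#' evaluation itself).
#'
#' @param spec a [respiratory_spec()].
#' @param timestamps frame times, increasing.
#' @param grid a [volume_grid()].
#' @param form `"fields"` for dense per-frame fields, `"rank1"` for a
#'   [motion_parameters()] instance (requires `spline`).
#' @param spline a [spline_config()] for the rank-1 form.
#' @return For `"fields"`: list with `fields` (list of [motion_field()]),
#'   `profile` (the per-frame mm displacement vector) and the cycle
#'   bookkeeping. For `"rank1"`: list with `params`, `profile` and
#'   `weight` (the spatial weight volume).
#' @export
make_respiratory_motion <- function(spec, timestamps, grid,
                                    form = c("fields", "rank1"),
                                    spline = NULL) {
  stopifnot(inherits(spec, "respiratory_spec"))
  form <- match.arg(form)
  if (length(timestamps) > 1L && any(diff(timestamps) <= 0)) {
    stop("timestamps must be increasing")
  }
  prof <- breathing_profile(timestamps, spec)
  w <- diaphragm_weight(grid)
  axw <- spec$axis_weights / max(sum(abs(spec$axis_weights)), 1e-12) *
    sum(abs(spec$axis_weights))
  if (form == "fields") {
    fields <- lapply(seq_along(timestamps), function(i) {
      disp <- array(0, c(grid$shape, 3L))
      for (a in 1:3) {
        if (axw[a] != 0) disp[, , , a] <- w * prof$values[i] * axw[a]
      }
      motion_field(grid, disp, timestamps[i])
    })
    return(list(fields = fields, profile = prof$values,
                cycle_starts = prof$cycle_starts, periods = prof$periods,
                amplitudes = prof$amplitudes))
  }
  if (is.null(spline)) stop("rank-1 form needs a spline_config")
  time_range <- range(timestamps)
  params <- motion_parameters(spline, grid, time_range, 1L)
  # spatial coefficients: fit the separable basis to the weight volume by
  # sampling it at the control-point Greville positions (adequate for the
  # smooth taper); temporal coefficients: least-squares spline fit of the
  # breathing profile
  basis <- spatial_basis(spline, grid)
  greville <- function(knots) {
    n <- length(knots) - 4L
    vapply(seq_len(n), function(i) mean(knots[(i + 1):(i + 3)]), numeric(1))
  }
  gz <- greville(basis$knots[[3]])
  wz <- stats::approx(grid_axis_mm(grid, 3),
                      w[1, 1, ] / max(w), xout = gz, rule = 2)$y
  ncp <- spline$spatial_control_points
  for (a in 1:3) {
    if (axw[a] == 0) next
    coefs <- array(rep(wz * axw[a] * max(w), each = ncp[1] * ncp[2]), ncp)
    params$components[[1]][[c("cx", "cy", "cz")[a]]] <- coefs
  }
  Btau <- temporal_basis(spline, timestamps, time_range)
  ct <- stats::coef(stats::lm.fit(Btau, prof$values))
  ct[!is.finite(ct)] <- 0
  params$components[[1]]$ct <- as.numeric(ct)
  list(params = params, profile = prof$values, weight = volume(grid, w),
       cycle_starts = prof$cycle_starts, periods = prof$periods,
       amplitudes = prof$amplitudes)
}

#' Simulate a noisy dynamic cone-beam acquisition
#'
#' Per frame: deform the phantom to its motion state (pull warp), forward
#' project, then draw counts as
#' `Poisson(s0 exp(-y_t)) + Normal(0, sigma2)`, floored at zero. With
#' `noise_free = TRUE` the Poisson draw is replaced by its mean and the
#' Gaussian term dropped, so the counts invert exactly under the log
#' transform. The clean line integrals and the per-frame fields are
#' retained for evaluation.
#'
#' @param phantom the reference [volume()].
#' @param motion ground truth: a list of per-frame [motion_field()]s, a
#'   [motion_parameters()] model, or `NULL` for a static object.
#' @param geom a [scan_geometry()].
#' @param noise a [noise_spec()].
#' @param noise_free logical switch for deterministic counts.
#' @return list with `counts` (a counts-domain [projection_set()]),
#'   `clean_line_integrals` (array), and `fields` (per-frame ground-truth
#'   fields, `NULL` for static).
#' @export
simulate_acquisition <- function(phantom, motion, geom,
                                 noise = noise_spec(),
                                 noise_free = FALSE) {
  stopifnot(inherits(phantom, "cbct_volume"), inherits(geom, "scan_geometry"))
  T_ <- geom$n_frames
  fields <- NULL
  if (inherits(motion, "motion_parameters")) {
    sig <- spatial_component_fields(motion, phantom$grid)
    tau <- temporal_component_values(motion, geom$timestamps_s)
    fields <- lapply(seq_len(T_), function(t) {
      disp <- 0
      for (ci in seq_len(motion$n_components)) {
        disp <- disp + sig[[ci]] * tau[t, ci]
      }
      motion_field(phantom$grid, array(disp, c(phantom$grid$shape, 3L)),
                   geom$timestamps_s[t])
    })
  } else if (is.list(motion) && length(motion) && inherits(motion[[1]], "motion_field")) {
    if (length(motion) != T_) stop("need one ground-truth field per frame")
    fields <- motion
  } else if (!is.null(motion)) {
    stop("motion must be fields, motion_parameters, or NULL")
  }
  clean <- array(0, c(geom$detector_rows, geom$detector_cols, T_))
  for (t in seq_len(T_)) {
    obj <- if (is.null(fields)) phantom else pull_volume(phantom, fields[[t]])
    clean[, , t] <- forward_project(obj, geom, t)
  }
  mean_counts <- noise$s0 * exp(-clean)
  if (noise_free) {
    counts <- mean_counts
  } else {
    set.seed(noise$rng_seed)
    n <- length(mean_counts)
    counts <- stats::rpois(n, lambda = as.numeric(mean_counts)) +
      stats::rnorm(n, 0, sqrt(noise$sigma2_electronic))
    counts <- array(pmax(counts, 0), dim = dim(mean_counts))
  }
  list(counts = projection_set(geom, counts, "counts"),
       clean_line_integrals = clean,
       fields = fields)
}

#' Default acquisition protocol
#'
#' The clinical short-scan protocol: 160 frames at 182 ms spacing (29 s),
#' gantry angles uniform over 180 degrees, 512x512 detector at 0.8 mm pixel
#' pitch, 1536 mm source-detector distance, 1000 mm source-isocenter
#' distance. `scale` shrinks the detector grid (and its pixel count)
#' proportionally for desk-scale experiments while preserving the
#' magnification ratio SDD/SAD; `n_frames` overrides the frame count with
#' the same total arc and duration.
#'
#' @param scale detector down-scaling factor in (0, 1]; default 1.
#' @param n_frames number of frames (default 160).
#' @return a [scan_geometry()].
#' @export
default_protocol <- function(scale = 1, n_frames = 160L) {
  n_frames <- as.integer(n_frames)
  dt <- 0.182 * (160 / n_frames)
  angles <- seq(0, by = 180 / n_frames, length.out = n_frames)
  times <- seq(0, by = dt, length.out = n_frames)
  npix <- max(16L, as.integer(round(512 * scale)))
  scan_geometry(source_to_isocenter_mm = 1000,
                source_to_detector_mm = 1536,
                detector_rows = npix, detector_cols = npix,
                pixel_spacing_mm = 0.8 * (512 / npix),
                angles_deg = angles, timestamps_s = times)
}
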