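# separable Gaussian smoothing with edge padding, used by the SSIM map
gaussian_kernel_1d <- function(sigma, truncate = 3.5) {
  r <- as.integer(truncate * sigma + 0.5)
  k <- stats::dnorm(seq(-r, r), sd = sigma)
  k / sum(k)
}

shift_index <- function(n, s, mode) {
  idx <- seq_len(n) + s
  if (mode == "nearest") {
    pmin(pmax(idx, 1L), n)
  } else {  # reflect (half-sample symmetric, scipy's default "reflect")
    period <- 2L * n
    idx <- ((idx - 1L) %% period + period) %% period
    ifelse(idx < n, idx + 1L, period - idx)
  }
}

smooth_axis <- function(arr, k, axis, mode) {
  r <- (length(k) - 1L) %/% 2L
  out <- array(0, dim(arr))
  n <- dim(arr)[axis]
  for (j in seq_along(k)) {
    idx <- shift_index(n, j - r - 1L, mode)
    shifted <- switch(axis,
                      arr[idx, , , drop = FALSE],
                      arr[, idx, , drop = FALSE],
                      arr[, , idx, drop = FALSE])
    out <- out + k[j] * shifted
  }
  out
}

gaussian_smooth3 <- function(arr, sigma, truncate = 3.5, mode = "nearest") {
  k <- gaussian_kernel_1d(sigma, truncate)
  for (a in 1:3) arr <- smooth_axis(arr, k, a, mode)
  arr
}

#' Structural similarity between two volumes
#'
#' Standard SSIM with a Gaussian weighting window (sigma 1.5, 11-voxel
#' support) and the usual stabilizing constants `K1 = 0.01`, `K2 = 0.03`,
#' computed as a per-voxel map and averaged; the border the window cannot
#' fully cover is cropped before averaging. A field-of-view mask restricts
#' the average to the region seen by all projections. The measure is
#' symmetric and equals 1 for identical inputs.
#'
#' @param a,b [volume()] objects on the same grid.
#' @param fov_mask optional logical array on the grid; only masked voxels
#'   (inside the cropped border) enter the average.
#' @param data_range intensity range of the data; defaults to the combined
#'   range of both volumes.
#' @return scalar in \[-1, 1\].
#' @export
ssim_volume <- function(a, b, fov_mask = NULL, data_range = NULL) {
  stopifnot(inherits(a, "cbct_volume"), inherits(b, "cbct_volume"))
  if (!identical(a$grid$shape, b$grid$shape)) stop("grids do not match")
  x <- a$values; y <- b$values
  if (is.null(data_range)) data_range <- diff(range(c(x, y)))
  if (data_range <= 0) stop("data_range must be positive")
  sigma <- 1.5; truncate <- 3.5
  r <- as.integer(truncate * sigma + 0.5)
  C1 <- (0.01 * data_range)^2
  C2 <- (0.03 * data_range)^2
  mu_x <- gaussian_smooth3(x, sigma, truncate)
  mu_y <- gaussian_smooth3(y, sigma, truncate)
  sxx <- gaussian_smooth3(x * x, sigma, truncate) - mu_x^2
  syy <- gaussian_smooth3(y * y, sigma, truncate) - mu_y^2
  sxy <- gaussian_smooth3(x * y, sigma, truncate) - mu_x * mu_y
  S <- ((2 * mu_x * mu_y + C1) * (2 * sxy + C2)) /
    ((mu_x^2 + mu_y^2 + C1) * (sxx + syy + C2))
  n <- dim(x)
  if (any(n <= 2L * r)) stop("volume too small for the SSIM window")
  keep <- array(FALSE, n)
  keep[(r + 1):(n[1] - r), (r + 1):(n[2] - r), (r + 1):(n[3] - r)] <- TRUE
  if (!is.null(fov_mask)) {
    if (!identical(dim(fov_mask), as.integer(n))) {
      stop("fov_mask shape does not match the grid")
    }
    keep <- keep & fov_mask
  }
  mean(S[keep])
}

#' Edge-spread-function width of a line profile
#'
#' Fits the error-function edge model
#' `offset + amplitude * Phi((x - x0) / w)` to an intensity profile that
#' crosses a single dominant edge (the ESF of a Gaussian line-spread
#' function with standard deviation `w`). The inverse of the fitted width
#' is the sharpness proxy reported alongside.
#'
#' @param profile numeric intensity samples along the line.
#' @param spacing_mm sample spacing.
#' @return list with `width_mm` (fitted `w`), `sharpness_per_mm` (its
#'   inverse), `x0_mm`, and the `fit` object; on fit failure, `failed =
#'   TRUE` with a `message`.
#' @export
esf_width <- function(profile, spacing_mm = 1) {
  n <- length(profile)
  if (n < 5L) stop("profile too short for an edge fit")
  x <- (seq_len(n) - 1) * spacing_mm
  dgrad <- diff(profile)
  i0 <- which.max(abs(dgrad))
  start <- list(offset = min(profile),
                amplitude = diff(range(profile)) * sign(dgrad[i0]),
                x0 = x[i0],
                w = max(2 * spacing_mm, diff(range(x)) / 20))
  if (start$amplitude < 0) {
    start$offset <- max(profile)
  }
  dat <- data.frame(x = x, yv = profile)
  fit <- tryCatch(
    minpack.lm::nlsLM(
      yv ~ offset + amplitude * pnorm((x - x0) / w),
      data = dat, start = start,
      lower = c(-Inf, -Inf, min(x), spacing_mm / 100),
      upper = c(Inf, Inf, max(x), Inf),
      control = minpack.lm::nls.lm.control(maxiter = 200)),
    error = function(e) e)
  if (inherits(fit, "error")) {
    return(list(failed = TRUE, message = conditionMessage(fit)))
  }
  w <- abs(stats::coef(fit)[["w"]])
  list(width_mm = w, sharpness_per_mm = 1 / w,
       x0_mm = stats::coef(fit)[["x0"]], fit = fit, failed = FALSE)
}

#' Per-axis RMSE between motion profiles
#'
#' Root-mean-square difference between an estimated and a ground-truth
#' displacement trajectory, per spatial axis, in mm.
#'
#' @param estimated,truth numeric matrices `n_frames x 3` (columns x, y, z)
#'   sampled at the same timestamps.
#' @return named numeric vector `c(x=, y=, z=)` in mm.
#' @export
motion_rmse <- function(estimated, truth) {
  estimated <- as.matrix(estimated)
  truth <- as.matrix(truth)
  if (!all(dim(estimated) == dim(truth))) stop("profile lengths differ")
  out <- sqrt(colMeans((estimated - truth)^2))
  names(out) <- c("x", "y", "z")[seq_len(ncol(estimated))]
  out
}

#' Cylindrical field-of-view mask for a geometry
#'
#' Voxels within the transverse radius that every projection of a full
#' half-arc sees, i.e. the inscribed detector-limited cylinder mapped to
#' the isocenter by the magnification SDD/SAD.
#'
#' @param grid a [volume_grid()].
#' @param geom a [scan_geometry()].
#' @return logical array on the grid.
#' @export
fov_mask <- function(grid, geom) {
  mag <- geom$source_to_detector_mm / geom$source_to_isocenter_mm
  r_fov <- geom$detector_cols * geom$pixel_spacing_mm[2] / 2 / mag
  h_fov <- geom$detector_rows * geom$pixel_spacing_mm[1] / 2 / mag
  xs <- grid_axis_mm(grid, 1); ys <- grid_axis_mm(grid, 2)
  zs <- grid_axis_mm(grid, 3)
  rad <- sqrt(outer(xs^2, ys^2, `+`))
  mask2 <- rad <= r_fov
  zok <- abs(zs) <= h_fov
  array(outer(mask2, zok, `&`), grid$shape)
}
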