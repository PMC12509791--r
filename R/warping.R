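#' Pull (sample) a volume through a motion field
#'
#' Forward warp: `out[r] = img[r + delta(r)]` by tri-linear interpolation,
#' deforming the reference image into the frame's motion state. Sample
#' positions outside the grid read 0 (air).
#'
#' @param img a [volume()].
#' @param field a [motion_field()] on the same grid (displacement in mm).
#' @return the warped [volume()].
#' @export
pull_volume <- function(img, field) {
  stopifnot(inherits(img, "cbct_volume"), inherits(field, "motion_field"))
  if (!identical(img$grid$shape, field$grid$shape)) {
    stop("image and field grids do not match")
  }
  v <- .cpp_pull(as.numeric(img$values), img$grid$shape,
                 as.numeric(field$displacement), img$grid$voxel_size_mm)
  volume(img$grid, array(v, dim = img$grid$shape))
}

#' Push (splat) a volume through a motion field
#'
#' Scatter adjoint of [pull_volume()]: each voxel value is splatted to the
#' eight voxels around its displaced position with tri-linear weights. The
#' raw mode is the exact linear adjoint of pull; the normalized mode divides
#' by the splat of a ones-image (the count of contributions landing in each
#' voxel), which approximates warping with the inverse motion field.
#' Voxels receiving no contributions are set to 0.
#'
#' @param img a [volume()].
#' @param field a [motion_field()] on the same grid.
#' @param normalized logical; `TRUE` gives the approximate-inverse warp.
#' @return a [volume()].
#' @export
push_volume <- function(img, field, normalized = TRUE) {
  stopifnot(inherits(img, "cbct_volume"), inherits(field, "motion_field"))
  if (!identical(img$grid$shape, field$grid$shape)) {
    stop("image and field grids do not match")
  }
  num <- .cpp_push_raw(as.numeric(img$values), img$grid$shape,
                       as.numeric(field$displacement),
                       img$grid$voxel_size_mm)
  if (normalized) {
    den <- .cpp_push_raw(rep(1, length(num)), img$grid$shape,
                         as.numeric(field$displacement),
                         img$grid$voxel_size_mm)
    num <- ifelse(den > 0, num / pmax(den, .Machine$double.eps), 0)
  }
  volume(img$grid, array(num, dim = img$grid$shape))
}

#' Round-trip residual of the approximate inverse warp
#'
#' Pulls an image through the field and pushes it back with the normalized
#' push; since an exact inverse displacement generally does not exist, the
#' relative residual `||push(pull(img)) - img|| / ||img||` quantifies how
#' well the normalized push approximates the inverse deformation.
#'
#' @param img a [volume()].
#' @param field a [motion_field()].
#' @return scalar relative residual (0 for the identity field).
#' @export
compose_check <- function(img, field) {
  rt <- push_volume(pull_volume(img, field), field, normalized = TRUE)
  nrm <- sqrt(sum(img$values^2))
  if (nrm == 0) return(0)
  sqrt(sum((rt$values - img$values)^2)) / nrm
}

# gradient of the pulled value w.r.t. displacement (mm^-1 units), as
# [nx,ny,nz,3]; used by the analytic loss gradient
pull_gradient <- function(img, field) {
  g <- .cpp_pull_grad(as.numeric(img$values), img$grid$shape,
                      as.numeric(field$displacement),
                      img$grid$voxel_size_mm)
  array(g, c(img$grid$shape, 3L))
}
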