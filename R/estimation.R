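#' Motion-estimation settings
#'
#' @param learning_rate NAdam step size (default 0.1).
#' @param n_epochs number of full-batch gradient steps (default 100).
#' @param init_scale half-width of the uniform random coefficient
#'   initialization, in mm-equivalents (default 0.01: the first iterate is
#'   nearly the identity motion).
#' @param rng_seed integer seed for the random initialization.
#' @return An `estimation_config` object.
#' @export
estimation_config <- function(learning_rate = 0.1, n_epochs = 100,
                              init_scale = 0.01, rng_seed = 0L) {
  if (!(learning_rate > 0)) stop("learning_rate must be positive")
  if (n_epochs < 1) stop("n_epochs must be at least 1")
  if (init_scale < 0) stop("init_scale must be non-negative")
  structure(list(learning_rate = as.numeric(learning_rate),
                 n_epochs = as.integer(n_epochs),
                 init_scale = as.numeric(init_scale),
                 rng_seed = as.integer(rng_seed)),
            class = "estimation_config")
}

#' Predicted line integrals of a deformed reference image
#'
#' The signal model of one frame: warp the reference image into the frame's
#' motion state with the model field, then forward project. With zero
#' coefficients this is exactly the projection of the reference.
#'
#' @param params a [motion_parameters()].
#' @param reference reference [volume()] (`x0`), on the reconstruction grid.
#' @param geom a [scan_geometry()].
#' @param frame 1-based frame index.
#' @return matrix `detector_rows x detector_cols`.
#' @export
forward_model <- function(params, reference, geom, frame) {
  field <- evaluate_motion_field(params, reference$grid,
                                 geom$timestamps_s[frame])
  forward_project(pull_volume(reference, field), geom, frame)
}

#' Projection-space motion-estimation loss
#'
#' Sum over frames of the squared residual between modeled and measured
#' line integrals, plus the weighted smoothness penalty:
#' `L(c) = sum_t ||F_t(c|x0) - y_t||^2 + lambda R`.
#'
#' @param params a [motion_parameters()].
#' @param reference reference [volume()].
#' @param geom a [scan_geometry()].
#' @param projections line-integral [projection_set()] with
#'   `geom$n_frames` frames.
#' @param reg a [regularizer_config()] (its `weight` is lambda).
#' @return non-negative scalar.
#' @export
motion_loss <- function(params, reference, geom, projections,
                        reg = regularizer_config()) {
  stopifnot(inherits(projections, "projection_set"))
  if (projections$domain != "line_integral") {
    stop("motion_loss expects line-integral projections")
  }
  data_term <- 0
  for (t in seq_len(geom$n_frames)) {
    r <- forward_model(params, reference, geom, t) -
      projections$values[, , t]
    data_term <- data_term + sum(r^2)
  }
  reg_term <- if (reg$weight > 0) {
    jacobian_penalty(params, reference$grid, geom$timestamps_s, reg)
  } else 0
  data_term + reg$weight * reg_term
}

# loss value and analytic gradient w.r.t. the flattened coefficient vector.
# Chain rule: residual -> A_t^T (projector adjoint as the backward step) ->
# d(pull)/d(displacement) -> separable spline basis transposes.
loss_value_grad <- function(params, reference, geom, projections, reg,
                            basis, Btau) {
  grid <- reference$grid
  ncomp <- params$n_components
  nvox <- prod(grid$shape)
  sig <- spatial_component_fields(params, grid, basis)
  sig_vec <- unlist(lapply(sig, as.numeric), use.names = FALSE)
  tau <- sapply(seq_len(ncomp), function(ci) {
    as.numeric(Btau %*% params$components[[ci]]$ct)
  })
  tau <- matrix(tau, nrow = nrow(Btau))
  ref_vals <- as.numeric(reference$values)
  H <- numeric(3 * nvox * ncomp)
  q <- matrix(0, geom$n_frames, ncomp)
  data_term <- 0
  for (t in seq_len(geom$n_frames)) {
    warped <- .cpp_pull_lowrank(ref_vals, grid$shape, sig_vec, tau[t, ],
                                grid$voxel_size_mm)
    pred <- .cpp_forward_project(
      warped, grid$shape, grid$voxel_size_mm, grid$origin_mm,
      geom$source_to_isocenter_mm, geom$source_to_detector_mm,
      geom$detector_rows, geom$detector_cols,
      geom$pixel_spacing_mm[1], geom$pixel_spacing_mm[2],
      geom$angles_deg[t])
    resid <- pred - projections$values[, , t]
    data_term <- data_term + sum(resid^2)
    gvol <- .cpp_back_project(
      2 * resid, grid$shape, grid$voxel_size_mm, grid$origin_mm,
      geom$source_to_isocenter_mm, geom$source_to_detector_mm,
      geom$pixel_spacing_mm[1], geom$pixel_spacing_mm[2],
      geom$angles_deg[t])
    q[t, ] <- .cpp_grad_accum(ref_vals, grid$shape, sig_vec, tau[t, ],
                              grid$voxel_size_mm, gvol, H)
  }
  grad_comps <- vector("list", ncomp)
  for (ci in seq_len(ncomp)) {
    Hc <- array(H[(ci - 1L) * 3L * nvox + seq_len(3L * nvox)],
                c(grid$shape, 3L))
    gx <- contract3(Hc[, , , 1], basis$Bx, basis$By, basis$Bz)
    gy <- contract3(Hc[, , , 2], basis$Bx, basis$By, basis$Bz)
    gz <- contract3(Hc[, , , 3], basis$Bx, basis$By, basis$Bz)
    gt <- as.numeric(crossprod(Btau, q[, ci]))
    grad_comps[[ci]] <- c(as.numeric(gx), as.numeric(gy), as.numeric(gz), gt)
  }
  grad <- unlist(grad_comps, use.names = FALSE)
  value <- data_term
  if (reg$weight > 0) {
    rg <- reg_value_grad(params, grid, Btau, convention = reg$convention)
    value <- value + reg$weight * rg$value
    grad <- grad + reg$weight * rg$grad
  }
  list(value = value, grad = grad)
}

#' Estimate time-resolved motion directly in projection space
#'
#' Minimizes the projection-space loss over the low-rank spline coefficients
#' with full-batch NAdam (Nesterov-momentum adaptive gradient descent),
#' starting from a small seeded random initialization so the first iterate
#' is approximately the identity motion. Gradients are analytic: the
#' projector adjoint is the backward step for the line integrals, composed
#' with the tri-linear sampling derivative and the spline basis transposes.
#'
#' @param reference reference [volume()] (`x0`), approximately in a fixed
#'   motion state.
#' @param geom a [scan_geometry()].
#' @param projections line-integral [projection_set()].
#' @param spline a [spline_config()].
#' @param config an [estimation_config()].
#' @param reg a [regularizer_config()].
#' @param n_components model rank (default 1).
#' @return An `estimation_result`: `params` (fitted [motion_parameters()]),
#'   `loss_trace` (per-epoch loss), `final_loss`.
#' @export
estimate_motion <- function(reference, geom, projections,
                            spline = spline_config(),
                            config = estimation_config(),
                            reg = regularizer_config(),
                            n_components = 1L) {
  stopifnot(inherits(projections, "projection_set"))
  if (projections$domain != "line_integral") {
    stop("estimate_motion expects line-integral projections")
  }
  grid <- reference$grid
  time_range <- range(geom$timestamps_s)
  template <- motion_parameters(spline, grid, time_range, n_components)
  nparam <- n_parameters(template)
  set.seed(config$rng_seed)
  theta <- stats::runif(nparam, -config$init_scale, config$init_scale)
  basis <- params_spatial_basis(template, grid)
  Btau <- temporal_basis(spline, geom$timestamps_s, time_range)

  # NAdam state (Dozat-style Nesterov Adam, PyTorch momentum schedule)
  beta1 <- 0.9; beta2 <- 0.999; eps <- 1e-8; psi <- 0.004
  m <- numeric(nparam); v <- numeric(nparam); mu_prod <- 1
  loss_trace <- numeric(config$n_epochs)
  for (epoch in seq_len(config$n_epochs)) {
    params <- vector_to_params(theta, template)
    lv <- loss_value_grad(params, reference, geom, projections, reg,
                          basis, Btau)
    if (!is.finite(lv$value)) {
      stop(sprintf("non-finite loss at epoch %d; aborting", epoch))
    }
    loss_trace[epoch] <- lv$value
    g <- lv$grad
    mu_t <- beta1 * (1 - 0.5 * 0.96^(epoch * psi))
    mu_next <- beta1 * (1 - 0.5 * 0.96^((epoch + 1) * psi))
    mu_prod <- mu_prod * mu_t
    m <- beta1 * m + (1 - beta1) * g
    v <- beta2 * v + (1 - beta2) * g^2
    m_hat <- mu_next * m / (1 - mu_prod * mu_next) +
      (1 - mu_t) * g / (1 - mu_prod)
    v_hat <- v / (1 - beta2^epoch)
    theta <- theta - config$learning_rate * m_hat / (sqrt(v_hat) + eps)
  }
  params <- vector_to_params(theta, template)
  final_loss <- loss_value_grad(params, reference, geom, projections, reg,
                                basis, Btau)$value
  structure(list(params = params,
                 loss_trace = loss_trace,
                 final_loss = final_loss),
            class = "estimation_result")
}

#' @export
print.estimation_result <- function(x, ...) {
  cat(sprintf("estimation_result: %d epochs, loss %.4g -> %.4g\n",
              length(x$loss_trace), x$loss_trace[1], x$final_loss))
  invisible(x)
}
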