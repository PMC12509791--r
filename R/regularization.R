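#' Regularizer configuration
#'
#' Smoothness penalty on the motion: the squared L2 (Dirichlet) norm of the
#' spatial displacement gradients, summed over all nine component/direction
#' pairs, voxels and frames. It is zero for any rigid translation and grows
#' quadratically with deformation amplitude.
#'
#' @param weight non-negative regularization strength (the lambda of the
#'   motion-estimation loss); default `1e-6`.
#' @param gradient_mode `"analytic_bspline"` (derivatives from the B-spline
#'   derivative expansion) or `"finite_difference"`.
#' @param convention `"displacement"` penalizes the gradients of the
#'   displacement (default; translation-invariant). `"mapping"` penalizes
#'   the gradients of the full mapping `D(r) = r + delta(r)` literally,
#'   which adds a constant offset of 3 per voxel per frame.
#' @return A `regularizer_config` object.
#' @export
regularizer_config <- function(weight = 1e-6,
                               gradient_mode = c("analytic_bspline",
                                                 "finite_difference"),
                               convention = c("displacement", "mapping")) {
  if (!(weight >= 0)) stop("weight must be non-negative")
  structure(list(weight = as.numeric(weight),
                 gradient_mode = match.arg(gradient_mode),
                 convention = match.arg(convention)),
            class = "regularizer_config")
}

# central differences inside, one-sided at the boundary, per world mm
fd_gradient_axis <- function(vol, axis, h_mm) {
  n <- dim(vol)[axis]
  idx_p <- pmin(seq_len(n) + 1L, n)
  idx_m <- pmax(seq_len(n) - 1L, 1L)
  span <- (idx_p - idx_m) * h_mm
  pick <- function(i) {
    switch(axis,
           vol[i, , , drop = FALSE],
           vol[, i, , drop = FALSE],
           vol[, , i, drop = FALSE])
  }
  g <- (pick(idx_p) - pick(idx_m)) / rep(span, each = prod(dim(vol)[seq_len(axis - 1L)]))
  array(g, dim(vol))
}

# dense-field penalty contribution of a single frame
field_penalty_fd <- function(field, convention) {
  grid <- field$grid
  total <- 0
  for (p in 1:3) {
    comp <- field$displacement[, , , p]
    for (d in 1:3) {
      g <- fd_gradient_axis(comp, d, grid$voxel_size_mm[d])
      if (convention == "mapping" && p == d) g <- g + 1
      total <- total + sum(g^2)
    }
  }
  total
}

#' Spatial smoothness penalty on the motion
#'
#' Computes `R = sum_t sum_p sum_d || d delta_t^p / d_d ||^2` over the voxel
#' grid — the joint squared norm of all displacement-gradient components,
#' summed over frames. Accepts either a fitted low-rank model (analytic
#' B-spline derivatives, or finite differences of the densely evaluated
#' fields) or one/more dense [motion_field()] objects (finite differences).
#'
#' @param x a [motion_parameters()], a [motion_field()], or a list of
#'   motion fields.
#' @param grid evaluation [volume_grid()]; defaults to the model grid or
#'   field grid.
#' @param frame_times times at which to evaluate a parametric model; ignored
#'   for dense fields.
#' @param config a [regularizer_config()].
#' @return non-negative scalar; 0 iff displacement is spatially constant in
#'   every frame (displacement convention).
#' @export
jacobian_penalty <- function(x, grid = NULL, frame_times = NULL,
                             config = regularizer_config()) {
  if (inherits(x, "motion_field")) x <- list(x)
  if (is.list(x) && !inherits(x, "motion_parameters")) {
    return(sum(vapply(x, field_penalty_fd, numeric(1),
                      convention = config$convention)))
  }
  stopifnot(inherits(x, "motion_parameters"))
  if (is.null(grid)) grid <- x$grid
  if (is.null(frame_times)) stop("frame_times required for a parametric model")
  if (config$gradient_mode == "finite_difference") {
    fields <- lapply(frame_times, function(t) evaluate_motion_field(x, grid, t))
    return(sum(vapply(fields, field_penalty_fd, numeric(1),
                      convention = config$convention)))
  }
  Btau <- temporal_basis(x$config, frame_times, x$time_range_s)
  reg_value_grad(x, grid, Btau, convention = config$convention,
                 want_grad = FALSE)$value
}

# Analytic value (and optionally gradient w.r.t. the flattened coefficient
# vector) of the penalty, exploiting the low-rank factorization:
#   R = sum_{p,d} sum_{c,c'} [sum_r G_c^{pd} G_c'^{pd}] [sum_t tau_c tau_c'],
# where G_c^{pd} is the d-derivative of spatial component field sigma_c^p.
reg_value_grad <- function(params, grid, Btau, convention = "displacement",
                           want_grad = TRUE) {
  ncomp <- params$n_components
  bd <- list(
    params_spatial_basis(params, grid, deriv = c(1L, 0L, 0L)),
    params_spatial_basis(params, grid, deriv = c(0L, 1L, 0L)),
    params_spatial_basis(params, grid, deriv = c(0L, 0L, 1L)))
  coef_names <- c("cx", "cy", "cz")
  # G[[ci]][[p]][[d]]: derivative fields
  G <- lapply(seq_len(ncomp), function(ci) {
    cmp <- params$components[[ci]]
    lapply(1:3, function(p) {
      lapply(1:3, function(d) {
        B <- bd[[d]]
        expand3(cmp[[coef_names[p]]], B$Bx, B$By, B$Bz)
      })
    })
  })
  tau <- sapply(seq_len(ncomp), function(ci) {
    as.numeric(Btau %*% params$components[[ci]]$ct)
  })
  tau <- matrix(tau, nrow = nrow(Btau))
  Tmat <- crossprod(tau)                       # sum_t tau_c tau_c'
  # M[p,d][c,c'] spatial Gram matrices
  Mpd <- array(0, c(3, 3, ncomp, ncomp))
  for (p in 1:3) for (d in 1:3) {
    for (ci in seq_len(ncomp)) for (cj in seq_len(ci)) {
      s <- sum(G[[ci]][[p]][[d]] * G[[cj]][[p]][[d]])
      Mpd[p, d, ci, cj] <- s
      Mpd[p, d, cj, ci] <- s
    }
  }
  value <- 0
  for (p in 1:3) for (d in 1:3) {
    value <- value + sum(Mpd[p, d, , ] * Tmat)
  }
  nvox <- prod(grid$shape)
  nT <- nrow(Btau)
  if (convention == "mapping") {
    # cross term 2 sum_t sum_p sum_r d(delta^p)/dp + constant 3 * nvox * T
    tau_sum <- colSums(tau)
    div_sum <- vapply(seq_len(ncomp), function(ci) {
      sum(vapply(1:3, function(p) sum(G[[ci]][[p]][[p]]), numeric(1)))
    }, numeric(1))
    value <- value + 2 * sum(div_sum * tau_sum) + 3 * nvox * nT
  }
  if (!want_grad) return(list(value = value))

  grad_comps <- vector("list", ncomp)
  Msum <- apply(Mpd, c(3, 4), sum)             # sum over p,d of M^{pd}
  for (ci in seq_len(ncomp)) {
    gsp <- list(array(0, dim(params$components[[ci]]$cx)),
                array(0, dim(params$components[[ci]]$cx)),
                array(0, dim(params$components[[ci]]$cx)))
    for (p in 1:3) {
      acc <- gsp[[p]]
      for (d in 1:3) {
        # sum over c' of T_{c c'} G_{c'}^{pd}, contracted back to coef space
        fld <- 0
        for (cj in seq_len(ncomp)) {
          fld <- fld + Tmat[ci, cj] * G[[cj]][[p]][[d]]
        }
        B <- bd[[d]]
        acc <- acc + contract3(fld, B$Bx, B$By, B$Bz)
      }
      gsp[[p]] <- 2 * acc
    }
    # temporal gradient: 2 B^T [ sum_c' Msum_{c c'} tau_{c'}(t) ]
    q <- tau %*% Msum[ci, ]
    gt <- 2 * as.numeric(crossprod(Btau, q))
    if (convention == "mapping") {
      for (p in 1:3) {
        B <- bd[[p]]
        ones_c <- contract3(array(1, grid$shape), B$Bx, B$By, B$Bz)
        gsp[[p]] <- gsp[[p]] + 2 * sum(tau[, ci]) * ones_c
      }
      div_ci <- sum(vapply(1:3, function(p) sum(G[[ci]][[p]][[p]]),
                           numeric(1)))
      gt <- gt + 2 * div_ci * colSums(Btau)
    }
    grad_comps[[ci]] <- c(as.numeric(gsp[[1]]), as.numeric(gsp[[2]]),
                          as.numeric(gsp[[3]]), gt)
  }
  list(value = value, grad = unlist(grad_comps, use.names = FALSE))
}
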