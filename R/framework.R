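#' Full framework configuration
#'
#' Bundles the sub-configurations of the alternating motion-estimation /
#' motion-corrected-reconstruction loop.
#'
#' @param max_alternations outer-loop cap (default 50). 0 disables the loop
#'   and returns the motion-corrupted reconstruction with identity motion.
#' @param convergence_rel_tol relative final-loss improvement below which
#'   the loop stops (default 1e-3); any loss increase also stops it.
#' @param estimation an [estimation_config()].
#' @param sirt a [sirt_config()].
#' @param regularizer a [regularizer_config()].
#' @param spline a [spline_config()].
#' @param n_components motion-model rank (default 1).
#' @param reinitialize if `TRUE` (default) each alternation's estimation
#'   restarts from a fresh random initialization (seed derived from the
#'   master seed and the alternation index); if `FALSE`, warm-starts are
#'   not used either — estimation always starts near identity.
#' @return A `moco_config` object.
#' @export
moco_config <- function(max_alternations = 50,
                        convergence_rel_tol = 1e-3,
                        estimation = estimation_config(),
                        sirt = sirt_config(),
                        regularizer = regularizer_config(),
                        spline = spline_config(),
                        n_components = 1L,
                        reinitialize = TRUE) {
  if (max_alternations < 0) stop("max_alternations must be >= 0")
  structure(list(max_alternations = as.integer(max_alternations),
                 convergence_rel_tol = as.numeric(convergence_rel_tol),
                 estimation = estimation, sirt = sirt,
                 regularizer = regularizer, spline = spline,
                 n_components = as.integer(n_components),
                 reinitialize = isTRUE(reinitialize)),
            class = "moco_config")
}

#' Convergence detection on the per-alternation loss history
#'
#' The loop is declared converged when the relative decrease of the final
#' estimation loss falls below the tolerance, or when the loss increases
#' (further alternations overfit and worsen the estimate). The reported
#' index is the best (minimum-loss) alternation.
#'
#' @param loss_history numeric vector of per-alternation final losses.
#' @param rel_tol relative-improvement tolerance.
#' @return list with `converged` flag and `index` of the best alternation.
#' @export
detect_convergence <- function(loss_history, rel_tol = 1e-3) {
  n <- length(loss_history)
  if (n < 2L) return(list(converged = FALSE, index = n))
  last <- loss_history[n - 1L]
  cur <- loss_history[n]
  rel_improve <- (last - cur) / abs(last)
  list(converged = (cur > last) || (rel_improve < rel_tol),
       index = which.min(loss_history))
}

#' Joint reconstruction of motion and image
#'
#' The outer alternation: (i) log-transform counts if needed (estimating
#' the source intensity from a corner background region when not given);
#' (ii) motion-corrupted SIRT for the initial reference; (iii) repeat
#' {estimate motion from the current reference, motion-compensated SIRT
#' with the estimate} until the final estimation loss stops improving or
#' `max_alternations` is reached; the best-loss alternation's image and
#' motion are returned. Three consecutive diverging alternations trigger an
#' early stop with a warning.
#'
#' @param projections a [projection_set()] in counts or line-integral
#'   domain.
#' @param geom a [scan_geometry()].
#' @param config a [moco_config()].
#' @param grid reconstruction [volume_grid()] **before** domain extension;
#'   the transverse margin of `config$sirt` is applied internally.
#' @param s0 source intensity for the counts log-transform; estimated from
#'   a detector-corner background ROI when `NULL`.
#' @param seed master seed; per-alternation estimation seeds are derived
#'   from it.
#' @return A `moco_result`: `corrected_image` (on the extended grid),
#'   `corrupted_image`, `motion`, `alternation_losses`, `converged_at`.
#' @export
run_moco <- function(projections, geom, config = moco_config(), grid,
                     s0 = NULL, seed = 0L) {
  stopifnot(inherits(projections, "projection_set"),
            inherits(grid, "volume_grid"))
  if (projections$domain == "counts") {
    if (is.null(s0)) {
      roi <- list(rows = 1:min(8L, geom$detector_rows),
                  cols = 1:min(8L, geom$detector_cols))
      s0 <- estimate_source_intensity(projections, roi)
    }
    projections <- log_transform(projections, s0)
  }
  ext_grid <- extend_grid(grid, config$sirt$extended_domain_margin)
  corrupted <- motion_corrupted_reconstruct(projections, geom,
                                            config$sirt, ext_grid)
  if (config$max_alternations == 0L) {
    identity_motion <- motion_parameters(config$spline, ext_grid,
                                         range(geom$timestamps_s),
                                         config$n_components)
    return(structure(list(corrected_image = corrupted,
                          corrupted_image = corrupted,
                          motion = identity_motion,
                          alternation_losses = numeric(0),
                          converged_at = 0L),
                     class = "moco_result"))
  }
  reference <- corrupted
  losses <- numeric(0)
  best <- list(loss = Inf, image = corrupted, motion = NULL)
  n_diverging <- 0L
  for (alt in seq_len(config$max_alternations)) {
    est_cfg <- config$estimation
    if (config$reinitialize) {
      est_cfg$rng_seed <- as.integer(
        (as.numeric(config$estimation$rng_seed) + as.numeric(seed) +
           7919 * alt) %% 2147483647)
    }
    est <- estimate_motion(reference, geom, projections,
                           spline = config$spline, config = est_cfg,
                           reg = config$regularizer,
                           n_components = config$n_components)
    corrected <- sirt_reconstruct(projections, geom, est$params,
                                  config$sirt, ext_grid)
    losses <- c(losses, est$final_loss)
    if (est$final_loss < best$loss) {
      best <- list(loss = est$final_loss, image = corrected,
                   motion = est$params)
      n_diverging <- 0L
    } else {
      n_diverging <- n_diverging + 1L
      if (n_diverging >= 3L) {
        warning("loss diverged for 3 consecutive alternations; stopping early")
        break
      }
    }
    conv <- detect_convergence(losses, config$convergence_rel_tol)
    if (conv$converged) break
    reference <- corrected
  }
  conv <- detect_convergence(losses, config$convergence_rel_tol)
  structure(list(corrected_image = best$image,
                 corrupted_image = corrupted,
                 motion = best$motion,
                 alternation_losses = losses,
                 converged_at = conv$index),
            class = "moco_result")
}

#' @export
print.moco_result <- function(x, ...) {
  cat(sprintf("moco_result: %d alternations, best at %d (loss %.4g)\n",
              length(x$alternation_losses), x$converged_at,
              min(x$alternation_losses)))
  invisible(x)
}
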