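# small dynamic study used across estimation tests
tiny_study <- function(n = 16, n_frames = 24, amplitude = 6,
                       noise_free = TRUE) {
  grid <- volume_grid(rep(n, 3L), 128 / n)
  geom <- scan_geometry(1000, 1536, n, n, 512 * 0.8 / n,
                        angles_deg = seq(0, 180, length.out = n_frames + 1)[-(n_frames + 1)],
                        timestamps_s = seq(0, 10, length.out = n_frames))
  phant <- make_phantom(phantom_spec(grid))
  spl <- spline_config(4, temporal_rate_hz = 0.4)
  resp <- make_respiratory_motion(
    respiratory_spec(amplitude_mm = amplitude, mean_period_s = 5,
                     period_jitter_fraction = 0,
                     amplitude_jitter_fraction = 0),
    geom$timestamps_s, grid, form = "rank1", spline = spl)
  sim <- simulate_acquisition(phant, if (amplitude > 0) resp$params else NULL,
                              geom, noise_spec(rng_seed = 1),
                              noise_free = noise_free)
  list(grid = grid, geom = geom, phantom = phant, spline = spl,
       truth = resp, y = log_transform(sim$counts, 1e5))
}

test_that("forward model composes warp and projection", {
  st <- tiny_study(amplitude = 0)
  params <- motion_parameters(st$spline, st$grid,
                              range(st$geom$timestamps_s))
  # zero parameters: identical to projecting the reference
  expect_equal(forward_model(params, st$phantom, st$geom, 3),
               forward_project(st$phantom, st$geom, 3), tolerance = 1e-14)
  # matches the manual pull-then-project composition
  set.seed(41)
  params$components[[1]]$cz <- array(rnorm(64, 0, 2), c(4, 4, 4))
  params$components[[1]]$ct <- runif(params$n_temporal)
  t0 <- st$geom$timestamps_s[5]
  fld <- evaluate_motion_field(params, st$grid, t0)
  manual <- forward_project(pull_volume(st$phantom, fld), st$geom, 5)
  expect_equal(forward_model(params, st$phantom, st$geom, 5), manual,
               tolerance = 1e-12)
  # linear in the reference for fixed parameters
  a <- smooth_random_volume(st$grid, seed = 42)
  b <- smooth_random_volume(st$grid, seed = 43)
  ab <- volume(st$grid, a$values + b$values)
  expect_equal(forward_model(params, ab, st$geom, 2),
               forward_model(params, a, st$geom, 2) +
                 forward_model(params, b, st$geom, 2), tolerance = 1e-10)
})

test_that("loss matches an independent per-frame accumulation", {
  st <- tiny_study()
  set.seed(44)
  params <- motion_parameters(st$spline, st$grid,
                              range(st$geom$timestamps_s))
  params$components[[1]]$cz <- array(rnorm(64), c(4, 4, 4))
  params$components[[1]]$ct <- runif(params$n_temporal)
  reg <- regularizer_config(weight = 1e-5)
  lv <- motion_loss(params, st$phantom, st$geom, st$y, reg)
  acc <- 0
  for (t in seq_len(st$geom$n_frames)) {
    acc <- acc + sum((forward_model(params, st$phantom, st$geom, t) -
                        st$y$values[, , t])^2)
  }
  acc <- acc + reg$weight *
    jacobian_penalty(params, frame_times = st$geom$timestamps_s,
                     config = reg)
  expect_lt(abs(lv - acc) / acc, 1e-8)
  # lambda = 0 reduces to the pure data term
  expect_equal(motion_loss(params, st$phantom, st$geom, st$y,
                           regularizer_config(weight = 0)),
               acc - reg$weight *
                 jacobian_penalty(params,
                                  frame_times = st$geom$timestamps_s,
                                  config = reg),
               tolerance = 1e-10)
  expect_error(motion_loss(params, st$phantom, st$geom,
                           projection_set(st$geom,
                                          array(1, dim(st$y$values)),
                                          "counts"), reg),
               "line-integral")
})

test_that("true parameters give a vanishing loss on noiseless data", {
  st <- tiny_study(amplitude = 6, noise_free = TRUE)
  loss <- motion_loss(st$truth$params, st$phantom, st$geom, st$y,
                      regularizer_config(weight = 0))
  expect_lt(loss, 1e-6 * sum(st$y$values^2))
})

test_that("analytic gradient matches central finite differences", {
  st <- tiny_study(n = 10, n_frames = 6)
  for (rank in c(1L, 2L)) {
  template <- motion_parameters(st$spline, st$grid,
                                range(st$geom$timestamps_s), rank)
  set.seed(45)
  theta <- runif(n_parameters(template), -1, 1)
  params <- cbctmoco:::vector_to_params(theta, template)
  reg <- regularizer_config(weight = 1e-4)
  basis <- cbctmoco:::params_spatial_basis(template, st$grid)
  Btau <- temporal_basis(st$spline, st$geom$timestamps_s,
                         range(st$geom$timestamps_s))
  lv <- cbctmoco:::loss_value_grad(params, st$phantom, st$geom, st$y, reg,
                                   basis, Btau)
  h <- 1e-5
  idx <- sample(seq_along(theta), 12)
  for (i in idx) {
    tp <- theta; tp[i] <- tp[i] + h
    tm <- theta; tm[i] <- tm[i] - h
    num <- (motion_loss(cbctmoco:::vector_to_params(tp, template),
                        st$phantom, st$geom, st$y, reg) -
              motion_loss(cbctmoco:::vector_to_params(tm, template),
                          st$phantom, st$geom, st$y, reg)) / (2 * h)
    expect_lt(abs(num - lv$grad[i]) / max(abs(num), 1e-6), 1e-3)
  }
  }
})

test_that("estimation of static data stays near the identity motion", {
  st <- tiny_study(amplitude = 0, noise_free = TRUE)
  est <- estimate_motion(st$phantom, st$geom, st$y, spline = st$spline,
                         config = estimation_config(n_epochs = 100,
                                                    rng_seed = 0),
                         reg = regularizer_config())
  fld <- evaluate_motion_field(est$params, st$grid,
                               mean(range(st$geom$timestamps_s)))
  mean_disp <- mean(sqrt(rowSums(matrix(fld$displacement, ncol = 3)^2)))
  expect_lt(mean_disp, 0.2 * min(st$grid$voxel_size_mm))
})

test_that("optimization descends and is reproducible across seeds", {
  st <- tiny_study(amplitude = 6)
  traces <- list()
  for (seed in 0:2) {
    est <- estimate_motion(st$phantom, st$geom, st$y, spline = st$spline,
                           config = estimation_config(n_epochs = 25,
                                                      rng_seed = seed),
                           reg = regularizer_config())
    expect_length(est$loss_trace, 25)
    expect_lt(est$final_loss, est$loss_trace[1])
    traces[[as.character(seed)]] <- est$loss_trace
  }
  # 10-epoch moving average of the loss is non-increasing
  ma <- stats::filter(traces[["0"]], rep(1 / 10, 10), sides = 1)
  ma <- ma[!is.na(ma)]
  expect_true(all(diff(ma) <= 1e-9))
  # bitwise-identical rerun under the same seed
  rerun <- estimate_motion(st$phantom, st$geom, st$y, spline = st$spline,
                           config = estimation_config(n_epochs = 25,
                                                      rng_seed = 1),
                           reg = regularizer_config())
  expect_identical(rerun$loss_trace, traces[["1"]])
})

test_that("stronger regularization yields a smaller converged penalty", {
  st <- tiny_study(amplitude = 6)
  pen_at <- function(w) {
    est <- estimate_motion(st$phantom, st$geom, st$y, spline = st$spline,
                           config = estimation_config(n_epochs = 30,
                                                      rng_seed = 0),
                           reg = regularizer_config(weight = w))
    jacobian_penalty(est$params, frame_times = st$geom$timestamps_s,
                     config = regularizer_config())
  }
  expect_gte(pen_at(1e-6), pen_at(1e-1))
})
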