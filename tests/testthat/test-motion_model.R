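# independent Cox-de Boor recursion for clamped cubic B-splines (oracle)
cox_de_boor <- function(knots, x, i, p) {
  if (p == 0) {
    # right-closed on the last interval so the basis covers [a, b]
    last <- max(which(knots < knots[length(knots)]))
    if ((x >= knots[i] && x < knots[i + 1]) ||
        (x == knots[length(knots)] && i == last)) return(1)
    return(0)
  }
  d1 <- knots[i + p] - knots[i]
  d2 <- knots[i + p + 1] - knots[i + 1]
  t1 <- if (d1 > 0) (x - knots[i]) / d1 * cox_de_boor(knots, x, i, p - 1) else 0
  t2 <- if (d2 > 0) {
    (knots[i + p + 1] - x) / d2 * cox_de_boor(knots, x, i + 1, p - 1)
  } else 0
  t1 + t2
}

test_that("spline configuration enforces cubic support", {
  expect_error(spline_config(3), "at least 4")
  expect_error(spline_config(8, temporal_rate_hz = 0), "positive")
  cfg <- spline_config(c(5, 6, 7), 2)
  expect_equal(cfg$spatial_control_points, c(5L, 6L, 7L))
})

test_that("spatial basis satisfies partition of unity and Cox-de Boor", {
  cfg <- spline_config(c(6, 5, 4))
  grid <- volume_grid(c(17, 13, 9), c(3, 4, 5))
  b <- spatial_basis(cfg, grid)
  expect_lt(max(abs(rowSums(b$Bx) - 1)), 1e-10)
  expect_lt(max(abs(rowSums(b$By) - 1)), 1e-10)
  expect_lt(max(abs(rowSums(b$Bz) - 1)), 1e-10)
  # oracle check at 100 random points
  set.seed(11)
  kn <- b$knots[[1]]
  a <- kn[4]
  bb <- kn[length(kn) - 3]
  xs <- c(stats::runif(98, a, bb), a, bb)
  for (x in xs[sample.int(100, 25)]) {
    ref <- vapply(seq_len(6), function(i) cox_de_boor(kn, x, i, 3), numeric(1))
    mine <- cbctmoco:::basis_matrix(kn, x)
    expect_lt(max(abs(mine - ref)), 1e-10)
  }
})

test_that("temporal basis has the protocol's control-point count", {
  cfg <- spline_config(8, temporal_rate_hz = 2)
  times <- seq(0, 29, by = 0.182)
  B <- temporal_basis(cfg, times, c(0, 29))
  expect_equal(attr(B, "n_interior"), 58L)    # 29 s at 2.0 per second
  expect_equal(ncol(B), 61L)                  # + clamped boundary padding
  expect_lt(max(abs(rowSums(B) - 1)), 1e-10)
  # constant coefficients expand to a constant in time
  k <- 2.7
  expect_equal(as.numeric(B %*% rep(k, 61)), rep(k, length(times)),
               tolerance = 1e-12)
  expect_error(temporal_basis(cfg, numeric(0)), "non-empty")
})

test_that("motion field evaluation matches a nested-loop oracle", {
  set.seed(12)
  cfg <- spline_config(c(5, 4, 6), temporal_rate_hz = 1)
  grid <- volume_grid(c(12, 10, 14), c(3, 4, 2.5))
  params <- motion_parameters(cfg, grid, c(0, 10), 2)
  for (ci in 1:2) {
    for (f in c("cx", "cy", "cz")) {
      params$components[[ci]][[f]] <-
        array(rnorm(prod(cfg$spatial_control_points)),
              cfg$spatial_control_points)
    }
    params$components[[ci]]$ct <- rnorm(params$n_temporal)
  }
  fld <- evaluate_motion_field(params, grid, 4.3)
  b <- cbctmoco:::params_spatial_basis(params, grid)
  Bt <- temporal_basis(cfg, 4.3, c(0, 10))
  for (trial in 1:50) {
    v <- c(sample.int(12, 1), sample.int(10, 1), sample.int(14, 1))
    expected <- c(0, 0, 0)
    for (ci in 1:2) {
      tau <- sum(Bt * params$components[[ci]]$ct)
      s <- c(0, 0, 0)
      for (i in 1:5) for (j in 1:4) for (k in 1:6) {
        w <- b$Bx[v[1], i] * b$By[v[2], j] * b$Bz[v[3], k]
        s <- s + w * c(params$components[[ci]]$cx[i, j, k],
                       params$components[[ci]]$cy[i, j, k],
                       params$components[[ci]]$cz[i, j, k])
      }
      expected <- expected + s * tau
    }
    expect_lt(max(abs(fld$displacement[v[1], v[2], v[3], ] - expected)), 1e-8)
  }
})

test_that("zero and uniform coefficients give identity and pure translation", {
  cfg <- spline_config(5, temporal_rate_hz = 1)
  grid <- volume_grid(c(10, 10, 10), 4)
  params <- motion_parameters(cfg, grid, c(0, 6))
  fld <- evaluate_motion_field(params, grid, 3)
  expect_identical(max(abs(fld$displacement)), 0)   # D(r) = r exactly
  # all spatial z-coefficients 3 mm, temporal value 0.5
  params$components[[1]]$cz <- array(3, cfg$spatial_control_points)
  params$components[[1]]$ct <- rep(0.5, params$n_temporal)
  fld <- evaluate_motion_field(params, grid, 3)
  expect_equal(as.numeric(fld$displacement[, , , 3]),
               rep(1.5, 1000), tolerance = 1e-12)
  expect_equal(max(abs(fld$displacement[, , , 1:2])), 0)
  # uniform translation has a zero Jacobian
  J <- motion_jacobian(params, grid, 3)
  expect_lt(max(abs(J)), 1e-12)
})

test_that("analytic Jacobian agrees with finite differences", {
  set.seed(13)
  cfg <- spline_config(5, temporal_rate_hz = 1)
  grid <- volume_grid(c(12, 12, 12), 4)
  params <- motion_parameters(cfg, grid, c(0, 6))
  for (f in c("cx", "cy", "cz")) {
    params$components[[1]][[f]] <- array(rnorm(125, 0, 3), c(5, 5, 5))
  }
  params$components[[1]]$ct <- runif(params$n_temporal, 0.5, 1)
  J <- motion_jacobian(params, grid, 3)
  h <- 1e-4
  for (v in list(c(6, 6, 6), c(4, 8, 5), c(9, 3, 7))) {
    for (d in 1:3) {
      gp <- grid; gp$origin_mm[d] <- gp$origin_mm[d] + h
      gm <- grid; gm$origin_mm[d] <- gm$origin_mm[d] - h
      fp <- evaluate_motion_field(params, gp, 3)$displacement[v[1], v[2], v[3], ]
      fm <- evaluate_motion_field(params, gm, 3)$displacement[v[1], v[2], v[3], ]
      fd <- (fp - fm) / (2 * h)
      expect_lt(max(abs(J[v[1], v[2], v[3], , d] - fd) /
                      pmax(abs(fd), 1e-3)), 1e-3)
    }
  }
})

test_that("low-rank structure: displacement is linear in the temporal row", {
  set.seed(14)
  cfg <- spline_config(4, temporal_rate_hz = 1)
  grid <- volume_grid(c(8, 8, 8), 5)
  params <- motion_parameters(cfg, grid, c(0, 4))
  params$components[[1]]$cz <- array(rnorm(64, 0, 2), c(4, 4, 4))
  ct1 <- rnorm(params$n_temporal)
  ct2 <- rnorm(params$n_temporal)
  d_at <- function(ct, t) {
    p <- params
    p$components[[1]]$ct <- ct
    evaluate_motion_field(p, grid, t)$displacement
  }
  t0 <- 1.7
  expect_equal(d_at(2 * ct1 + 3 * ct2, t0),
               2 * d_at(ct1, t0) + 3 * d_at(ct2, t0), tolerance = 1e-10)
})

test_that("parameter count matches the model arithmetic", {
  cfg <- spline_config(c(5, 6, 7), temporal_rate_hz = 2)
  grid <- volume_grid(c(8, 8, 8), 10)
  params <- motion_parameters(cfg, grid, c(0, 10), 3)
  expect_equal(n_parameters(params),
               3L * (3L * 5L * 6L * 7L + params$n_temporal))
  expect_error(motion_parameters(cfg, grid, c(0, 10), 0), "at least 1")
})

test_that("motion profile probe equals the dense field at that voxel", {
  set.seed(15)
  cfg <- spline_config(5, temporal_rate_hz = 1)
  grid <- volume_grid(c(10, 10, 10), 4)
  params <- motion_parameters(cfg, grid, c(0, 6))
  for (f in c("cx", "cy", "cz")) {
    params$components[[1]][[f]] <- array(rnorm(125), c(5, 5, 5))
  }
  params$components[[1]]$ct <- rnorm(params$n_temporal)
  v <- c(3, 7, 5)
  prof <- motion_profile_at(params, grid, v, c(1.1, 4.2))
  f1 <- evaluate_motion_field(params, grid, 1.1)
  f2 <- evaluate_motion_field(params, grid, 4.2)
  expect_equal(prof[1, ], f1$displacement[3, 7, 5, ], tolerance = 1e-10)
  expect_equal(prof[2, ], f2$displacement[3, 7, 5, ], tolerance = 1e-10)
})
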