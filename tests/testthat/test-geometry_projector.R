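test_that("geometry and container constructors enforce their invariants", {
  expect_error(scan_geometry(1000, 900, 16, 16, 1, 0, 0), "exceed")
  expect_error(scan_geometry(-1, 900, 16, 16, 1, 0, 0), "positive")
  expect_error(scan_geometry(500, 900, 16, 16, 1, c(0, 1), c(1, 0)),
               "increasing")
  expect_error(scan_geometry(500, 900, 16, 16, 1, c(0, 1), 0), "equal length")
  expect_error(volume_grid(c(0, 4, 4), 1), "counts")
  expect_error(volume_grid(c(4, 4, 4), -1), "positive")
  g <- volume_grid(c(4, 4, 4), 2)
  expect_equal(g$origin_mm, c(-3, -3, -3))   # grid centered on isocenter
  expect_error(volume(g, array(NA_real_, c(4, 4, 4))), "finite")
  geom <- tiny_geometry()
  expect_error(projection_set(geom, array(0, c(16, 16, 3))), "n_frames")
  expect_error(projection_set(geom, array(-1, c(16, 16, 4)), "counts"),
               "non-negative")
})

test_that("forward projection is linear and zero at the origin", {
  geom <- tiny_geometry()
  grid <- volume_grid(c(8, 8, 8), 10)
  expect_equal(forward_project(volume(grid, 0), geom, 2),
               matrix(0, 16, 16))
  set.seed(2)
  x1 <- volume(grid, array(rnorm(512), c(8, 8, 8)))
  x2 <- volume(grid, array(rnorm(512), c(8, 8, 8)))
  sum12 <- volume(grid, x1$values + x2$values)
  expect_equal(forward_project(sum12, geom, 3),
               forward_project(x1, geom, 3) + forward_project(x2, geom, 3),
               tolerance = 1e-12)
  expect_error(forward_project(x1, geom, 5), "out of range")
})

test_that("projection of a unit cube matches dense ray-marching", {
  grid <- volume_grid(c(24, 24, 24), 4)
  cube <- array(0, c(24, 24, 24))
  cube[7:18, 7:18, 7:18] <- 1     # 48 mm cube, axis-aligned
  vol <- volume(grid, cube)
  geom <- scan_geometry(1000, 1536, 16, 16, 6,
                        angles_deg = c(0, 28, 75), timestamps_s = 0:2)
  for (frame in 1:3) {
    p <- forward_project(vol, geom, frame)
    for (px in list(c(8, 8), c(9, 9), c(8, 10))) {
      oracle <- ray_march_integral(vol, geom, frame, px[1], px[2])
      expect_lt(abs(p[px[1], px[2]] - oracle) / oracle, 0.005)
    }
  }
})

test_that("back projection is the exact adjoint and linear", {
  geom <- tiny_geometry()
  grid <- volume_grid(c(8, 8, 8), 10)
  expect_equal(back_project(matrix(0, 16, 16), geom, 1, grid)$values,
               array(0, c(8, 8, 8)))
  set.seed(4)
  for (i in 1:20) {
    x <- volume(grid, array(rnorm(512), c(8, 8, 8)))
    p <- matrix(rnorm(256), 16, 16)
    f <- sample.int(4, 1)
    lhs <- sum(forward_project(x, geom, f) * p)
    rhs <- sum(x$values * back_project(p, geom, f, grid)$values)
    expect_lt(abs(lhs - rhs) /
                (sqrt(sum(x$values^2)) * sqrt(sum(p^2))), 1e-4)
  }
  p1 <- matrix(rnorm(256), 16, 16)
  p2 <- matrix(rnorm(256), 16, 16)
  expect_equal(back_project(p1 + p2, geom, 2, grid)$values,
               back_project(p1, geom, 2, grid)$values +
                 back_project(p2, geom, 2, grid)$values,
               tolerance = 1e-12)
  expect_error(back_project(matrix(0, 8, 8), geom, 1, grid), "shape")
})

test_that("adjointness holds against a materialized dense matrix", {
  geom <- tiny_geometry(n_frames = 2)
  grid <- volume_grid(c(8, 8, 8), 10)
  A <- dense_system_matrix(geom, 2, grid)
  set.seed(5)
  x <- rnorm(512)
  p <- rnorm(256)
  lhs <- sum((A %*% x) * p)
  rhs <- sum(x * as.numeric(back_project(matrix(p, 16, 16), geom, 2,
                                         grid)$values))
  expect_lt(abs(lhs - rhs) / (sqrt(sum(x^2)) * sqrt(sum(p^2))), 1e-4)
})

test_that("rotating phantom and gantry together leaves projections unchanged", {
  grid <- volume_grid(c(20, 20, 12), 5)
  vol <- smooth_random_volume(grid, seed = 7)
  geom <- scan_geometry(600, 1000, 16, 16, 5,
                        angles_deg = c(33, 123), timestamps_s = 0:1)
  # rotate the volume by +90 deg about z: world (x,y) -> (-y,x)
  rot <- aperm(vol$values, c(2, 1, 3))[rev(seq_len(20)), , , drop = FALSE]
  vol_rot <- volume(grid, rot)
  p_orig <- forward_project(vol, geom, 1)       # gantry at 33
  p_rot <- forward_project(vol_rot, geom, 2)    # object +90, gantry +90
  expect_equal(p_rot, p_orig, tolerance = 1e-10)
})

test_that("log transform inverts the Beer-Lambert counts model", {
  geom <- tiny_geometry(n_frames = 2)
  s0 <- 1e5
  counts <- array(s0, c(16, 16, 2))
  s <- projection_set(geom, counts, "counts")
  expect_equal(log_transform(s, s0)$values, array(0, c(16, 16, 2)))
  s2 <- projection_set(geom, array(s0 * exp(-2), c(16, 16, 2)), "counts")
  expect_equal(log_transform(s2, s0)$values, array(2, c(16, 16, 2)),
               tolerance = 1e-12)
  # round trip including the clamp at the floor
  set.seed(8)
  raw <- array(stats::runif(16 * 16 * 2, 0, 50), c(16, 16, 2))
  s3 <- projection_set(geom, raw, "counts")
  y <- log_transform(s3, s0)
  expect_equal(s0 * exp(-y$values), pmax(raw, 1), tolerance = 1e-12)
  expect_error(log_transform(s3, 0), "positive")
  expect_error(log_transform(y, s0), "counts")
})

test_that("source intensity is estimated from background counts", {
  geom <- tiny_geometry(n_frames = 160)
  roi <- list(rows = 1:8, cols = 1:8)
  s <- projection_set(geom, array(123.4, c(16, 16, 160)), "counts")
  expect_equal(estimate_source_intensity(s, roi), 123.4)
  # Poisson flat field: law of large numbers over 32x32(restricted) x 160
  set.seed(9)
  flat <- array(stats::rpois(16 * 16 * 160, 1e5), c(16, 16, 160))
  sp <- projection_set(geom, flat, "counts")
  est <- estimate_source_intensity(sp, list(rows = 1:16, cols = 1:16))
  expect_lt(abs(est - 1e5) / 1e5, 0.001)
  expect_error(estimate_source_intensity(s, list(rows = 10:20, cols = 1:4)),
               "outside")
  expect_error(estimate_source_intensity(s, list(rows = integer(0),
                                                 cols = 1:4)), "non-empty")
})
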