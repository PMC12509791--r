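test_that("phantom construction is additive, bounded and deterministic", {
  grid <- volume_grid(c(24, 24, 24), 8)
  empty <- phantom_spec(grid, structures = list())
  expect_equal(make_phantom(empty)$values, array(0, c(24, 24, 24)))
  p1 <- make_phantom(phantom_spec(grid))
  p2 <- make_phantom(phantom_spec(grid))
  expect_identical(p1$values, p2$values)
  expect_true(all(p1$values >= 0))
  neg <- phantom_spec(grid, structures = list(
    list(center = c(0, 0, 0), semi_axes = c(40, 40, 40), delta = -0.01)))
  expect_error(make_phantom(neg), "negative")
})

test_that("a single ellipsoid has the analytic volume", {
  grid <- volume_grid(c(64, 64, 64), 2)
  semi <- c(40, 30, 25)
  spec <- phantom_spec(grid, structures = list(
    list(center = c(0, 0, 0), semi_axes = semi, delta = 1)))
  vol <- make_phantom(spec)
  count <- sum(vol$values > 0.5)
  analytic <- 4 / 3 * pi * prod(semi) / prod(grid$voxel_size_mm)
  expect_lt(abs(count - analytic) / analytic, 0.02)
})

test_that("respiration is periodic without jitter and jitters as configured", {
  times <- seq(0, 29, by = 0.182)
  grid <- volume_grid(c(12, 12, 12), 16)
  spec0 <- respiratory_spec(amplitude_mm = 0)
  m0 <- make_respiratory_motion(spec0, times, grid)
  expect_true(all(vapply(m0$fields, function(f) max(abs(f$displacement)),
                         numeric(1)) == 0))
  # zero jitter: peaks exactly one mean period (5 s) apart
  spec <- respiratory_spec(amplitude_mm = 12, period_jitter_fraction = 0,
                           amplitude_jitter_fraction = 0)
  m <- make_respiratory_motion(spec, times, grid)
  prof <- m$profile
  peaks <- which(diff(sign(diff(prof))) == -2) + 1
  expect_gte(length(peaks), 4)
  gaps <- diff(times[peaks])
  expect_true(all(abs(gaps - 5) < 0.2))
  # mean cycle length across 100 seeded draws near the mean period
  periods <- unlist(lapply(1:100, function(s) {
    mm <- make_respiratory_motion(
      respiratory_spec(period_jitter_fraction = 0.1, rng_seed = s),
      times, grid)
    mm$periods
  }))
  expect_lt(abs(mean(periods) - 5) / 5, 0.05)
})

test_that("the acquisition simulator follows the counts noise model", {
  grid <- volume_grid(c(12, 12, 12), 10)
  phant <- make_phantom(phantom_spec(grid))
  geom <- scan_geometry(1000, 1536, 10, 10, 40,
                        angles_deg = seq(0, 170, length.out = 12),
                        timestamps_s = seq(0, 2, length.out = 12))
  # noise-free counts invert exactly under the log transform
  sim <- simulate_acquisition(phant, NULL, geom, noise_spec(),
                              noise_free = TRUE)
  expect_equal(sim$counts$values, 1e5 * exp(-sim$clean_line_integrals),
               tolerance = 1e-14)
  y <- log_transform(sim$counts, 1e5)
  expect_lt(max(abs(y$values - sim$clean_line_integrals)), 1e-12)
  # seeded determinism of the noisy draw
  s1 <- simulate_acquisition(phant, NULL, geom, noise_spec(rng_seed = 5))
  s2 <- simulate_acquisition(phant, NULL, geom, noise_spec(rng_seed = 5))
  expect_identical(s1$counts$values, s2$counts$values)
})

test_that("static objects give angle-dependent-only projections", {
  grid <- volume_grid(c(12, 12, 12), 10)
  phant <- make_phantom(phantom_spec(grid))
  geom <- scan_geometry(1000, 1536, 10, 10, 40,
                        angles_deg = c(10, 50, 10, 50),
                        timestamps_s = 0:3)
  spl <- spline_config(4, temporal_rate_hz = 1)
  resp <- make_respiratory_motion(
    respiratory_spec(amplitude_mm = 0, period_jitter_fraction = 0,
                     amplitude_jitter_fraction = 0),
    geom$timestamps_s, grid, form = "rank1", spline = spl)
  sim <- simulate_acquisition(phant, resp$params, geom, noise_spec(),
                              noise_free = TRUE)
  expect_equal(sim$clean_line_integrals[, , 1],
               sim$clean_line_integrals[, , 3], tolerance = 1e-12)
  expect_equal(sim$clean_line_integrals[, , 2],
               sim$clean_line_integrals[, , 4], tolerance = 1e-12)
  expect_gt(max(abs(sim$clean_line_integrals[, , 1] -
                      sim$clean_line_integrals[, , 2])), 1e-3)
})

test_that("the default protocol reproduces the clinical acquisition timing", {
  geom <- default_protocol()
  expect_equal(geom$n_frames, 160L)
  expect_equal(geom$timestamps_s[160], 0.182 * 159, tolerance = 1e-12)
  expect_lt(abs(geom$timestamps_s[160] - 29), 0.2)    # a 29 s scan
  expect_equal(diff(geom$angles_deg)[1], 180 / 160, tolerance = 1e-12)
  expect_equal(geom$detector_rows, 512L)
  expect_equal(geom$pixel_spacing_mm, c(0.8, 0.8))
  expect_equal(geom$source_to_detector_mm, 1536)
  # scaled variant preserves the magnification and the total arc
  small <- default_protocol(scale = 1 / 8)
  expect_equal(small$source_to_detector_mm / small$source_to_isocenter_mm,
               geom$source_to_detector_mm / geom$source_to_isocenter_mm)
  expect_equal(small$detector_rows, 64L)
  expect_equal(small$detector_rows * small$pixel_spacing_mm[1],
               geom$detector_rows * geom$pixel_spacing_mm[1])
})
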