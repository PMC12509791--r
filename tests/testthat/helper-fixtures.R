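# Shared fixtures, built in code at test time.

# small cone-beam geometry for operator tests
tiny_geometry <- function(n_frames = 4, det = 16, pitch = 4,
                          sad = 500, sdd = 800) {
  scan_geometry(sad, sdd, det, det, pitch,
                angles_deg = seq(0, 150, length.out = n_frames),
                timestamps_s = seq(0, 3, length.out = n_frames))
}

# smooth random volume (attenuation-like, non-negative)
smooth_random_volume <- function(grid, seed = 1, sigma = 1.2) {
  set.seed(seed)
  v <- array(stats::rnorm(prod(grid$shape), 0.02, 0.01), grid$shape)
  v <- cbctmoco:::gaussian_smooth3(v, sigma)
  volume(grid, pmax(v, 0))
}

# partial-volume antialiased ball (4x supersampled occupancy)
ball_volume <- function(grid, radius_mm) {
  n <- grid$shape
  vox <- grid$voxel_size_mm
  ax <- lapply(1:3, function(a) cbctmoco:::grid_axis_mm(grid, a))
  sub <- lapply(1:3, function(a) ((1:4) - 2.5) * vox[a] / 4)
  vals <- array(0, n)
  for (sx in sub[[1]]) for (sy in sub[[2]]) for (sz in sub[[3]]) {
    d2xy <- outer((ax[[1]] + sx)^2, (ax[[2]] + sy)^2, `+`)
    for (k in seq_len(n[3])) {
      vals[, , k] <- vals[, , k] + (d2xy + (ax[[3]][k] + sz)^2 <= radius_mm^2)
    }
  }
  volume(grid, vals / 64)
}

# analytic chord length of the ray through detector pixel (row, col),
# together with its impact parameter (distance of the ray to the center)
ray_chord <- function(geom, frame, row, col, radius_mm) {
  th <- geom$angles_deg[frame] * pi / 180
  sad <- geom$source_to_isocenter_mm
  sdd <- geom$source_to_detector_mm
  du <- geom$pixel_spacing_mm[2]
  dv <- geom$pixel_spacing_mm[1]
  u <- (col - 1 - (geom$detector_cols - 1) / 2) * du
  v <- (row - 1 - (geom$detector_rows - 1) / 2) * dv
  S <- c(-sad * sin(th), sad * cos(th), 0)
  D0 <- c((sdd - sad) * sin(th), -(sdd - sad) * cos(th), 0)
  P <- D0 + u * c(cos(th), sin(th), 0) + v * c(0, 0, 1)
  d <- P - S
  d <- d / sqrt(sum(d^2))
  b <- sqrt(sum((S - sum(S * d) * d)^2))
  chord <- if (b < radius_mm) 2 * sqrt(radius_mm^2 - b^2) else 0
  list(chord = chord, impact = b)
}

# dense ray-marching line integral through a volume (independent oracle):
# tri-linear samples every `step_frac` of a voxel along the source-pixel ray
ray_march_integral <- function(vol, geom, frame, row, col, step_frac = 0.1) {
  grid <- vol$grid
  th <- geom$angles_deg[frame] * pi / 180
  sad <- geom$source_to_isocenter_mm
  sdd <- geom$source_to_detector_mm
  du <- geom$pixel_spacing_mm[2]
  dv <- geom$pixel_spacing_mm[1]
  u <- (col - 1 - (geom$detector_cols - 1) / 2) * du
  v <- (row - 1 - (geom$detector_rows - 1) / 2) * dv
  S <- c(-sad * sin(th), sad * cos(th), 0)
  D0 <- c((sdd - sad) * sin(th), -(sdd - sad) * cos(th), 0)
  P <- D0 + u * c(cos(th), sin(th), 0) + v * c(0, 0, 1)
  dir <- P - S
  len <- sqrt(sum(dir^2))
  step_mm <- step_frac * min(grid$voxel_size_mm)
  ts <- seq(0, 1, by = step_mm / len)
  tri <- function(w) {       # world position -> tri-linear sample
    q <- (w - grid$origin_mm) / grid$voxel_size_mm
    i0 <- floor(q)
    f <- q - i0
    acc <- 0
    for (dx in 0:1) for (dy in 0:1) for (dz in 0:1) {
      ii <- i0 + c(dx, dy, dz)
      if (any(ii < 0) || any(ii > grid$shape - 1)) next
      w3 <- prod(ifelse(c(dx, dy, dz) == 1, f, 1 - f))
      acc <- acc + w3 * vol$values[ii[1] + 1, ii[2] + 1, ii[3] + 1]
    }
    acc
  }
  vals <- vapply(ts, function(t) tri(S + t * (P - S)), numeric(1))
  sum(vals) * step_mm   # rectangle rule at fine steps
}

# rank-1 sinusoidal z-motion study: the standard synthetic case
make_rank1_study <- function(n = 48, n_frames = 160, amplitude_mm = 10,
                             ctrl = 8, noise_seed = 1, noise_free = FALSE) {
  grid <- volume_grid(rep(n, 3L), 256 * 1.2 / n)
  geom <- default_protocol(scale = n / 512, n_frames = n_frames)
  phant <- make_phantom(phantom_spec(grid))
  spl <- spline_config(ctrl, temporal_rate_hz = 2)
  resp <- make_respiratory_motion(
    respiratory_spec(amplitude_mm = amplitude_mm, mean_period_s = 5,
                     period_jitter_fraction = 0,
                     amplitude_jitter_fraction = 0),
    geom$timestamps_s, grid, form = "rank1", spline = spl)
  sim <- simulate_acquisition(phant, resp$params, geom,
                              noise_spec(rng_seed = noise_seed),
                              noise_free = noise_free)
  list(grid = grid, geom = geom, phantom = phant, spline = spl,
       truth = resp, sim = sim,
       y = log_transform(sim$counts, 1e5))
}

# probe voxel on the liver-dome (diaphragm-like) interface of the phantom
diaphragm_probe_voxel <- function(grid) {
  n <- grid$shape
  c(round(n[1] / 2 + 0.38 * n[1] / 2), round(n[2] / 2),
    round(n[3] / 2 + 0.03 * n[3] / 2))
}

# materialize the system matrix of one frame as a dense matrix
dense_system_matrix <- function(geom, frame, grid) {
  nvox <- prod(grid$shape)
  npix <- geom$detector_rows * geom$detector_cols
  A <- matrix(0, npix, nvox)
  for (j in seq_len(nvox)) {
    e <- numeric(nvox)
    e[j] <- 1
    A[, j] <- as.numeric(forward_project(
      volume(grid, array(e, grid$shape)), geom, frame))
  }
  A
}
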