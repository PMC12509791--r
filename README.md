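# cbctmoco

Gate-less, model-based estimation and correction of non-rigid motion in
cone-beam CT (CBCT).

## The problem

CBCT for radiotherapy position verification acquires one 2D projection per
gantry angle over roughly half a minute. Breathing, bowel motion and
repositioning during the scan blur the reconstruction, most visibly at
high-contrast interfaces such as the lung–liver boundary. Respiratory
gating addresses only periodic motion; irregular breathing still produces
blurred or doubled anatomy.

`cbctmoco` reconstructs both the motion and the image, without gating. A
time-resolved non-rigid 3D motion field is estimated *per projection
frame* (182 ms temporal resolution for the emulated scanner protocol)
directly in projection space, and alternated with a motion-compensated
iterative reconstruction. It is aimed at researchers in tomographic image
reconstruction and adaptive radiotherapy who want a transparent, fully
testable desk-scale implementation of this class of algorithm.

## The model

Counts follow Beer–Lambert, `s_t = s0 exp(-y_t)`; the negative log gives
line integrals `y_t = A_t x_t` with `A_t` the frame's cone-beam system
matrix (Joseph ray tracing with its exact transpose). The dynamic object
is a deformation of a reference image `x0`:

    y_t = A_t x0[r + delta_t(r)]

The displacement is a low-rank spatio-temporal cubic B-spline model,
`delta_t(r) = sum_c sigma_c(r) tau_c(t)`, and the motion coefficients `c`
minimize the projection-space loss

    L(c) = sum_t || A_t x0[D_t(r|c)] - y_t ||^2 + lambda R,

with `R` the squared norm of the spatial displacement gradients, by
full-batch NAdam with analytic gradients (the projector adjoint is the
backward step). Reconstruction is motion-compensated SIRT: the current
guess is pulled into each frame's motion state, compared, backprojected,
and the correction pushed back with the normalized splat that approximates
the inverse warp. The outer loop alternates estimation and reconstruction
from a motion-corrupted initial reference until the estimation loss stops
improving.

A deformable digital thorax phantom (ellipsoid body, lungs, liver dome,
tumor, ribs), a semi-periodic breathing generator (mean period 5 s,
per-cycle amplitude/period jitter) and a Poisson + Gaussian counts
simulator (`s0 = 1e5`, electronic variance 10) provide fully synthetic,
seeded studies. Evaluation metrics: volumetric SSIM over the field of
view, edge-spread-function width (sharpness `1/w`), and per-axis motion
RMSE.

## Worked example

Simulate a breathing thorax phantom at desk scale, then estimate its
motion from the projections alone:

```r
library(cbctmoco)

# desk-scale study: 32^3 thorax phantom, 80 projections over 180 degrees
grid  <- volume_grid(c(32, 32, 32), voxel_size_mm = 9.6)
geom  <- default_protocol(scale = 32 / 512, n_frames = 80)
phant <- make_phantom(phantom_spec(grid))

# ground-truth breathing: 10 mm sinusoidal z-motion, 5 s period,
# generated as an exact rank-1 instance of the spline model
spl  <- spline_config(spatial_control_points = 6, temporal_rate_hz = 2)
resp <- make_respiratory_motion(
  respiratory_spec(amplitude_mm = 10, period_jitter_fraction = 0,
                   amplitude_jitter_fraction = 0),
  geom$timestamps_s, grid, form = "rank1", spline = spl)

# noisy acquisition: counts = Poisson(1e5 exp(-y)) + N(0, 10)
sim <- simulate_acquisition(phant, resp$params, geom, noise_spec(rng_seed = 1))
y   <- log_transform(sim$counts, s0 = 1e5)

# projection-space motion estimation against the true reference
est <- estimate_motion(phant, geom, y, spline = spl,
                       config = estimation_config(n_epochs = 40, rng_seed = 0))
est
#> estimation_result: 40 epochs, loss 1935 -> 54.02

probe <- c(22, 16, 17)   # voxel on the lung-liver interface
rmse <- motion_rmse(
  motion_profile_at(est$params, grid, probe, geom$timestamps_s),
  motion_profile_at(resp$params, grid, probe, geom$timestamps_s))
round(rmse, 3)
#>     x     y     z
#> 0.358 0.022 0.392
```

The loss drops by a factor ~36 over 40 epochs, and the recovered
displacement trajectory at the interface voxel tracks the 10 mm ground
truth with sub-millimeter RMSE on every axis — far below the 9.6 mm voxel
size. The full pipeline (`run_moco()`) additionally reconstructs the
motion-corrected image; on the same study its SSIM against the static
truth exceeds the motion-corrupted reconstruction's.

A command-line front end wraps the same functions:

```sh
exec/cbctmoco simulate --out study --voxels 48 --frames 160 --seed 1
exec/cbctmoco run --projections study/projections.tif \
    --geometry study/geometry.json --out study/result --seed 1
```

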