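---
title: "Gate-less motion estimation and correction for cone-beam CT"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Gate-less motion estimation and correction for cone-beam CT}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(cbctmoco)
```

## The problem

A cone-beam CT scan acquires one 2D projection per gantry angle over half a
minute. A patient who breathes during that time is imaged in 160 different
motion states, and a reconstruction that ignores this shows blurred or
doubled organ interfaces — most visibly the lung–liver boundary. Gating
mitigates the artifact by sorting projections into respiratory phases, but
it assumes periodicity and fails on irregular breathing.

`cbctmoco` takes the gate-less route: it estimates a non-rigid 3D motion
field *for every projection frame* directly in projection space, and
alternates that estimation with a motion-compensated iterative
reconstruction. No phase sorting, no surrogate signal, no periodicity
assumption.

## Signal model

Photon counts at frame $t$ follow the mono-energetic Beer–Lambert model
$s_t = s_0 \exp(-y_t)$, where $y_t = A_t x_t$ are cone-beam line integrals
of the attenuation volume $x_t$ and $A_t$ is the frame's system matrix.
Taking the negative log linearizes the model. The dynamic object is a
deformation of a reference image $x_0$:
$x_t[r] = x_0[r + \delta_t(r)]$, with per-voxel displacement $\delta_t$.
Substituting gives the forward model used throughout,
$y_t = A_t\, x_0[D_t(r)]$ with $D_t(r) = r + \delta_t(r)$.

The projector is Joseph (slice-interpolated) ray tracing with its exact
transpose as the backprojector. Exact adjointness is not cosmetic: the
motion optimization backpropagates through $A_t$, and a mismatched
forward/backward pair biases every gradient. The inner-product identity
$\langle A x, p\rangle = \langle x, A^\top p\rangle$ holds to rounding
error and is asserted in the tests, including against a fully materialized
dense matrix.

## Low-rank spline motion model

Estimating a dense displacement per frame from a single 2D view is hopeless
without structure. Three assumptions make it tractable:

1. **Spatial smoothness** — $\delta_t$ lives on a coarse grid of cubic
   B-spline control points (`spline_config(spatial_control_points = 32)` at
   clinical resolution; proportionally fewer at desk scale).
2. **Spatio-temporal correlation** — the field factorizes into a small sum
   of spatial components scaled by temporal components (rank
   `n_components`, default 1 for respiration):
   $\delta_t(r) = \sum_c \sigma_c(r)\,\tau_c(t)$, each factor a spline
   expansion of coefficients. Temporal control points default to 2 per
   second of scan time.
3. **Regularity** — a spatial penalty on the displacement gradients (below).

Spatial coefficients carry mm; temporal coefficients are unitless. The
bilinear product has a gauge freedom ($\alpha\sigma \cdot \tau/\alpha$); we
leave components unnormalized, which the optimizer tolerates. Boundary
knots are clamped (replicated) so the basis spans the reconstruction
domain exactly and the basis is a partition of unity everywhere inside;
displacement outside the knot span is zero. The 1D bases are evaluated
with `splines::splineDesign`; the tests verify them against an independent
Cox–de Boor recursion.

## Regularizer

The penalty is the joint squared L2 norm of all nine displacement-gradient
components, summed over voxels and frames:
$R = \sum_t \sum_{p,d} \lVert \partial \delta_t^p / \partial d \rVert^2$.
Written on the full mapping $D = r + \delta$ this expression is minimized
by the degenerate collapse $\partial\delta = -I$, and despite occasionally
being called a total-variation penalty it is a squared (Dirichlet) norm.
We therefore penalize the **displacement** gradients, which is zero for
rigid translations and matches the intent of encouraging realistic motion;
the literal mapping convention is available via
`regularizer_config(convention = "mapping")`. The default weight is
$\lambda = 10^{-6}$. Because the model is low-rank, $R$ collapses to a sum
of small Gram-matrix products — it is evaluated and differentiated without
ever forming per-frame dense fields. Whether the penalty is summed per
frame or pooled is ambiguous in principle; we sum per frame, so doubling
the frame count doubles $R$.

## Motion estimation

The loss is plain least squares in projection space plus the weighted
penalty:
$L(c) = \sum_t \lVert A_t x_0[D_t(r\,|\,c)] - y_t \rVert_2^2 + \lambda R$.
There is no explicit noise model in the data term. Optimization is
full-batch NAdam (Nesterov-momentum Adam, PyTorch momentum schedule) with
learning rate 0.1 for 100 epochs, from a uniform random initialization in
$[-0.01, 0.01]$ so the first iterate is essentially the identity motion.

Gradients are analytic: residual → projector adjoint (the registered
backward step for the line integrals) → derivative of the tri-linear
interpolant with respect to the sample position → transposes of the
separable spline expansions. The chain is verified against central finite
differences to $10^{-3}$ relative in the tests. Per-frame work is fused
into C++ kernels that evaluate the low-rank displacement on the fly, so an
epoch costs two projector passes and two warp-gradient passes per frame.

## Motion-compensated SIRT

Reconstruction solves the concatenated least-squares problem with the
simultaneous iterative reconstruction technique,
$x \leftarrow x + C \sum_t W_t^{-1}\{A_t^\top R_t (y_t - A_t W_t\{x\})\}$,
with row/column normalizations $R_t = 1/(A_t 1)$ and
$C = 1/\sum_t A_t^\top 1$, followed by a non-negativity clamp. $W_t$ pulls
(tri-linearly samples) the current guess into frame $t$'s motion state;
$W_t^{-1}$ is the normalized push — splat with the same weights, divided
by the splat of a ones-image — because an exact inverse displacement does
not generally exist. Raw push is the exact linear adjoint of pull
(machine-precision identity in the tests); the normalized variant is the
approximate inverse, whose round-trip residual `compose_check()` reports.

Two numerical choices matter here:

* **Coverage cutoff instead of a floor.** Rays that barely graze the
  volume and voxels barely inside the cone have near-zero normalization
  sums. Flooring them before division amplifies whatever the push scatters
  into them by orders of magnitude, and the pull feeds that back into the
  prediction — we observed exponential divergence on a constant 5 mm
  translation. Entries below `normalization_floor` (default 0.05, relative
  to the positive median) therefore receive **zero** update weight: barely
  sampled voxels are frozen rather than amplified. With identity motion
  and healthy sums this reduces exactly to plain SIRT (asserted
  operator-level).
* **Extended domain.** The transverse grid is padded by 25% per side
  (configurable) so anatomy moving partly outside the field of view can be
  represented; results are returned on the extended grid and cropped with
  `crop_volume()` for comparison.

SIRT starts from zero; alternations are not warm-started (the estimation
re-randomizes per alternation with a seed derived from the master seed,
matching the per-call random initialization of the estimation algorithm —
exposed as a switch).

## The alternation

`run_moco()` log-transforms counts (estimating $s_0$ from background
pixels if not supplied), reconstructs a motion-corrupted reference,
then alternates motion estimation and motion-compensated reconstruction.
The reference motion state is whatever state the corrupted reconstruction
implicitly averages to; no re-anchoring to mid-ventilation is attempted.
Convergence is automated: the loop stops when the final estimation loss
improves by less than `convergence_rel_tol` (default $10^{-3}$) or
increases — continuing past that point demonstrably worsens the estimate —
and the minimum-loss alternation's image and motion are returned. Three
consecutive worsening alternations trigger an early stop with a warning.

## The synthetic study

The simulator stands in for licensed anthropomorphic phantoms and clinical
raw data, preserving the features the method actually exploits:

* **Phantom** — additive ellipsoids: a soft-tissue body, two low-attenuation
  lungs, a liver dome protruding into the right lung (the high-contrast,
  diaphragm-like interface where motion is well encoded), a small tumor,
  and rib-like inclusions. The liver interior is homogeneous, so motion is
  weakly encoded there, as in real anatomy.
* **Motion** — cycle-wise $A_i \sin^2(\pi s/P_i)$ superior-inferior
  translation of sub-diaphragm structures with a smooth cranial taper;
  amplitude and period jitter per cycle (10% default), mean period 5 s.
  The default 15 mm amplitude sits mid-range of clinically observed
  breathing (5.2–30.6 mm). Zero jitter gives exactly periodic motion. The
  ground truth can also be emitted as an exact rank-1 instance of the
  spline model, which recovery tests use to separate optimizer behavior
  from model mismatch.
* **Acquisition** — 160 frames at 182 ms spacing over a 180° arc (29 s),
  512×512 detector at 0.8 mm pitch and 1536 mm source-detector distance,
  with desk-scale variants that shrink the detector proportionally. The
  source-isocenter distance defaults to 1000 mm (the protocol's SDD is
  printed; the SAD is not). Counts are
  $\mathrm{Poisson}(s_0 e^{-y_t}) + \mathcal{N}(0, \sigma^2)$ with
  $s_0 = 10^5$ and $\sigma^2 = 10$.

What the simulator does **not** emulate: scatter, beam hardening, detector
lag/ghosting, anatomical texture, sliding interfaces, and hysteresis.
Passing tests therefore demonstrate correctness of the operators and the
estimation machinery under the stated noise model — not clinical
performance.

## Problem sizes used by the tests and the acceptance script

Runs are sized for a single CPU. Operator, model, and regularizer checks
use 8³–24³ grids where dense oracles are affordable (the SIRT oracle
materializes all twenty 256×512 system matrices). The parameter-recovery
study runs at 48³ with all 160 frames, a 48² detector, 8³ spatial control
points and 60 NAdam epochs, over three seeds; the end-to-end alternation
study runs at 48³ with 80 frames, 40 SIRT iterations, 30 epochs and 2
alternations. The ball-projection accuracy check uses a 192³
partial-volume ball and excludes rays whose impact parameter is within
4 mm of the rim, where the chord formula's unbounded derivative makes any
discretized comparison meaningless. The projector's surface-quantization
error is first-order in voxel size, which sets that exclusion.

## Known limitations

* The normalized push only approximates the inverse warp; its error grows
  with field amplitude (`compose_check()` is monotone in amplitude) and is
  unbounded in theory for strongly compressing fields.
* Motion in homogeneous regions is unidentifiable from projections alone;
  the regularizer interpolates it from encoded regions. The liver interior
  of the phantom shows this.
* The estimation is non-convex; different seeds give slightly different
  coefficient sets (the recovered *fields* agree — the gauge freedom
  absorbs the difference).
* Near gantry angles where the dominant motion is parallel to the rays,
  single-frame encoding is weak; the temporal spline carries the estimate
  through those angles.
* No scatter/ghosting correction and no polychromatic physics; helical or
  non-circular trajectories are out of scope.
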