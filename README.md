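# multitilt

Multi-tilt electron tomography for plastic-embedded specimens: simulation,
automatic fiducial alignment, deformation monitoring, and reconstruction.

## What problem this solves

Electron tomography reconstructs a 3D density map of a semi-thick specimen
section from projection micrographs collected over a ±60° tilt range. The
limited range leaves a *missing wedge* of Fourier space unsampled, which
elongates and smears every feature along the beam direction. Because
plastic-embedded, heavy-metal-stained sections tolerate accumulated dose
(damage tracks the dose *rate*), one can trade dose for sampling: rotate
the specimen azimuthally n times following a multilevel access scheme
(MAS) and record a full tilt series at each orientation — up to ~2000
views — shrinking the missing wedge to a missing pyramid and averaging
noise over many samplings of the same volume.

`multitilt` provides the computational pipeline for this acquisition
strategy, for microscopists and methods developers who want a desk-scale,
fully testable implementation:

* **simulate** — gold-bead phantoms, n-fold MAS tilt schemes, analytic
  micrograph rendering, dose-dependent specimen compression, seeded noise;
* **detect / track** — determinant-of-Hessian bead detection with subpixel
  refinement, and ray-clustering track building across all series;
* **align** — simultaneous multi-series bundle adjustment of polynomial
  projection maps $P_\omega$ and 3D bead positions $X_j$, minimizing
  $\sum_{j,\omega} \lVert P_\omega(X_j) - x_{j\omega}\rVert^2$;
* **deformation monitoring** — the per-micrograph indicator
  $n_{3}$ (cross-product norm of the map's linear-part rows; exactly 1 for
  an ideal rotation-projection) oscillates between a zero-tilt bound set by
  lateral compression and a high-tilt bound set by normal-axis compression,
  and a three-rate saturation model
  $s_A(i) = 1 - \gamma_A (1 - e^{-i/\tau})$ is fitted to it;
* **reconstruct** — Shepp–Logan filtered back-projection and a weighted
  SIRT (path-length row weighting, coverage column weighting, mixing
  parameter α = 2, 50 sweeps), built on an exactly adjoint
  projector/backprojector pair;
* **sampling** — the closed-form missing Fourier fraction
  $q(n) = \tfrac{n}{6}\tan(\tfrac{\pi}{2n})\,(\tfrac{L_z/L}{\tan\theta_\max})^2$
  with its conical limit, validated by a Monte-Carlo coverage oracle.

## Worked example

A 4-fold acquisition of 30 beads with compression rates
γ = (0.03, 0.03, 0.15) and τ = 61.5 micrographs, detection noise σ = 0.3:

```r
library(multitilt)

scheme <- tilt_scheme(4, tilt_step = 3, detector_shape = c(128L, 128L))
beads  <- random_phantom(30, extent = c(128, 128, 40), seed = 1)
sim <- simulate_tilt_series(beads, scheme,
         model = deformation_model(c(0.03, 0.03, 0.15), tau = 1.5 * 41),
         noise = list(gaussian_sigma = 0.3), seed = 1)

detections <- detect_beads_stack(sim$stacks, scheme, sigma = 2, threshold = 0.1)
tracks     <- build_tracks(detections, nominal_maps(scheme), scheme)
tracks
#> <marker_track_set> 30 tracks ( 30 usable ), 4782 observations
#>   rms reprojection residual: 0.5353 px

fit <- bundle_adjust(tracks, scheme)
glance(fit)
#> # A tibble: 1 x 7
#>   rms_residual n_obs n_beads n_maps order rounds converged
#>          <dbl> <int>   <int>  <int> <dbl>  <int> <lgl>
#> 1        0.172  4782      30    164     1    200 FALSE
```

All 30 beads are tracked through all 164 micrographs and the joint
alignment reaches a 0.17 px per-coordinate reprojection residual — the
detection-noise floor (the round cap, not the tolerance, ended the
alternation; the cost was flat). The aligned maps carry the deformation
record; fitting the three-rate model to their n3 series (with `reference`
pointing at the gauge-pinned micrograph, since aligned maps express
deformation relative to the pin time):

```r
dfit <- fit_deformation(n3_series(fit), scheme, reference = fit$gauge_i_omega)
tidy(dfit)
#> # A tibble: 4 x 3
#>   term    estimate std.error
#>   <chr>      <dbl>     <dbl>
#> 1 gamma_X   0.0638   0.0124
#> 2 gamma_Y   0        0.0133
#> 3 gamma_Z   0.216    0.00782
#> 4 tau      68.3      6.21
```

The monitor recovers the regime: a dominant normal-axis compression
(~15–20 %), lateral compression an order of magnitude smaller (the two
lateral rates are individually weakly identified from noisy alignment-based
n3 — the zero-tilt bound constrains mainly their sum, recovered here as
0.064 vs the generating 0.06), and the saturation constant 68 ± 6 against
the generating 61.5. Reconstruction then uses the aligned maps directly:

```r
spec <- volume_spec(c(128, 128, 40))
mic <- scheme$micrographs
images <- lapply(mic$i_omega, function(i) {
  s <- mic$series[i]; j <- which(mic$i_omega[mic$series == s] == i)
  sim$stacks[[s]][, , j]
})
vol <- fbp(images, fit$maps, spec)
vol
#> <mt_volume> 128 x 128 x 40 voxels at 1 nm; range [ -0.3579 , 1.038 ]
coefficient_of_variation(vol)
#> [1] 4.287018
autoplot(vol)                      # middle tomogram slice
write_volume(vol, "tomogram.mrc")
```

`wsirt(images, fit$maps, spec)` runs the weighted iterative reconstruction
(50 sweeps, α = 2) for lower bead-fringe artifacts at higher compute cost.
And the coverage arithmetic that motivates the whole design:

```r
missing_fraction_table()
#>       n missing_fraction missing_percent
#>   <dbl>            <dbl>           <dbl>
#> 1     1          NA                NA
#> 2     2           0.111            11.1
#> 3     4           0.0920            9.20
#> 4     8           0.0884            8.84
#> 5    16           0.0875            8.75
#> 6   Inf           0.0873            8.73
```

Going from 2 to 16 series shrinks the missing information only from 11.1 %
to 8.75 % — the real gain of many series is denser resampling and noise
averaging, not recovered Fourier content.

A thin command-line front end (`inst/cli/multitilt.R`) exposes the same
stages (`simulate`, `detect`, `track`, `align`, `deform-fit`, `recon-fbp`,
`recon-wsirt`, `cv`, `sampling`) over on-disk artifacts; see
`vignettes/multitilt-methods.Rmd` for the models, parameter meanings and
design decisions.

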