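---
title: "Multi-tilt electron tomography with multitilt: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Multi-tilt electron tomography with multitilt: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(multitilt)
```

## The problem

Electron tomography of plastic-embedded, heavy-metal-stained sections
reconstructs a 3D density map from projection micrographs taken at many
goniometer tilts. A single tilt series is limited to roughly ±60°, which
leaves a *missing wedge* of Fourier space unsampled and elongates every
feature along the beam axis. Because plastic sections tolerate dose (it is
the dose *rate* that damages them), one can instead collect an n-fold
multi-tilt acquisition: the specimen is rotated in the holder by a sequence
of azimuths and a full tilt series is recorded at each, turning the missing
wedge into a progressively smaller missing pyramid and averaging noise over
up to ~2000 views of the same volume.

`multitilt` implements the computational side of this strategy at desk
scale: a synthetic acquisition simulator, automatic gold-fiducial detection
and track building, simultaneous multi-series bundle adjustment with
monitoring of beam-induced specimen compression, filtered back-projection
(FBP) and weighted-SIRT (wSIRT) reconstruction, and a closed-form plus
Monte-Carlo analysis of Fourier-space coverage.

## Acquisition geometry

A `tilt_scheme(n_series)` enumerates micrographs series-major with a global
index $i_\omega$. Azimuths follow the multilevel access scheme (MAS): the
angles $k \cdot 180°/n$ are visited in bit-reversed order of $k$, so
successive tilt axes are maximally spread (for $n = 8$: 0°, 90°, 45°, 135°,
22.5°, 112.5°, 67.5°, 157.5°). The per-series tilt grid defaults to −60°
… +60° in 1° steps.

Coordinates are fixed once: the specimen frame is right-handed with Z along
the section normal and origin at the section centre; detector pixels are
0-based with (x, y) = (column, row); a view applies the azimuthal rotation
$R_z(\varphi)$ first, then the goniometer tilt $R_y(\theta)$ about the
*lab-frame* y axis, then projects along the beam. Because the specimen is
what rotates in the holder, the tilt axis is fixed along detector y in
every series; this matters for the ramp-filter direction below.

Each micrograph's registration is a **projection map**: a polynomial map
from 3D specimen coordinates to 2D detector coordinates, stored as two
coefficient rows over the 3-variable monomials in graded-lexicographic
order (4 coefficients per axis for the affine case $d = 1$, 10 for $d = 2$,
20 for $d = 3$). The affine order is the default throughout: the simulator's
ground truth is a rotation-projection composed with a diagonal compression,
which order 1 captures exactly. Higher orders are available as warm-started
refinement stages for distortion studies.

## The simulator defines the study conditions

`random_phantom()` deposits gold beads (default radius 3 nm at 1 nm/px) on
both faces of a slab, as colloidal gold sits on real sections, with a
minimum lateral separation of three radii (colloids do not interpenetrate)
over the central 80 % of the field so nothing clips at ±60°. The default
desk-scale geometry is a 256×256 px detector at 1 nm/px and a 60 nm-thick
slab; the 4k detector of a real acquisition enters only as metadata.

Beam-induced compression follows a three-rate exponential-saturation model:
the per-axis scale after $i$ micrographs is

$$ s_A(i) = 1 - \gamma_A \left(1 - e^{-i/\tau}\right), \qquad A \in \{X, Y, Z\}, $$

with defaults $\gamma = (0.03, 0.03, 0.15)$ — a few percent laterally and
15 % along the normal, the regime reported for irradiated epoxy sections —
and $\tau$ = 1.5 series lengths, which puts the transient inside the first
series and reaches the stationary state after 3–4 series. The scaling is
composed into the ground-truth projection maps, which is equivalent to
warping the specimen and letting the per-micrograph maps absorb it.

Micrographs store density line integrals (bright = dense; display inversion
is a viewer concern, and the convention keeps all reconstruction algebra
sign-free). Bead footprints are rendered analytically as projected-sphere
chord-length profiles with 4×4 subpixel quadrature, so the integrated
density of a bead is conserved across tilts to 0.1 % and detector tests
have subpixel-exact ground truth. Noise is optional Poisson on expected
counts plus additive Gaussian read noise; the reference papers in this
field rarely state their noise statistics, so these defaults are a
configuration choice, not a claim. Everything is deterministic given the
seed.

What the simulator does *not* emulate: electron optics (defocus, CTF,
energy filtering), curvilinear trajectories, charging, or structured
biological background. Passing tests therefore demonstrate the correctness
of the geometry, alignment and reconstruction machinery under the stated
deformation and noise models — not robustness to optical distortions, for
which the polynomial map orders above 1 are the intended hook.

## Fiducial detection and track building

`detect_beads()` uses a second-order Gaussian-derivative blob detector: the
scale-normalized determinant of the Hessian,
$\sigma^4 (L_{xx} L_{yy} - L_{xy}^2)$, evaluated at a single scale matched
to the bead radius ($\sigma \approx r/\sqrt{2}$), with the Laplacian sign
selecting bright or dark polarity and a quadratic 3×3 fit refining maxima
to subpixel positions. The determinant rather than the Laplacian was chosen
because it suppresses elongated edge responses; response plateaus from
exact symmetry keep their first pixel in column-major order so detection is
deterministic.

`build_tracks()` turns per-micrograph detections into bead identities, a
cluster analysis over back-projected rays:

1. **Seeding.** In each series, detections in a low-tilt anchor micrograph
   are paired with detections in a partner ~30° away; ray pairs whose
   closest approach is within twice the match radius triangulate candidate
   3D positions, deduplicated at the match radius.
2. **Greedy growth.** Candidates are reprojected into every micrograph and
   detections join the nearest candidate within `match_radius` (5 px
   default), globally ordered by ascending reprojection distance with ties
   broken by ascending $i_\omega$; each detection is used at most once and
   each track holds at most one detection per micrograph.
3. **Refinement.** Tracks are re-triangulated by least squares; between
   growth passes a per-micrograph offset (the median matched residual
   vector — systematic initial-map error is shared by all detections of a
   micrograph) is folded into the ray geometry, which is what makes growth
   robust to a few pixels of initial misalignment. Leftover detections
   re-seed new candidates for up to three rounds; near-duplicate candidates
   with complementary observation sets (the signature of a split track, as
   opposed to a genuinely close bead pair, which conflicts in nearly every
   view) are merged.

Unassigned detections remain singleton tracks; tracks shorter than
`min_track_length` (10) are excluded from alignment, where they would
destabilize the normal equations. `merge_tracks_across_series()` fuses
per-series track sets by 3D agreement — all series share one specimen frame
through the azimuths in their maps — with union-find semantics, so a merge
radius of zero degenerates to concatenation.

## Bundle adjustment

`bundle_adjust()` minimizes the total squared reprojection error

$$ \sum_{j,\omega} \left\lVert P_\omega(X_j) - x_{j\omega} \right\rVert^2 $$

jointly over all per-micrograph maps $P_\omega$ and 3D bead positions
$X_j$, handling all series simultaneously. The solver is block alternation:
given positions, each map is an independent linear least-squares problem (a
polynomial map is linear in its coefficients, accumulated here via
per-micrograph normal equations); given maps, each bead is an independent
3-unknown problem, exactly linear for affine maps and Gauss–Newton
otherwise. Rounds continue until the relative cost change drops below
1e−10 or 200 rounds. Alternation was chosen over a monolithic sparse
Levenberg–Marquardt because every subproblem is closed-form and separately
testable; its price is slow convergence along gauge-coupled global modes,
which is invisible at the noise floor but means exact (noiseless) recovery
to machine precision is only reached when the initialization is consistent
with the ground-truth gauge. Bead positions are initialized by
triangulating from the earliest third of series 1 — the lowest-dose,
least-deformed views — rather than from all observations: positions are
defined in the (nearly) pristine specimen state, and an all-view
triangulation would average over the deformation trajectory and leave the
solver a slowly-converging global mode that visibly distorts the n3
monitor described below.

Marker-based alignment leaves a global affine transform undetermined
(compose every map with $G$ and every position with $G^{-1}$ and nothing
observable changes). The gauge is fixed by pinning the zero-tilt map of
series 1 to its initial nominal value, the simplest testable convention; it
is recorded in the result's `gauge` field. The reported `rms_residual` is
the per-coordinate root mean square, $\sqrt{\tfrac{1}{2n}\sum \lVert r
\rVert^2}$, so that for i.i.d. Gaussian detection noise of width $\sigma$
it should approach $\sigma \sqrt{1 - p/N}$ with $p$ the parameter count and
$N$ the residual count — the calibration check used in the tests. Optional
Huber weighting (δ = 3×MAD) is available for outlier-contaminated
detections and off by default so the least-squares oracles stay exact.

`iterative_refine()` alternates track building (with the current maps) and
bundle adjustment until the assignment partition stops changing, with a
ten-cycle cap.

## Deformation monitoring: the n3 indicator

For each aligned map, `n3()` is the Euclidean norm of the cross product of
the two rows of the linear part, after normalizing out the pixel scale. A
pure rotation-projection has orthonormal rows and $n_3 = 1$ identically;
composing a diagonal compression $\mathrm{diag}(s_X, s_Y, s_Z)$ gives

$$ n_3 = \left\lVert \det(S)\, S^{-1} r_3 \right\rVert
  = \sqrt{(s_Y s_Z \sin\theta \cos\varphi)^2 +
          (s_X s_Z \sin\theta \sin\varphi)^2 +
          (s_X s_Y \cos\theta)^2}, $$

where $r_3$ is the beam row of the view rotation. At zero tilt $n_3 = s_X
s_Y$ (lateral compressions only); at high tilt the normal-axis factor
$s_Z$ dominates. Along an acquisition the indicator therefore oscillates
with one period per tilt series between an upper bound set by the lateral
rates and a lower bound set by the normal rate — a deformation monitor read
directly off the alignment, with no extra measurements.

`fit_deformation()` fits $(\gamma_X, \gamma_Y, \gamma_Z, \tau)$ to an
observed $n_3$ series by bounded Levenberg–Marquardt on this closed form,
multi-started over $\tau \in \{0.5, 1, 2, 4\}$ series lengths, with
asymptotic standard errors from the numerically differentiated Jacobian.
At least two series are required: a single series constrains the laterals
only through their product at zero tilt, while the azimuth rotation mixes
$s_X$ and $s_Y$ into the high-tilt bound and separates them. The fit
operates on $n_3$ only rather than on full map elements — a smaller,
better-conditioned problem.

One gauge subtlety: maps from [the bundle adjustment] are pinned to the
nominal zero-tilt map of series 1, so they express deformation *relative to
the pin-time state* — the $n_3$ series of an alignment starts above its
stationary band. Passing the pin index as `reference` makes the fit divide
the model scales by $s_A(i_\text{ref})$, so the recovered rates refer to
the pristine specimen; ground-truth $n_3$ series use the absolute default.

## Reconstruction

The projector pair is voxel-driven: `reproject()` pushes every voxel
through its map and splats it bilinearly into the detector with quadrature
weight voxel-volume / pixel-area (the $1/\cos$ obliquity of the line
integral arises automatically from voxel crowding under the in-plane
Jacobian, so it is not applied twice), and `backproject()` is the exact
transpose — identical weights and inclusion tests — so
$\langle A x, y\rangle = \langle x, A^{\mathsf T} y\rangle$ holds to
machine precision. That adjointness is the structural gate for the
iterative method. Straight rays are used for affine maps; maps of order
> 1 simply evaluate the polynomial per voxel, so bent rays emerge naturally
(flagged experimental).

**FBP.** Each micrograph is convolved (FFT, zero-padded to the next power
of two at least twice the width) with the discrete Shepp–Logan kernel
$2 / (\pi^2 (1 - 4k^2))$ or the Ram-Lak kernel, along the detector
direction perpendicular to the projected tilt axis — with this package's
acquisition convention, along detector x. Backprojection weight is
$\pi / n_\text{micrographs}$, keeping reconstructions from different series
counts on one density scale. Coverage maps are attached rather than divided
out by default, so edge behaviour stays visible.

**wSIRT.** The weighted iterative method starts from a zero volume and, per
sweep, visits every micrograph in a bit-reversed (MAS-style) order — the
same maximal-spreading idea as the acquisition itself, applied to the
update sequence — and applies

$$ x \leftarrow x + \tfrac{\alpha}{2}\, C_\omega B^{\mathsf T}_\omega
   R_\omega \left(v_\omega - P_\omega x\right), $$

where $R_\omega$ divides each ray residual by that ray's path length
through the volume and $C_\omega$ divides each voxel by its ray coverage
(the column sums of the weighted projector) — the weighting along
trajectory paths. The correction is normalized so that the reference
operating point $\alpha = 2$ applies exactly the unit-relaxation weighted
correction; the scheme is stable for $\alpha \in (0, 4)$, and a residual
that grows for five consecutive sweeps aborts with the history attached.
Design note: a fully simultaneous update with these weightings either
destabilizes (count-based column normalization) or stalls on marginal
modes at relaxation 2 and converges an order of magnitude more slowly; the
block-sequential form reproduces the intended operating point — monotone
decay and a relative projection residual below $5\times10^{-3}$ within 50
sweeps on consistent two-series data at the 64×64×24 test scale — which is
why it is the implemented interpretation. The per-sweep relative residual
$\lVert v - v_i \rVert / \lVert v \rVert$ is recorded in
`residual_history`.

`coefficient_of_variation()` (std/mean of the middle slice) is the
convergence metric used to watch reconstructions stabilize as series
accumulate: missing-wedge fringes inflate apparent contrast, so the metric
falls as artifacts attenuate and plateaus once orientation space is
effectively sampled (around $N = 8$ on the synthetic phantom).
`bead_psf_fwhm()` (z/x width ratio of a reconstructed point bead) and
`bead_fringe_energy()` (normalized squared intensity in an annulus around
beads) quantify the elongation and white-fringe artifacts that the
additional series and the iterative weighting suppress. One subtlety worth
stating: the half-maximum core width along z is set by the tilt range
alone — the z extent of the covered Fourier region does not grow with the
number of series, and the coverage analysis below shows how little the
missing fraction itself shrinks past two series — so the progression with
series count is measured at a tail-sensitive amplitude level (`level =
0.2`), which is where the shrinking missing pyramid actually lives.

## Fourier-space coverage

For an n-fold scheme with maximum tilt $\theta_\text{max}$ on a slab of
aspect $L_z/L$, the unsampled ("missing pyramid") fraction of Fourier-space
information is, for $n$ a power of two, $L_z < L$ and
$\theta_\text{max} > 45°$:

$$ q(n) = \frac{n}{6} \tan\!\left(\frac{\pi}{2n}\right)
   \left(\frac{L_z/L}{\tan\theta_\text{max}}\right)^2
   \;\xrightarrow{\;n\to\infty\;}\;
   \frac{\pi}{12}\left(\frac{L_z/L}{\tan\theta_\text{max}}\right)^2 . $$

`missing_fraction()` implements this; `monte_carlo_missing_fraction()` is
an independent geometric oracle that samples the Fourier box
$[-1,1]^2 \times [-L_z/L,\, L_z/L]$ uniformly and tests membership in the
union of the $n$ double wedges
$|k_z| \le \tan\theta_\text{max}\, |k_{xy} \cdot w_j|$ (in-plane normals
spaced $\pi/n$). Integrating this geometry analytically reproduces the
closed form exactly — the lateral domain must be the square detector box, a
disc gives a $4/\pi$ mismatch — which pins the convention; the two routes
agree within binomial error in the tests. The numbers are sobering and
motivate the whole design: at aspect 1 and 60°, doubling from 2 to 16
series only shrinks the missing fraction from 11.1 % to 8.75 % (conical
limit 8.73 %) — the gain of many series is *resampling and averaging*, not
the removal of missing data. The companion rule
$\Delta\theta = (2/L) \cdot 180°/\pi$ shows a 4k detector would nominally
need 0.03° tilt steps, far below practical increments, so the discretization
gap is real and more orientations are the only remedy.

## Numerical choices and limitations

* Tie-breaks are fixed everywhere (column-major plateau pixels in
  detection, ascending distance then ascending $i_\omega$ in track growth),
  and all stochastic stages take explicit seeds, so identical inputs give
  bit-identical outputs.
* Degenerate inputs are handled explicitly: zero-tilt-only triangulations
  are ridge-regularized toward the section plane, collinear map rows raise
  a degenerate-geometry error, empty images yield empty detection tables,
  a zero-mean slice makes the coefficient of variation an error rather
  than a number.
* Problem sizes in the tests are the package's desk-scale choices:
  alignment is exercised at the full 16×121-view, 100-bead geometry
  (tracks only — no images needed), while image-space stages use 48–128 px
  detectors, 3–5° tilt steps and 64×64×24-voxel grids, which keep each
  stage in seconds to a few minutes on one core while preserving every
  geometric property being tested.
* The eucentricity bookkeeping of a real microscope, CTF/optics
  correction, marker-free alignment and GPU execution are out of scope;
  the alignment-feedback-inside-wSIRT refinement (using systematic
  patterns in the projection residuals to re-correct the maps during
  iterations) is a natural extension hook but is not implemented.

## A worked desk-scale run

```{r pipeline, eval = FALSE}
library(multitilt)

cfg <- run_config(n_series = 4, tilt_step = 3, n_beads = 30,
                  detector_nx = 128, detector_ny = 128, thickness = 40,
                  recon_nx = 128, recon_ny = 128, recon_nz = 40, seed = 1)
out <- run_pipeline(cfg, dir = "run4",
                    stages = c("simulate", "detect", "track", "align",
                               "deform_fit", "recon_fbp", "cv"))
out$align$rms_residual     # px, near the detection noise floor
out$deform_fit$gamma_Z     # recovered normal-axis compression rate

maps <- read_projection_maps(file.path("run4", "aligned_maps.txt"))
scheme <- tilt_scheme(4, tilt_step = 3, detector_shape = c(128L, 128L))
pin <- with(scheme$micrographs[scheme$micrographs$series == 1, ],
            i_omega[which.min(abs(tilt_deg))])
autoplot(fit_deformation(n3_series(maps), scheme, reference = pin))
```

The same stages are scriptable from a shell through
`inst/cli/multitilt.R`, each stage reading and writing only on-disk
artifacts (MRC stacks, projection-map text files, CSV tables), so any step
can be re-run or replaced independently.
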