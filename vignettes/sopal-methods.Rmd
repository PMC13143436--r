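---
title: "Stereoscopic optical palpation: models and numerical methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Stereoscopic optical palpation: models and numerical methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The measurement principle

Stereoscopic optical palpation (SOP) maps the mechanical stress at the
surface of soft tissue by imaging the compression of a compliant silicone
sensing layer placed between the tissue and a rigid imaging window. The
layer (5 mm thick, Young's modulus around 17 kPa) carries a plane of
phosphorescent microparticles on its tissue-facing surface. Two parallel
cameras behind the window view this particle plane; the lateral offset
(disparity) of a particle between the two rectified views is inversely
proportional to its optical distance,

  z = b f / (x_L − x_R),

with baseline `b` and focal length `f`. Stiffer regions beneath the layer
deform it more, bringing the particle plane closer to the window, so a
disparity map becomes a layer-thickness map `d(x, y)`, then a bulk
engineering strain map

  eps_E = (L0 − d) / L0,

and finally a stress map through the layer's pre-characterized uniaxial
stress-strain response. `sopal` implements this chain end to end, a forward
simulator that renders synthetic stereo frames of deforming layers, a
large-deformation finite-element (FE) inversion ("computational optical
palpation"), and the image-quality metrics used to compare the two stress
reconstruction methods on a stiff-inclusion phantom.

## Synthetic scenes and the effective camera model

`make_particle_field()` draws a Poisson-count random particle field over the
19 mm layer disc (default 150 particles/mm², chosen so a 35-pixel matching
window contains roughly ten blobs — a richly featured speckle pattern).
`render_stereo_pair()` projects each particle through two ideal rectified
pinholes and splats isotropic Gaussian blobs (default sigma 2 px) on a 2x
supersampled grid that is box-averaged down, followed by optional additive
Gaussian noise and 8-bit quantization. The blob width matters: at sigma
near 1 px the quadratic sub-pixel refinement of the matcher suffers strong
pixel locking (disparity scatter of 0.2-0.3 px), while sigma = 2 px keeps
the flat-scene scatter well below 0.05 px; the default reflects that
measurement, and emulates defocused sub-30 um particles at the default
pixel scale (~8.9 um/px).

The camera geometry is an *effective* model. The physical probe places the
camera plane about 16 mm behind the window, but the optical distance in the
stereoscopy relation accumulates the camera module's internal optics and
refraction through window and layer, which the real instrument never
measures separately — it calibrates disparity against thickness
empirically. An ideal pinhole at a 16 mm object distance would make
disparity visibly nonlinear in thickness over the 0-4 mm calibration range
(reciprocal curvature worth ~0.09 mm RMS against a linear fit), which no
linear per-pixel calibration could absorb. The default rig therefore uses
an effective contact distance of 120 mm with a 13800 px focal length: the
lateral scale (~115 px/mm) matches the probe's field of view while the
disparity-thickness relation is linear to better than 0.02 mm over the
calibration range. `nominal_working_distance_mm` is retained as descriptive
metadata, and all geometry parameters are configurable. The overlap
field-of-view anchors (8.9 x 6.9 mm² at contact, 10.7 x 8.4 mm² at 4 mm)
are stored as empirical anchor values in the calibration model — a single
ideal pinhole cannot reproduce both printed anchors on both axes, so they
are data, not derived geometry.

## Disparity matching and calibration

`match_disparity()` evaluates, for every processed left-image pixel, a
normalized least-squares cost between a circular window (default 35 px
diameter) and candidate windows along the same row of the right image. The
normalization is zero-mean SSD scaled by the window norms — algebraically
`2(1 − ZNCC)` — making the cost invariant to affine intensity changes;
plain SSD over window energy is available behind a switch. The integer
minimum (ties broken toward smaller disparity) is refined by the vertex of
the parabola through the three neighbouring costs, clamped to (−1, 1);
boundary minima, constant windows and out-of-frame windows are masked.
Live mode processes every second pixel with a 17 px window.

`fit_disparity_thickness()` fits an ordinary least-squares line of
disparity versus thickness at every pixel of a flat-plane calibration stack
(default thicknesses 0-4 mm including the contact point). Per-pixel fits
absorb tilt between camera plane and window, which the test-suite verifies
by round-tripping a stack rendered with a 1 degree tilted plane.
`thickness_from_disparity()` inverts the lines, clamping to
[0, L0 + 0.1 mm] and flagging pixels beyond the tolerance. The
field-of-view scale model is linear in the image-mean thickness between the
two anchors.

## Layer mechanics

The layer is Neo-Hookean. Under the compressive-positive convention used
throughout (strain and stress reported as positive magnitudes in
compression), the incompressible uniaxial law is

  sigma_E = 2 C10 (1/lambda² − lambda),   lambda = 1 − eps_E,

with small-strain modulus E = 6 C10. The default C10 = 2.83 kPa encodes the
layer silicone's ~17 kPa modulus via that small-strain relation; reading
the quoted value instead as a tangent modulus at 10% strain would give
C10 ≈ 2.27 kPa, a defensible alternative within the material's stated
tolerance. `fit_neo_hookean()` fits C10 (linear least squares on
engineering stress — the law is linear in C10) to a uniaxial table; since
no tabulated layer data ships with the probe, a synthetic table generator
is the default fixture.

Stress maps are *presented* as true stress via

  sigma_T = sigma_E (1 + eps_E),

applied identically to both reconstruction methods. This is a display
convention: the algebraic chain applies it to its engineering stress, and
the computational map converts its Cauchy interface stress to the
engineering measure through the measured bulk strain
(sigma_E = sigma_C / lambda) before applying the same factor. A single
shared convention is what makes the two maps comparable pixel by pixel; in
the homogeneous frictionless limit they then coincide up to the
near-incompressibility error of the FE material (about 0.6% at nu = 0.49),
which the test suite checks against a 1% bound. The raw Cauchy profile is
always retained alongside the presented map.

## The finite-element solver

Computational optical palpation replaces the uniaxial, frictionless,
depth-uniform stress assumption of the algebraic chain with an FE
simulation: the layer is compressed between the rigid window and a sample
surface moved to the measured position, and the true (Cauchy) stress where
the layer meets the sample is extracted.

The solver is a total-Lagrangian large-deformation Neo-Hookean code on
bilinear quadrilaterals, axisymmetric or plane strain. The discrete energy
splits into an isochoric term `C10 (J^{-2/3} I1 − 3)` integrated at the
2x2 Gauss points and a volumetric penalty `K/2 (J − 1)²` evaluated at the
element centroid (a mean-dilatation, B-bar-type selective treatment that
prevents volumetric locking of fully integrated quads near
incompressibility). The bulk modulus follows nu = 0.49 by default; the
penalty keeps |J − 1| below 3% in homogeneous compression. The residual is
the exact analytic gradient of this discrete energy; the consistent tangent
is obtained by central finite differences of those analytic Gauss-point
gradients (machine-accurate at step 1e-6, so Newton retains quadratic
convergence while eliminating an entire class of hand-derived-tangent
bugs). A property test verifies the residual against a finite-difference
gradient of the scalar energy.

Meshes are structured tensor grids; the interface element size defaults to
0.2 mm (0.15 mm in the benchmark pipeline, refined to 0.1 mm within 2.5 mm
of the axis where the inclusion stress peak lives) and elements are built
taller by 1/(1 − 0.4) so they approach unit aspect ratio after the
expected 40% compression. Loading is incremental
(20 equal displacement increments by default) with Newton iteration, a
backtracking line search that rejects element-inverting or
residual-increasing steps, adaptive increment halving down to 1/64 of the
base increment, and one automatic retry at a doubled increment count. The
deep halving floor and line search are what carry the solver through the
strongly distorted region at the inclusion-edge stress cliff, where local
Jacobians drop to ~0.3.

### Contact and friction

The window side is held by a bilateral rigid-plane condition (normal
displacement fixed); the sample side is driven to the measured position
with the normal component prescribed. Tangentially, both surfaces follow a
regularized Coulomb law

  t = −mu p tanh(u_t / s_el),

with mu = 0.2 (a lubricated layer), the nodal normal pressure `p` lagged
from the previously converged increment (the first increment is
frictionless), and a fixed elastic-slip distance s_el = 0.05 mm (1% of the
layer thickness). An earlier element-size-proportional stick stiffness was
abandoned: it made the regularized friction state mesh-dependent, shifting
the friction hill across the whole contact by several percent under mesh
halving. After the final increment the solver re-equilibrates with the
contact pressure updated from the current state until it stabilizes, so
the converged state is as schedule-independent as the regularization
allows. Genuine Coulomb friction is path-dependent physics: a few percent
of friction-state indeterminacy remains in the far-field interface stress
between different increment schedules, while region-mean quantities such
as the stress contrast are stable at the ~1% level. Whether both
displacement components of the sample surface should be prescribed is left
configurable (`tangential = "prescribed"`); the default prescribes the
normal component only, since only that is measurable.

### Forward phantom model

`phantom_forward_model()` builds the ground truth for the in-silico
benchmark: an axisymmetric two-material (plus inclusion) conforming mesh of
the layer on the phantom, compressed by the rigid window until the layer's
area-mean strain reaches the target (secant iteration on the window
displacement, tolerance 2%). The phantom base is bonded to its support
plate. The layer-phantom interface is bonded by default. A lubricated
frictional interface (duplicated nodes, stiff normal penalty tie, pair-wise
Coulomb slip) is implemented as an option, but it predicts partial
lift-off of the layer around the inclusion — an annulus of near-zero
contact pressure — which the bilateral node-to-node tie cannot represent
faithfully (it admits no true separation), so the bonded interface is the
default study condition. The domain is truncated at the layer radius
(9.5 mm); the inclusion edge sits ~9 mm from the lateral boundary, far
beyond the layer-thickness coupling scale.

The forward/inverse pair is validated by an inverse-consistency check:
feeding the forward model's exact interface displacement (both components,
on an independently built layer mesh whose interface nodes are aligned
with the forward profile samples) through `solve_layer_compression()`
recovers the forward interface stress within the test suite's 5% pointwise
bound away from the lateral edge.

## The in-silico benchmark

`run_benchmark()` replays the phantom experiment fully in simulation: the
forward model (0.8 mm diameter x 2 mm stiff inclusion, ~900 kPa, 0.3 mm
below the surface of a ~15 kPa background, under the 5 mm ~17 kPa layer at
40% mean strain) provides the deformed particle geometry; noiseless stereo
frames and a flat-plane calibration stack are rendered; the measurement
chain runs both stress reconstructions; and `metrics_report()` computes
the stress contrast (3x3-pixel center mean over a background annulus at
2-3 inclusion radii) and the stress resolution (FWHM of the peak-normalized
lateral gradient of the center-to-background profile, half-maximum
crossings located by linear interpolation).

Two processing choices matter here. First, the FE inversion amplifies
pixel-scale thickness noise at the interface into large spurious stress
variation — the method's known noise sensitivity — so the measured radial
profile is smoothed with a count-weighted Gaussian kernel (bandwidth half
an element) before driving the solver. Second, metric profiles are taken
as annular averages around the center (identical to a line profile for a
noise-free axisymmetric map) lightly smoothed at 1.5 px, so the
gradient-based resolution measures the stress edge rather than pixel
noise. The processed region is a 8 x 2.6 mm rectangle around the
inclusion (about 920 x 300 px), which covers the metric regions and the
radial profile while keeping the per-pixel matcher affordable.

What passing the benchmark does and does not show: the synthetic scenes
share the real probe's geometry, speckle statistics, quantization and
mechanics, but not lens distortion or rectification residuals, tissue
texture under white light, LED reflection artifacts, surface roughness, or
acquisition noise (the benchmark renders noiselessly by design). A
noiseless replica therefore gives a *cleaner* algebraic baseline than the
physical experiment; the computational method's contrast is bounded by the
forward ground truth, so the *relative* contrast improvement of the
computational method over the algebraic one is structurally smaller in
silico than on the physical phantom, even when both absolute contrasts
meet their experimental values. The benchmark reports both methods'
absolute metrics alongside the forward-model ground truth for exactly this
reason.

## Numerical choices and degenerate inputs

- Ties at the integer cost minimum break toward the smaller disparity;
  window-exiting and zero-variance windows are masked, never padded.
- A numerically exact integer match (cost below 1e-9) short-circuits the
  quadratic refinement to a zero offset.
- Thickness clamping beyond 0.1 mm outside [0, L0] flags and invalidates
  the pixel rather than silently clamping.
- Negative strains (thickness above L0) are flagged and masked.
- Zero calibration slope invalidates the pixel; fewer than two distinct
  stack thicknesses is an error.
- Plane-strain mode pins the lateral rigid-body mode at the mid-width
  sample node when friction alone cannot anchor it (zero pressure at the
  first increment).
- Solver failures raise a typed condition carrying the full convergence
  history; in the row-wise plane-strain map a failed row is masked and the
  map assembled from the remaining rows.

## Problem sizes

The default test-suite and benchmark sizes are chosen for single-CPU runs:
a 420 x 260 px test rig with ~2800 particles for matcher and calibration
properties; FE meshes between ~100 and ~3500 elements; the benchmark at
the full 1800 x 936 px rig with a 920 x 300 px processed region,
0.15/0.1 mm FE meshes and 20-40 load increments. The complete benchmark
runs in a few minutes on one CPU.

## Known limitations

- The effective pinhole geometry reproduces the probe's pixel scale and
  calibration linearity, not its exact optical path; absolute field-of-view
  anchors are empirical inputs.
- The axisymmetric inversion is exact only for centered cylindrically
  symmetric scenes; the row-wise plane-strain mode ignores cross-row
  coupling and overestimates confinement.
- The frictional layer-phantom interface option cannot represent contact
  separation (bilateral tie); scenes that bridge or lift off are outside
  its validity.
- Regularized Coulomb friction leaves a few percent of path/schedule
  indeterminacy in far-field interface stress — inherent to quasi-static
  friction, not a convergence defect; contrast-type metrics are far less
  sensitive.
- The interface stress peak over a sub-millimetre inclusion converges
  slowly with mesh size (the peak sharpens under refinement); reported
  computational contrasts at the default meshes are conservative
  (under-resolved) estimates.
- The FE-recovered stress edge in a noiseless simulation can be sharper
  than any physically measured one; resolution numbers from the benchmark
  characterize the pipeline, not the instrument's optical limits.
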