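---
title: "Measuring posterior scleral deformation under optic-nerve tethering: models, parameters and numerical choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Measuring posterior scleral deformation under optic-nerve tethering}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The problem

In large adduction the optic nerve (ON) exhausts its slack and tethers the
globe: the straightened nerve and its sheath pull on the scleral insertion,
deforming the posterior eye wall. The deformations are focal — confined to
a millimetre or two around the ON sheath — and therefore invisible to
whole-globe imaging, while the exterior posterior sclera cannot be imaged
at high resolution in vivo at all. The measurement strategy implemented
here is the ex vivo one: speckle the posterior sclera, image it with
calibrated camera pairs before and after loading (incremental adduction
from the tethering threshold, or intraocular pressure elevation),
reconstruct the surface by stereo digital image correlation (3D-DIC), and
quantify deformation as per-triangle **surface area ratios** (loaded area /
reference area) rather than surface strain. The strain route is
deliberately avoided: surface strain from DIC assumes negligible thickness
change, and compressive tether loading violates that assumption. A ratio
below one is local compression, above one local expansion.

`scleradic` implements this chain end to end — synthetic scene generation,
DLT calibration and triangulation, subset correlation, meshing and
area-ratio regionalization — plus the supporting adduction kinematics and
the uniaxial tensile analysis (tangent moduli, toe-region detection,
reduced-polynomial hyperelastic representation) used to parameterize
eye-specific finite-element models. The finite-element solve itself is out
of scope; FEM surface exports (nodes + connectivity, before/after loading)
are post-processed with the same area-ratio operation as DIC surfaces, so
simulation and measurement are compared with one metric.

## The synthetic-data generator

Every stage is testable without experimental data because the generator
renders speckled surfaces through ideal pinhole cameras with exact ground
truth.

**Scene.** A sphere of radius 12 mm (the schematic emmetropic globe)
centred at the origin, posterior pole toward +z, nasal direction +x,
superior +y. The ON sheath occupies a polar cap bounded at
`asin(sheath_radius / globe_radius)`; the default sheath outer radius of
3.2 mm sits mid-range of the cadaver specimens (2.81–3.65 mm). Speckles
are anti-aliased Gaussian dots scattered uniformly over a 35° cap —
emulating iron-dust speckling — at 40 dots/mm² with 0.05 mm mean radius.
These two values are not stated in the source protocol; they were chosen
once so that a default 17–21 px correlation subset contains roughly 10–20
dots (enough texture for stable matching) and are fixed throughout. Images
are quantized to 16-bit levels; additive Gaussian sensor noise (default SD
0.005 on a 0–1 scale) is applied per image.

**Cameras.** Two pinhole cameras 112 mm from the globe centre, ±10° about
the pole axis, 3000 px focal length, 640×640 px — about 30 px/mm on the
surface. This is a scaled-down stand-in for a DSLR pair; lens distortion
is not simulated (the physical lenses showed 0.2% pincushion, which the
source protocol also ignored).

**Deformations.** Three families with analytic ground truth:

* rigid translation — every face area ratio is exactly 1;
* inflation by k about the globe centre — every ratio is exactly k²;
* tether — a tangential displacement along meridians toward the sheath
  margin, `u(s) = -A s (1-(s/S)^2)^2 w(alpha)` for arc distance `s` from
  the margin, with compact support `S = 2 * decay_mm` and a compact
  azimuthal window `w` centred on the nasal direction. The field is
  continuous (u(0) = u(S) = 0) and exactly zero beyond `2 * decay_mm`,
  matching the observation that adduction deformation is confined to
  within 2 mm of the sheath. The amplitude A is calibrated at scene-build
  time by root finding so that the mean ground-truth face ratio over the
  nasal 30° sector within 1 mm of the margin equals `nasal_ratio`
  (default 0.977, the reported adduction effect). A side effect of
  compact support is a mild expansion ring between 1 and 2 mm; the real
  tissue shows a milder version of the same return to unity.

**Tensile curves.** Stress follows `scale * (strain/breakpoint)^gamma`
with exponent `gamma_low` below the breakpoint and `gamma_high` above it,
so the log–log transform is exactly piecewise linear with a controlled
transition. The sheath-like defaults — breakpoint 0.034, scale 0.037 MPa,
exponents 1.2 / 1.7 — were calibrated once so the curve reproduces the
tissue's reported tangent moduli (≈1.3 MPa at 3% strain, ≈3.0 MPa at 7%)
together with the 3.4% toe transition. Noise is multiplicative on stress
only (default 2% relative SD). With equal exponents the curve degenerates
to a single power law, which the bilinear fit flags.

**What the generator does not emulate.** Real speckle is non-Gaussian and
can flake; real scleral surfaces are aspheric with thickness variation;
real deformations include out-of-plane bulging and are not axisymmetric in
azimuth; occlusion by the gripper removes the inferior sector entirely.
Passing the synthetic recovery tests therefore demonstrates correctness of
the algorithms and their error budget under idealized imaging, not
robustness to every pathology of cadaver data.

## Calibration and triangulation

Each camera is calibrated with the classic 11-parameter direct linear
transformation against a cylindrical target (default diameter 25.4 mm,
comparable to the eye) carrying a rings-by-columns feature grid. The
homogeneous least-squares system is solved after Hartley-style coordinate
normalization (centring and isotropic scaling of both point sets) for
conditioning; coplanar or otherwise deficient targets abort with a
condition-number diagnostic. Three-dimensional points come from linear
two-view intersection of the four DLT ray equations — no bundle
adjustment, keeping every step checkable against closed-form oracles. The
per-point residual (RMS reprojection over both views) is the
match-rejection statistic; the pipeline default rejects above 1 px.

Pair-level validation triangulates the calibration features back and
reports the RMS Euclidean 3D error in mm ("mean squared error" figures for
such rigs are read as RMS lengths here). Because a displacement is the
difference of two independently reconstructed positions, its RMS error is
the per-point error times √2 — a 10 µm point error yields a 14.1 µm
displacement error; `propagate_displacement_error()` is exactly that
factor and is verified against a 10⁵-draw sampling experiment.

## Subset correlation

`correlate()` implements subset DIC: zero-normalized cross-correlation
(ZNCC) over an integer search window, then Gauss–Newton refinement of the
zero-normalized SSD with bilinear interpolation, giving subpixel accuracy
of a few hundredths of a pixel on synthetic shifts. ZNCC makes scores and
matches invariant to per-image gain and offset. Matches are never dropped
silently: low contrast (subset SD below 0.01), search-window edge, and
sub-cutoff scores each carry a reason code.

Cross-camera (stereo) matching adds two things. First, a seed-and-grow
strategy: the grid point nearest the ROI centroid is matched with a wide
window (default ±80 px), and matches propagate outward initialized from
the nearest matched neighbour with a narrow window (±8 px), which absorbs
the large smoothly varying disparity of a curved surface. Second, a
6-parameter **affine subset warp** refined after the translation stage:
between cameras 20° apart the perspective distortion of a flat subset is
what limits a translation-only model (it depresses scores to ~0.6–0.8 and
biases centres by tens of micrometres); with the affine warp cross-camera
scores return to ≥0.95 and the median 3D reconstruction error on the
synthetic sphere drops to ~4 µm. If the affine iteration diverges the
translation solution is kept.

Defaults — 21 px subsets on a 5 px grid, ZNCC cutoff 0.8 for both temporal
and stereo matching — are desk-scale engineering choices, configurable in
`dic_params()`; the source protocol inherited all of them from external
DIC software without stating values. The ROI is a polygon (with optional
exclusion polygon), mirroring manual ROI selection.

## Surfaces, area ratios and regions

Matched grid points are triangulated per state and meshed once on a 2D
parameterization of the reference state (the camera-1 grid coordinates),
so face k is the same material patch in both states. Triangulation is an
in-package Bowyer–Watson Delaunay implementation (no Delaunay package is
available in the target environment); regular grids make every grid square
exactly cocircular, so a deterministic index-hashed jitter of 2⁻²⁶ of the
bounding-box diagonal breaks ties for the topology only — returned vertex
coordinates are untouched. Faces degenerate in the reference state
(area < 10⁻⁹ mm²) are dropped from both states and logged.

The area-ratio field divides per-face areas (cross-product formula,
algebraically identical to Heron's) loaded/reference. Two identities are
enforced by tests: the total-area ratio equals the area-weighted mean of
per-face ratios, and rigid/scaling laws hold to machine precision.

Regional statistics follow the cadaver-study layout: three fan-shaped 30°
sectors (nasal, superior, temporal; inferior is occluded in the physical
rig), each split into annuli at 1 and 2 mm from the sheath margin, plus
0.1 mm-wide strips along the three directions. Distances are geodesic arc
lengths on the best-fit sphere of the reference surface: the source text
says "radial distances" without specifying geodesic versus chord; geodesic
was chosen because the regions live on a curved surface (the difference is
second-order at 1–2 mm on a 12 mm globe). Region means are unweighted
across faces by default — whether the original means were area-weighted is
unstated — with the area-weighted mean always reported alongside. Strip
bins are centred at 0, 0.1, 0.2, … mm; ties at bin edges go to the lower
bin. Empty regions are flagged and excluded from statistics, never
imputed. `mad_from_unity()` gives the per-region mean |ratio − 1| used to
compare loading modes.

For the end-to-end scene reconstruction the default ROI is the annulus
from 0.05 to 2.8 mm outside the sheath margin, sampled with a 17 px subset
on a 4 px grid — finer than the generic defaults because the tether field
varies over ~1 mm (~30 px) and a large subset low-passes exactly the
gradient being measured. With these settings the full
images-to-regions pipeline recovers generator nasal ratios of 0.96–0.99
within ±0.01, with a residual attenuation of the effect (a few parts per
thousand) split between the unsampled first ~0.1 mm next to the margin and
subset smoothing.

## Kinematics of adduction tethering

All kinematics live in a right-handed globe-centred frame, nasal = +x for
a right eye (left eyes are mirrored). The straight ON runs from its
scleral junction (offset from the posterior pole by the 17° fovea–disc
angle) to a gripper at distance R from the globe centre; for an included
angle χ+ψ the law of cosines gives the length
√(r² + R² − 2rR cos(χ+ψ)). Rotating the eye by θ or the gripper by ψ
produce congruent centre–junction–gripper triangles when θ = ψ, so the two
loadings are kinematically equivalent — an identity the tests sweep to
10⁻¹⁰ mm. A virtual orbital apex sits 41 mm from the globe centre at 22°
from the sagittal plane (average orbital dimensions); a measured straight
ON length places the gripper on the junction→apex segment, and a length
exceeding the junction–apex distance is flagged as slack rather than
clamped. Under adduction the junction swings temporally while the apex is
fixed, so the apex–junction distance grows;
`extension_proportion()` returns its fractional increase between two gaze
angles. Globe translation is fixed at zero (measured translation is near
zero over 26–32°), so elongation figures that include translation from
in vivo data enter as inputs, not outputs. ON strain subtracts the 3%
central-gaze sinuosity from the percentage elongation
(chord-referenced convention: 6.6% − 3% → 3.6%); the ratio convention
((1.066/1.03) − 1 ≈ 3.5%) is available via an argument.

## Tensile analysis

Engineering strain is referenced to the grip separation at the 0.02 N
preload — the reference is implied rather than stated in the source
protocol, and it shifts every modulus, so it is prominent in the
documentation and configurable. The preload stress (preload / cross
section) is **not** subtracted; curves start at σ(0) = preload/(w·t).
Samples after the force maximum (rupture) are truncated.

Tangent moduli come from differentiating a polynomial fit whose order
(3–5) is chosen by adjusted R², lowest order winning ties, with a manual
override; the estimator is exact on polynomial data up to order 5. The
toe-region transition uses bilinear regression after log transformation:
every interior breakpoint with at least 4 samples per segment is tried,
two independent (not continuity-constrained) OLS lines are fitted, total
SSE is minimized, and the transition strain is the abscissa of the lines'
intersection mapped back from log units — with flags for degenerate
(single power law) and out-of-range intersections. Natural logs are used;
the base affects neither slopes' ratio nor the transition, and unit
changes of stress shift intercepts only (tested). Sheath-like synthetic
curves at 2% noise return the 3.4% breakpoint within ±0.4 strain
percentage points across seeds. Pooled fitting of one curve is the
default mode; per-specimen fits can simply be mapped over records.

## Hyperelastic representation

Tissues are represented with the incompressible reduced-polynomial form
W = Σ C_i0 (Ī₁ − 3)^i. For uniaxial stretch λ = 1 + ε,
Ī₁ = λ² + 2/λ and the nominal stress is
P(λ) = 2(λ − λ⁻²) Σ i C_i0 (Ī₁ − 3)^(i−1) — verified against numerical
differentiation of W, with the small-strain identity dP/dε|₀ = 6 C₁₀.
Because P is linear in the coefficients, fitting is ordinary least squares
on the order-wise basis responses: deterministic, exact on model-generated
data, and failing loudly when C₁₀ comes out non-positive. Default orders
are 2 for scleral regions and 1 (neo-Hookean) for the ON and sheath,
following the modeling convention for these tissues (the exact orders are
configurable). The 5% pre-stretch that represents baseline ON/sheath
tension at the 26° tethering threshold is a rigid translation of the curve
along the strain axis, applied to curves *before* coefficient fitting when
a pre-stretched material card is wanted (the order of operations is a
choice; applying it to raw curves mirrors feeding translated curves to a
FEM). The lamina cribrosa, too small to test directly, is the pointwise
mean of the ON and peripapillary scleral stresses on a common 200-point
strain grid over the overlap of their ranges, and is always bounded by its
inputs. Poisson ratio 0.495 travels as near-incompressibility metadata for
FEM export.

## Numerical and scale choices

Problem sizes are chosen for a laptop-scale run: 640×640 px scenes with
~6500 speckles, 2–4 thousand grid points per reconstruction, 60 000-face
ground-truth meshes, 100-seed Monte-Carlo loops for error statistics, and
10⁵ draws for the √2 propagation check. The full test suite and the
acceptance script each run in a few minutes on one CPU. Other numerical
choices worth recording: the stereo seed tries up to 25 central grid
points before giving up; camera-2 temporal matches are evaluated at the
rounded stereo partner locations (the displacement field is smooth, so the
half-pixel evaluation offset is second-order); triangulation warns on
near-parallel rays via the system's condition number; the translation
standard gives camera 2 its own wide-window seed because out-of-plane
motion shifts opposed cameras in opposite image directions; and the
repeat-run heat-map difference metric matches fields by nearest reference
centroid (subsampled to 2000 probe faces on dense meshes).

## Known limitations

The affine subset model absorbs first-order perspective distortion but
not curvature within a subset; accuracy would degrade for much steeper
camera angles or much coarser image scales than the defaults. The
Bowyer–Watson implementation is O(n²) and intended for the few-thousand
point clouds produced here, not for large meshes. The tether displacement
field is kinematic, not mechanical: it prescribes the observed class of
deformation rather than solving tissue mechanics, so only its calibrated
summary (the nasal 1 mm mean ratio) and its support are meaningful points
of contact with real data. Regional statistics assume an approximately
spherical reference surface for geodesic distances; strongly aspheric
globes would need a true surface-geodesic computation. The tensile module
models neither viscoelasticity nor preconditioning, and anisotropy is out
of scope throughout.
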