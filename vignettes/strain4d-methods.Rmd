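---
title: "Quantifying left-ventricular mechanics from 4D ultrasound meshes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying left-ventricular mechanics from 4D ultrasound meshes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(strain4d)
```

## The problem

Two-dimensional echocardiography estimates left-ventricular (LV) function
from planar views, which hides regional wall-motion abnormalities — the
defining signature of myocardial infarction. Gated 4D ultrasound instead
yields the full LV geometry over one cardiac cycle. In the workflow this
package implements, an upstream tracking step marks 48 boundary points
per frame (4 short-axis slices x 6 rotational points, on both the
endocardial and epicardial surfaces); everything downstream of those
tracked points is handled here:

1. resample the sparse points into a dense space-time surface mesh,
2. compute three Lagrangian strain components and their systolic rates,
3. map peak strain onto the AHA 17-segment model,
4. estimate infarct size from low-magnitude surface-area strain,
5. derive volumetric function indices and peak dP/dt, and
6. quantify infarct size in histological sections for cross-validation.

## The mesh and its conventions

A `mesh4d` stores node coordinates (mm) indexed by
`(frame, surface, slice, rotation)`. Frame 1 is end diastole and serves
as the Lagrangian reference configuration for every strain; slices run
base (1) to apex (Z); rotation angles are `2*pi*(j-1)/Theta` with the
anterior wall at angle 0, increasing counterclockwise viewed from the
apex. The default grid — 60 time points, 60 slices, 60 rotations — gives
3600 nodes per surface per frame.

`resample_mesh()` interpolates the tracked points onto this grid:

* **time**: periodic cubic spline across the cycle (the gated cycle is
  periodic by construction);
* **within a slice**: periodic cubic spline of *radius and height
  against node angle about the slice centroid*. Interpolating in polar
  form reproduces circular contours exactly, whereas a componentwise
  cubic through 6 points on a circle would bow inward by roughly 0.3% of
  the radius. Short-axis LV contours are near-elliptical, hence
  star-shaped about their centroid, which this parameterisation assumes;
* **base to apex**: the interpolating cubic through the four slice knots
  (`stats::spline`, method `"fmm"`). Natural end conditions were
  rejected: they force zero curvature at the base and apex, exactly
  where an ellipsoidal profile is most curved, and inflate the
  round-trip error by an order of magnitude. The four knots sit at the
  control set's recorded `slice_positions` (normalised base-to-apex
  fractions), because four *exactly* equally spaced slice indices do not
  exist on every grid.

The spline surface passes through every control point at its own
parameters to machine precision. On a phantom round trip
(mesh -> 48 tracked points -> resampled mesh) the worst node error is
below 1% of the cavity radius.

## Strain definitions

All strains are Lagrangian, referenced to end diastole (subscript D),
and reported in percent:

* circumferential, per slice z — the circumferential Green-Lagrange
  component from the endocardial slice circumference C:
  `E_cc(z,t) = 1/2 [ (C(z,t)/C_D(z))^2 - 1 ] x 100`;
* longitudinal, per rotation theta — the engineering small-strain form
  of the base-to-apex boundary length L:
  `E_ll(theta,t) = (L - L_D)/L_D x 100`;
* surface area, per endocardial patch between sequential slices:
  `E_a(z,theta,t) = (A - A_D)/A_D x 100`.

Patch areas split each quadrilateral along the fixed
(slice, rotation) to (slice+1, rotation+1) diagonal into two triangles;
the alternative diagonal differs at second order in the mesh spacing,
and fixing one keeps results deterministic. Cavity volume closes the
triangulated endocardial surface with planar caps at the base and apex
rings and applies the divergence theorem; a non-positive signed volume
under the package's orientation conventions indicates an inverted or
self-intersecting surface and is an error rather than a number.

Several quantities the source equations leave open are fixed as
follows:

* **Peak systole** is the frame of minimum cavity volume (earliest
  frame on ties) — one consistent event for all components, rather than
  per-curve extrema that could disagree across slices.
* **Global peaks**: `E_cc` averages non-degenerate slices (a degenerate
  apical slice with zero reference circumference is excluded with a
  warning); `E_ll` averages the six wall regions (each region the mean
  of its rotations); `E_a` is the reference-area-weighted mean over all
  patches — patches shrink toward the apex, and an unweighted mean
  would overweight them.
* **Strain rate** is the least-squares slope of strain against time
  from end diastole to peak systole, not a two-point secant, for
  robustness to single-frame noise.

## Regional mapping

The AHA 17-segment model partitions the wall into basal (1-6) and mid
(7-12) thirds of 60 degree sectors, an apical level (13-16) of
90 degree sectors, and an apex cap (17) covering the last tenth of the
long axis (`apex_cap = 0.9`, configurable; the thirds are the standard
reading of the model, the cap size is not standardised). Sector
boundaries are half-open `[a, b)` so every angle maps to exactly one
segment. The angular origin is a declared convention, not a measurement:
anterior at 0, sectors advancing anterior, anteroseptal, inferoseptal,
inferior, inferolateral, anterolateral with increasing angle, so the
septum spans 30-150 degrees. If a dataset uses a different origin,
rotate the mesh before analysis. The six-region wall labels used for
longitudinal strain follow the same sectors under their
anterior/posterior naming. Per-segment peak `E_a` is the
reference-area-weighted mean of member patches; segments with no
patches are reported `NA` and flagged, never silently zero.

## Strain-based infarct sizing

Akinetic tissue is identified as patches whose peak-systolic `|E_a|`
falls strictly below a threshold (default 20%), and infarct size is the
akinetic fraction of the *end-diastolic* endocardial surface area —
area-true and consistent with the Lagrangian reference. The equation
defines `E_a` on patches, so thresholding operates on patches with
their reference areas as weights. A flag switches the criterion to the
maximum `|E_a|` over the cycle instead of the peak-systolic value.

Two behaviours are documented rather than corrected, mirroring how the
method behaves on real hearts:

* a smooth border zone partially suppresses contraction, so some of the
  "at-risk" rim falls under the threshold and the estimate lands
  between the core fraction and core + border — border-zone inclusion;
* at a perfectly sharp border the single ring of patches tethered
  between frozen and contracting tissue *stretches* (`E_a` strongly
  positive), leaving the mask. Size can therefore dip as severity
  approaches 1 at fixed extent; with a border zone of at least two node
  spacings the severity response is monotone. For the same reason the
  phantom's ground-truth akinetic area is defined on the realised mesh
  — patches whose corner nodes are all akinetic — not on the nominal
  angular extent.

## Volumetric function and contractility

`LVEDV` is the frame-1 (reference) volume — consistent with the strain
reference, and in practice equal to the cycle maximum on gated data;
`LVESV` is the cycle minimum. `EF = (LVEDV-LVESV)/LVEDV x 100`,
`SV = LVEDV - LVESV` (uL), `CO = SV x HR / 1000` (mL/min), and
`HR = 60 / cycle duration` since the gated cycle defines one beat.
`+dP/dt max` is the maximum central-difference derivative of the
pressure trace (one-sided at the ends); for physiological traces this
maximum lies on the isovolumetric upstroke, so no explicit phase
detector is needed. `linear_fit()` wraps ordinary least squares
(`stats::lm`) with `tidy()`/`glance()`/`autoplot()` methods for the
strain-vs-contractility reports.

## Histology

Sections arrive as integer label masks (0 background, 1 healthy
myocardium, 2 scar). All quantities come from ray casting at 1 degree
steps from the myocardium centroid, which makes them invariant to image
rotation and pixel-size rescaling:

* a section is **transmural** when some ray crosses only scar between
  the endo- and epicardial boundaries;
* the **midline** method (transmural sections) reports the infarcted
  arc fraction of the mid-wall curve, each 1 degree bin weighted by its
  midline radius and counted as infarct when more than half its wall
  pixels carry the scar label;
* the **area** method (nontransmural sections) is the scar fraction of
  all myocardium pixels.

A heart's four sections are scored midline-if-transmural, area
otherwise, and averaged; how multiple sections combine into one size is
a package choice (the mean), as no standard exists.

## The phantom

`generate_phantom()` builds the synthetic study object: a truncated
half-ellipsoid (or cylinder) LV whose healthy tissue follows a
raised-cosine time course from end diastole to peak scales
`(lambda_min, mu_min)` and back — smooth, periodic, with a single
volume minimum at the configured systole fraction. Defaults approximate
a rat LV: 4 mm cavity radius, 12 mm length, 2 mm wall, 0.17 s cycle
(about 350 bpm), peak systole at 35% of the cycle,
`lambda_min = 0.8`, `mu_min = 0.9`. The ellipsoid is truncated one node
row above the pole so no slice has zero circumference. An akinetic
patch of prescribed angular/longitudinal extent blends the local scales
back toward 1 by `severity`, with a smoothstep border; matched
sinusoidal pressure traces (known `A x omega`) and labeled histology
masks complete a dataset. Optional Gaussian node jitter is seeded and
byte-reproducible.

Closed forms make the phantom a genuine oracle: a cylinder scaling by
`(lambda, mu)` has `E_cc = 50(lambda^2-1)`, `E_ll = 100(mu-1)`,
`E_a = 100(lambda mu - 1)` exactly at every location, and any surface
under isotropic scale s has `E_cc = 50(s^2-1)`, `E_ll = 100(s-1)`,
`E_a = 100(s^2-1)`. Ground-truth volumes use an independent numeric
route (shoelace cross-sections with trapezoidal integration), not the
divergence-theorem code they validate.

What the phantom does *not* emulate: speckle, image artifacts, tracking
error beyond white node jitter, wall torsion/twist, valve geometry,
asymmetric remodelling, and regional timing dispersion. Passing its
oracles therefore demonstrates correctness of the geometry and strain
machinery, not robustness to real acquisition noise.

## Validation scale and numerical tolerances

The test-suite problem sizes are: the full default grid
(60 x 60 x 60) for structural checks, analytic strain oracles, infarct
recovery and the volume benchmark; reduced grids (about 12-16 frames,
16-40 slices/rotations) for property sweeps; 512 px histology rasters
(about 0.03 mm/px, where the midline estimate resolves 1 degree bins);
1 kHz pressure traces; and 6-phantom contractility cohorts. Cylinder
closed forms are asserted at 1e-9, ellipsoid isotropic forms at 1e-6,
cavity volumes at 2% against analytic solids with monotone convergence
at 30/60/120 resolution, infarct recovery within 2 percentage points,
histology wedges within 1 percentage point, and strain-vs-histology
cross-modality agreement within 3 percentage points. Test grids place
the systole fraction exactly on a frame time so the configured peak
scales are attained; with an off-grid fraction the realised peak
undershoots by O((dt/T)^2), which is measurement reality rather than
error.

## Known limitations

* `E_ll` uses the endocardial boundary only; a mid-wall line would give
  slightly smaller magnitudes. The epicardial surface is stored and
  meshed but feeds no strain equation.
* Radial strain and torsion are out of scope.
* Nontransmural infarcts retain partial contraction, so the strain
  estimator can undervalue them — the histology area method exists
  precisely for those sections.
* The polar in-slice interpolation assumes star-shaped contours; grossly
  aneurysmal sections violating this need a denser control set.
* No pressure-volume loop analysis; pressure traces serve only
  `+dP/dt max`.
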