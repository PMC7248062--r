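---
title: "Quantifying skin-wound biomechanics from point tracking"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying skin-wound biomechanics from point tracking}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(woundstrain)
```

## The measurement problem

A healing wound is stiffer than the surrounding skin, so when the skin
is stretched along the cranio-caudal axis the wound region deforms
less. Imaging the stretch with a telecentric lens (30 × 30 mm field at
1000 × 1000 px, i.e. 0.03 mm/px) and tracking natural-contrast
landmarks turns this into a quantitative, non-invasive readout of
wound mechanics: an elastogram of local strain, an average wound
deformability, and the spatial extent of the mechanically affected
region. This vignette explains the models and estimators, the
parameters that matter, the synthetic test bed, and the numerical and
design choices made where more than one reasonable option existed.

## Kinematics

### Global strain and frame selection

The applied strain level is defined as the slope of the ordinary
least-squares regression of axis-projected displacement on
axis-projected reference position, over all reliably tracked points.
For a homogeneous elongation `u = eps * X` the slope is exactly `eps`,
and rigid motion contributes nothing. Because the load is applied
manually in the envisaged experiment, measurements are standardized by
selecting the first frame whose global strain reaches a prescribed
target (default 0.10; 0.05 is used for robustness checks). We use a
first-crossing rule without temporal interpolation and report the
achieved strain alongside, so downstream normalization can account for
the small overshoot. The regression is unweighted: every tracked point
is an equally informative sample of the far-field motion.

### Local deformation gradient

At each query location the local affine map `x = F X + c` is fitted by
weighted least squares over the neighboring tracking points, with
inverse-distance weights `w = (d + 1)^-1` cut off sharply at
`r_max` (default 100 px). The cutoff is a strict inequality
(`d < r_max`), taken literally from the weight definition. Two choices
deserve comment:

- The translation term `c` is estimated jointly with `F`. A gradient
  alone cannot absorb rigid translation, and dropping `c` would alias
  translation into spurious strain.
- The normal equations are formed on query-centered coordinates and
  solved directly; a condition number above 1e8 (or fewer than three
  supported points) raises an estimation-failure error naming the
  query point. Failures inside `compute_strain_field()` are collected
  per point rather than aborting the field.

The fit is exact (to rounding) whenever the true motion is affine, for
any weighting — this is the basis of the kinematics oracle tests,
which recover 100 random affine maps to better than 1e-9 and return
zero strain for 100 random rigid motions.

The Green–Lagrange tensor `E = (F'F - I)/2` is symmetrized to machine
precision and its axial component `e' E e` (unit extension axis `e`)
is the mapped quantity. `E` vanishes identically under rigid motion,
which is why it, rather than the displacement gradient, is the right
strain measure for a manually loaded, freely translating tissue
surface. For a uniaxial stretch `lambda`, the axial component is
`(lambda^2 - 1)/2` — `strain_from_stretch()` — linking the in vivo
fields to ex vivo tensile measurements under the same strain
definition.

### Choosing `r_max`

`r_max` trades random error against spatial resolution: the estimator
averages the deformation over its support, so structures smaller than
roughly `r_max` are smoothed. The 100 px default suits the sparse
natural contrast pattern of shaved skin at study scale. When a wound
region of radius `R` is quantified, the unbiased regime is
`roi_radius + r_max <= R`: every support point of every ROI query then
lies inside the homogeneously deforming core. The end-to-end
validation uses exactly this geometry (ROI radius 50 px + cutoff 50 px
= inclusion radius 100 px at a tracked-point density of ~0.0015 px^-2,
about 11 supported neighbors per query). With the default 100 px
cutoff on a 3 mm-radius wound, ROI averages carry a modest positive
bias from the stiffness transition zone; ratios between conditions are
unaffected because the bias scales with the load.

## Tracking

Fiducial points are local contrast maxima ranked by the smaller
eigenvalue of the smoothed gradient structure tensor (Shi–Tomasi
criterion), greedily thinned to a minimum pairwise spacing (default
15 px). Tracking is template matching by normalized cross-correlation
(NCC): a window (default 21 px) anchored in the *reference* frame is
searched in a region (default 31 px) around the previous position in
each subsequent frame. Reference anchoring avoids the drift
accumulation of frame-to-frame (optical-flow-style) trackers at the
cost of template mismatch growing with deformation; at the 10 % strain
used here the residual tracking error is below 0.2 px RMS with 2 %
image noise.

Subpixel refinement fits a least-squares paraboloid to the 3 × 3 NCC
neighborhood of the peak and reports its stationary point (clamped to
half a pixel); the full 2D fit captures the diagonal elongation a
sheared correlation peak exhibits, which separable 1D parabolas miss.
A peak is only accepted when its 3 × 3 neighborhood is finite and
interior to the search region — otherwise the true match may lie
(partially) outside the frame and the best in-bounds placement is a
look-alike; this is the common failure mode near image borders under
large stretch. Rejected or low-NCC matches (threshold 0.5) flag the
trajectory from that frame onward; flagged trajectories are excluded
from strain estimation but retained in the output with their
confidence values, never silently dropped. Tracking contains no
randomness: identical inputs give identical trajectories.

## Wound metrics

### Functional wound length

The displacement profile along a strip (default width 100 px) through
the wound is fitted with a continuous three-segment piecewise-linear
model: outer segments for compliant skin, a reduced-slope middle
segment for the wound. We impose continuity — without it the two
breakpoints are only weakly identified by independent segment fits —
and estimate the breakpoints by exhaustive search over a grid of
candidate pairs at the observed abscissae (capped at 50–80 candidates)
followed by Nelder–Mead refinement of the continuous pair. The
functional length is the breakpoint separation in mm. If the middle
slope is not below the outer slopes by a 20 % relative margin, the
profile is mechanically homogeneous and a zero length is returned with
`detected = FALSE` rather than a spurious positive value. Outer slopes
are left free rather than pinned to the global strain; on synthetic
data the fitted outer slopes match the applied strain to ~1 %, and
leaving them free keeps the estimator honest when the far field is not
perfectly homogeneous.

On smooth inclusion fields the breakpoints land inside the transition
bands, so the functional length exceeds the stiff-core diameter —
mirroring the observation that the mechanically affected region is
larger than the visible wound.

### Visible-wound morphometry

Ellipse fitting uses the direct least-squares conic fit constrained to
ellipses in its numerically stable partitioned form, on
centered/scaled coordinates; collinear input or a non-elliptic best
conic raises an error. Area (`pi a b`) and the extent of the ellipse
projected on the extension axis ("visible length") are reported in mm
via the pixel scale. A helper extracts the largest connected
component's boundary from a binary wound mask, so the workflow is
automated end to end; interactive ellipse tools can be substituted by
supplying any contour.

### Healing rates

Rates of change on the uneven day grid (3, 5, 7, 10, 14, 21) use the
three-point central difference for non-uniform spacing at interior
days, with the forward difference at the first day and the backward
difference at the last. The central formula is exact for quadratic
time courses — the basis of a property test over random quadratics and
random grids — while the endpoint formulas are exact only for linear
ones. Rates can be computed from pooled per-day means or per wound
when longitudinal identity is available; both are plain
`healing_series` objects.

## Collagen density maps

A binary fiber mask is divided into square elements (default 50 px;
partial edge elements use their actual pixel count as denominator).
Raw density is positive/total pixels. Smoothing averages each element
with the neighbors whose centroid-to-centroid distance is at most the
element diagonal — on a square grid exactly the 8-neighborhood,
corner neighbors included since they sit exactly at the diagonal
distance — and we include the element itself in its own average
(the natural reading of an averaging filter; declared because the
alternative exists). Uniform weights are used; distance weighting
within a single-element ring would change little and is harder to
motivate. Normalization divides by the image-specific maximum and is
skipped for empty masks. Uniform averaging makes the filter
mass-conserving away from boundaries, which the tests verify to 1e-12.

## The synthetic test bed

Real wounds cannot provide pointwise ground truth, so validation runs
on a kinematically prescribed inclusion field: axial engineering
strain `eps_in` inside a circular inclusion, `eps_out` outside, a
cosine ramp over a transition band as a function of radius, and axial
displacement obtained by integrating the strain profile along the
axis from the inclusion centre (composite Simpson with 2048
subintervals per point; the profile is C1, and the quadrature error is
below 1e-7 px, verified against central differences at 1e-6). The
transverse displacement is zero. This is deliberately *not* a
mechanical equilibrium solution — it is an exactly known displacement
field with the right qualitative structure (homogeneous far field,
soft-to-stiff transition, resolvable band), which is what an estimator
validation needs; a finite-element solution would add solver
dependencies without adding ground-truth precision.

Default study conditions: 1000 px (30 mm) sheet, inclusion radius
100 px (3 mm), band 40 px, `eps_out` 0.10, `eps_in` 0.02 (deformability
contrast 5, in the range observed for week-one wounds), speckle
density 0.012 blobs/px^2 (Gaussian blobs, sigma 1.5 px — about five
features per tracking window, comparable to a prepared DIC speckle
pattern), additive Gaussian noise 2 % of the dynamic range, six frames
ramping linearly to the full field. All randomness passes through an
explicit seed; identical seeds give bit-identical images and
trajectories.

The rate-dependent variant couples the inclusion contrast to loading
duration through a standard-linear-solid relaxation: contrast
`C(T) = C_eq + (C_inst - C_eq) g(T)` with ramp-averaged relaxation
fraction `g(T) = (tau/T)(1 - exp(-T/tau))`. Defaults (`C_inst` 9.13,
`C_eq` 6.72, `tau` 5 s) emulate a viscoelastic elastomer phantom with
a rigid 6-mm inclusion stretched to 15 % nominal strain: loading
durations of 1.5 s vs 150 s (a 100-fold strain-rate change) move the
inclusion-centre strain only from about 1.7 % to 2.2 % — the basis of
the rate-robustness property (< 35 % relative change), which is why a
manually applied, rate-uncontrolled load is acceptable in practice.

The healing-course simulator shrinks the visible wound and stiffens
the contrast over days 3–21 under a user-supplied monotone schedule,
to exercise the longitudinal rate machinery end to end.

### What passing these tests does and does not show

The generator emulates the geometry, contrast statistics, noise level,
and deformation structure of the imaging setup, and gives exact
ground truth. It does not emulate out-of-plane motion, illumination
drift, specular highlights, hair regrowth, occlusions, breathing
motion, or genuinely viscoelastic time-dependent fields within a
single extension. Passing the suite therefore validates the
estimators' correctness and noise robustness, not the biological
variability of real measurements; on real data the tracking confidence
flags and the per-point failure lists are the first place to look.

## Numerical choices and test problem sizes

- WLS condition-number threshold 1e8 for declaring degenerate support;
  queries are centered before forming normal equations.
- Strict `<` at the weight cutoff; weight at distance 0 is 1.
- NCC peaks with near-unity value (1 - 1e-9) skip subpixel refinement,
  making zero-motion sequences return exactly zero displacement.
- Breakpoint search: grid over observed abscissae (minimum four points
  per segment) then Nelder–Mead refinement; ties in RSS resolve to the
  first minimum encountered.
- Ellipse fit normalizes coordinates by centroid and scale before the
  eigen-decomposition.
- Image coordinates are 0-based with x rightward and y downward, the
  native convention of the image files; trajectory CSVs use 0-based
  frame indices with frame 0 the reference, while R-level frame
  indices are 1-based.

The unit and property tests run the pipeline at a 500 px sheet
(radius 60 px, band 30 px, up to 300 tracked points) — small enough to
keep the full suite fast while leaving every estimator in its
operating regime; the end-to-end recovery and the acceptance script
use the full 1000 px study geometry with 1500 tracked points. Recovery
accuracy at both scales is a few percent relative, well inside the
10 % validation bound.

## Known limitations

- Strictly 2D: out-of-plane motion is assumed removed by telecentric
  optics; no stereo reconstruction.
- No forces: the method measures deformability contrast, not stiffness
  in Pa; a uniform stress state is implicitly assumed when ratios are
  interpreted as stiffness ratios.
- Reference-anchored NCC degrades beyond ~15 % strain as template
  mismatch grows; subset-shape-function matching would be the next
  step if larger strains are needed.
- The functional-length model assumes a single wound per strip; two
  nearby wounds would merge into one affected region.
- Density-map class segmentation (thin/mixed/thick fibers) is an
  upstream, stain-specific step supplied by the user as binary masks.
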