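---
title: "Slice-wise micro-CT morphometry: models, estimators and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Slice-wise micro-CT morphometry: models, estimators and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(bonemorph)
```

## The analysis model

`bonemorph` treats a binarized micro-CT stack of a long-bone segment as a
stack of cross-sections indexed by *percent bone length*. The distal end of
the bone is 100%; moving proximally by one slice decreases percent by
`100 * voxel_size_mm / L`, where `L` is the caliper-measured bone length.
Because typically only the distal part of the bone is scanned, the distal
end is the anchoring landmark and the proximal end is extrapolated through
`L`. Every 2D morphometric parameter is computed on every slice, giving
per-specimen *morphometric distributions*; a cubic spline resamples each
distribution onto a common integer-percent grid (trabecular default
60–100%, cortical 40–80%, 1% step) where specimens and groups are compared
point by point. The native-resolution distribution is retained for
Trabecular Extent, which is resolution-sensitive (see below).

Assumptions worth stating explicitly:

- the input is already binarized (thresholding and reconstruction artefact
  correction are upstream concerns);
- voxels are isotropic (anisotropic stacks are rejected at load);
- the scanned segment is longer than wide, so its first principal axis is
  the shaft centreline — automated alignment warns when this fails;
- the growth-plate reference slice is supplied as metadata (identifying the
  chondrocyte seam is a manual, image-reading task outside this package).

## Alignment and the shared frame

Interactive rigid co-registration of each scan to a reference specimen is
replaced by per-specimen principal-axis alignment: the foreground's first
principal axis (second-moment eigen-decomposition) is rotated onto the
slice axis with trilinear interpolation and re-binarization at 0.5, which
conserves foreground volume in expectation (observed: within 0.2% on
cylinder fixtures, with < 0.1° residual tilt). Cross-specimen comparability
comes from the shared percent grid, not from voxel-level registration; this
is the quantity actually compared statistically. Rotation about the shaft
axis (axial spin) is left unconstrained — a known limitation for the
orientation (though not the value) of eccentricity, which is rotation
invariant.

## Compartment segmentation

Each slice is separated by a documented morphological pipeline (EBImage):

1. periosteal region = hole-filled closing (disc radius `closing_radius_px`,
   default 5) of the largest connected foreground component — the closing
   bridges small cortical breaches so the medullary cavity becomes a
   fillable hole;
2. cortical bone = foreground connected to the periosteal boundary. Thin
   trabecular bridges onto the endocortex are detached first by an erosion
   of depth `bridge_cut_px` (default 2 px); the surviving boundary-touching
   cores are grown back onto the bone by geodesic reconstruction of bounded
   depth, which recovers the eroded rim without re-crossing cut bridges;
3. trabecular ROI = medullary region minus a guard band (default = closing
   radius) along the endocortical boundary, so endocortical surface
   roughness is not counted as trabeculae; trabecular bone = foreground in
   the ROI.

The bridge-cut rule is the main judgement call: bone contiguous with the
cortex through a neck thicker than `2 * bridge_cut_px` is classified
cortical. Slices are QC-flagged as *open cortex* when the periosteal
boundary is poorly covered by cortical bone (< 95%) or when closing yields
no enclosed cavity although the section is strongly non-convex (an open
ring); more than 20% flagged slices abort segmentation. Slices are padded
with background before morphology, since border-clamped erosion would
otherwise fabricate foreground at the image edge.

## 2D estimators

**Areas** are pixel counts times `a²` (`a` = voxel size) — exact for the
mask, within ~1% of analytic values for rasterized discs at radius ≥ 20 px.

**Perimeters** use marching squares with linear interpolation on a
Gaussian-smoothed (σ = 1 px, reflected boundaries) copy of the mask.
Purely binary midpoint marching squares overestimates a circle of radius
50 px by 5.8%; the smoothed variant is within 0.4%, and straight edges stay
exact because smoothing is symmetric across them. Contours are *not*
closed at the image or ROI edge: a plate running out of the field
contributes only its long sides, which is the behaviour the plate-model
thickness needs. Smoothing rounds sharp corners slightly (≲ 0.4 px per
corner), a negligible bias for cortical shells but a reason not to use
perimeter-based metrics on few-pixel islands.

**Plate-model trabecular metrics** follow the classical identities
`Tb.Th = 2·B.Ar/B.Pm`, `Tb.N = (BA/TA)/Tb.Th`, `Tb.Sp = 1/Tb.N − Tb.Th`,
so the separation identity holds to machine precision by construction. The
plate model is the default because it matches the vendor-style 2D outputs
this workflow is meant to reproduce; a direct local-thickness model
(mean maximal-inscribed-disc diameter via exact Euclidean distance
transform and disc painting) is available via `thickness_model = "local"`
and is the default in 3D.

**J** includes the per-pixel self-moment `a⁴/6` so a single pixel is well
defined; it is computed about the section centroid and is therefore
translation invariant. **Ecc** is the square-rooted eigenvalue ratio of the
pixel-coordinate covariance; sections with a degenerate minor axis raise an
error rather than returning an unstable ratio.

## 3D estimators

**BS** is the area of the 0.5 iso-surface of the Gaussian-smoothed
(σ = 1 vx) indicator, triangulated by marching tetrahedra (six tetrahedra
per voxel cell, linear interpolation along edges). Marching tetrahedra was
chosen over classic marching cubes because it needs no case table and has
no ambiguous configurations; on the smoothed field it recovers a sphere of
radius 20 vx to 0.3% in area (binary marching cubes carries a several-percent
orientation-dependent bias). As in 2D, bone clipped by the VOI boundary is
left open — clipped cross-sections are not bone surface — so `2·BV/BS` of a
spanning plate equals its thickness.

**Direct thickness** (Tb.Th, Ct.Th, Tb.Sp on the background) is the
volume-weighted mean maximal-inscribed-sphere diameter: exact Euclidean
distance transform, then sphere painting in decreasing radius order. On
rasterized fixtures: plate thickness exact, rod diameter +1.4%, curved
tube wall +0.6% (odd-integer wall widths carry an inherent +0.5–1 px
digitization bias, which is why fixture features are kept ≥ 6 px and even
where possible).

**Conn.D** uses the Euler characteristic of the cubical complex of
foreground voxels (vertices − edges + faces − cubes of the union of closed
unit cubes — the 26-connectivity interpretation), validated against an
independent cell-enumeration oracle and against Betti numbers of known
solids (ball χ = 1, torus χ = 0, hollow shell χ = 2). `Conn.D = (1 − χ)/TV`
can legitimately be negative for fragmented structures. **Tb.Pf** is
`(S₁ − S₂)/(V₁ − V₂)` across one dilation with the full 3×3×3 structuring
element. **uPi** divides direct thickness by plate-model thickness
`2·BV/BS`; ideal plates give ≈ 1, ideal rods ≈ 2 (observed 0.95 and 1.96 on
8 px/radius-6 px fixtures).

Where a slice-wise quantity is also wanted per VOI (cortical areas, J,
Ecc), the per-slice values are averaged over the VOI slices; Ecc in
particular is a per-slice average, not a single whole-VOI fit. VOI presets
ship for the metaphyseal secondary spongiosa (81–85%), epiphysis (93–97%),
diaphysis (58–62%) and two metaphyseal cortical windows (81–85% and
76–80%); the 81–85% window is the primary metaphyseal preset and the
76–80% variant is provided as an alternative distal window.

## Trabecular Extent

Tb.E scans the *native-resolution* BA/TA distribution proximally from the
growth-plate reference level and reports the distance (in mm, converted
from percent by `L/100`) to the **first** crossing of each threshold
(default 0.30, 0.20, 0.10, 0), located by linear interpolation between the
bracketing slice samples. Sub-slice interpolation was chosen over snapping
to whole slices because the crossing is generically between samples; the
choice matters at most half a slice. First-occurrence semantics make Tb.E
deliberately sensitive to local rarefaction — a single pruned slice stops
the scan — which is why multiple thresholds plus the absolute extent
(distance to the most proximal slice with BA/TA > 0) are always reported
together. Thresholds never reached are *censored* at the full covered
distance and flagged (not NaN, so cohort tables stay rectangular; censored
values should be excluded pairwise from tests); thresholds above the BA/TA
value at the reference level return 0 with a flag.

## Statistics

Group comparison at each grid point uses the classic pooled-variance
Student t-test (Welch available via a flag), with means ± SE (SD/√n) and
the significance bands NS, .05 > p ≥ .01, .01 > p ≥ .001,
.001 > p ≥ .0001, p < .0001, implemented with exactly those half-open
boundaries (p = .05 is NS; p = .01 falls in the .05 band). No
multiple-testing correction is applied across grid points by default — the
bands are read as a pointwise significance *profile*, not as a family of
independent claims; a Holm option exists for users who want family-wise
control over the ~41–61 tests a grid implies. A *significant band* is
defined as a run of at least two consecutive significant points: an
isolated grid point at α = 0.05 is within the expected false-positive rate
of the pointwise procedure (the null calibration below accepts ~5% of
points rejecting) and is not reported as a spatial effect. Normality
screening runs Anderson–Darling (n ≥ 8) and Lilliefors (n ≥ 5) per group
and flags, never auto-switches, on rejection.

## The phantom generator

`make_phantom` emulates the features of a distal long-bone segment that
the pipeline actually measures: an (optionally elliptical) cortical tube
with linearly varying radii and an optional trochanter-like outer bump; a
trabecular lattice of plates or rods whose target area fraction is constant
distal of a virtual growth plate and decays linearly proximally —
the monotone metaphyseal BA/TA gradient. The decay is realized by seeded
probabilistic pruning of whole lattice elements, so rarefaction is
number-driven rather than thickness-driven, matching how metaphyseal bone
actually thins. The lattice stands off 8 px from the endocortical boundary
so phantom trabeculae never fall inside the segmentation guard band, making
generator bookkeeping (exact per-slice voxel counts, emitted as ground
truth) directly comparable to pipeline output. Defaults follow the
targeted scanner protocol (6.89 µm voxels, 36.81 mm femur); tests and
examples scale the voxel size up (10–20 µm on 2 mm "bones", 40–80 slices,
cross-sections ≈ 100² px) so suites run in minutes — these sizes are the
package's validation conditions, chosen once.

What the phantom does *not* emulate: greyscale noise and thresholding
artefacts, anatomically realistic condyle shapes, connected 3D trabecular
networks (pruning is per slice, so vertical continuity is broken — 3D
topology metrics on phantoms exercise the code path but not realistic
values), or partial-volume effects. Passing phantom tests therefore
validates the estimators and the pipeline plumbing, not the segmentation's
behaviour on real noisy endocortical surfaces, where the bridge-cut depth
is the parameter to audit.

Per-specimen cohort simulation for statistical testing runs at the
*distribution* level (`simulate_groups`): multiplicative lognormal noise
(unit mean, configurable CV) independently per specimen and grid point
around a base profile, with band-limited multiplicative deficits for the
second group. Independence across grid points is a simplification (real
profiles are spatially correlated within a specimen); it is the correct
model for calibrating the *pointwise* type-I error, which is what the
pipeline's tests need, but it understates the spatial clustering of false
positives in real data.

## Numerical conventions and degenerate inputs

- Interpolation onto the grid uses `stats::spline` (Forsythe–Malcolm–Moler
  end conditions); it reproduces constants and linear trends exactly and a
  smooth profile sampled at native resolution to < 1e−3 of its amplitude.
  No extrapolation: grid points outside the covered range are an error.
- Empty slices, empty ROIs and boneless ROIs return zeros with explicit
  flags rather than NaN, so per-slice tables and cohort matrices stay
  rectangular and machine-readable.
- Zero pooled variance at a grid point yields p = 1 (equal means) or the
  smallest positive double (unequal), flagged degenerate.
- All randomness (phantom pruning, cohort simulation) flows through
  explicit seeds and restores the caller's RNG state; pipeline reruns with
  the same config are byte-identical, and every output CSV carries an MD5
  hash of the analysis-relevant config.

## Known limitations

- The 2D plate-model thickness is a model, not a measurement; on rod-like
  structures it underestimates thickness by design (that mismatch is what
  uPi quantifies in 3D).
- Local thickness carries the usual half-voxel digitization bias on curved
  or odd-width structures.
- Eccentricity orientation is not standardized across specimens (axial
  spin is unconstrained by the alignment).
- BMP slice sequences are not read (TIFF and PNG are); greyscale
  densitometry and anisotropy measures are out of scope.
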