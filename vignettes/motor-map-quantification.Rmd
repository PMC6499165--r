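---
title: "Quantifying and comparing TMS motor cortex maps"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying and comparing TMS motor cortex maps}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(motormap)
```

## The problem

Neuronavigated transcranial magnetic stimulation (TMS) produces *motor
maps*: sets of stimulation events, each carrying a 3D scalp coordinate in
scanner mm and the peak-to-peak amplitude (microvolt) of the motor evoked
potential (MEP) recorded from a target muscle. Tracking how such a map
changes over time -- with motor learning, fatigue, or recovery from a brain
lesion -- requires (a) reducing the 3D point set to a 2D field that can be
interpolated, (b) dealing with the large trial-to-trial variability of MEPs
via repeated-measures clustering, and (c) summary metrics that can be
compared across sessions even when the stimulation grids do not align.

`motormap` implements this workflow end to end: angular projection through a
fitted scalp ellipsoid, quality-threshold clustering with five consolidation
operators, four non-parametric surface fitters, map metrics (centre of
gravity, peak, thresholded surface area, volume integral, per-peak
discretization), and continuous (RMSE) and categorical (ROC/AUC) map
comparison.

## Angular coordinates and the scalp ellipsoid

Stimulation sites hug the scalp, so the radial dimension carries almost no
information. Each point is reduced to two angles about the head centroid
$o = (x_o, y_o, z_o)$:

$$\theta = \arccos\frac{z - z_o}{\lVert p - o\rVert} \in [0, \pi], \qquad
  \varphi = \operatorname{atan2}(y - y_o,\; x - x_o) \in (-\pi, \pi].$$

$\theta$ is the inclination from the superior axis and $\varphi$ the
azimuth. We use the quadrant-aware two-argument arctangent throughout: a
single-argument form would collapse the two hemispheres onto one and could
not support a full-head projection. A point coinciding with the centroid has
no direction and raises a classed error rather than returning an arbitrary
angle; the same is true of the azimuth at the poles for downstream
operations that need it.

The centroid comes from the structural scan: the head is segmented from the
background (Otsu threshold, one-step morphological closing, largest
connected component, interior hole fill -- all deterministic), the mask is
thinned to a point cloud by taking every 25th foreground voxel in raster
order, and the centroid is the coordinate-wise mean of the cloud.

To go *back* from angles to 3D positions -- needed for the topographic
display and for all patch-based area integrals -- a surface model is fitted
to the cloud by per-axis least squares. Each centred coordinate is modelled
as a constant plus a fourth-order polynomial radial term modulated by the
axis direction cosine, e.g. for $x$:

$$x - x_o = w_1 + \left(w_2 + w_3\theta + w_4\varphi + w_5\theta^2 +
  w_6\varphi^2 + w_7\theta^3 + w_8\varphi^3 + w_9\theta^4 +
  w_{10}\varphi^4\right)\sin\theta\cos\varphi,$$

ten weights per axis (30 total). An exact sphere of radius $R$ solves with
$w_2 = R$ and all other weights zero. The fit residual is non-increasing as
terms are added, and ten terms is where extra parameters stop improving the
scalp approximation. Rank-deficient designs (e.g. all cloud points along a
ray) and clouds smaller than the parameter count raise classed errors.

Two numerical notes. First, because the radial polynomial differs per axis,
the model is not purely radial: the angular coordinate recovered from a
predicted 3D point differs slightly from the angle that generated it except
on a sphere. All analysis therefore lives consistently in the *recovered*
coordinate system. Second, the every-25th-voxel cloud samples the whole head
volume, not its surface, so the least-squares surface sits inside the scalp;
it is a projection manifold, not a skin reconstruction, and all package
geometry (site projection, patch areas) uses it consistently.

## Topographic display and equator snapping

The scan is rendered as a "globe-like" topographic image by sampling the
voxel intensity at the model surface point of every angular grid pixel
(nearest-voxel lookup, no interpolation, so raw intensities are preserved;
out-of-volume pixels take the background value). Default grid: $\theta \in
[0, \pi]$, $\varphi \in (-\pi, \pi]$ at $\pi/512$ rad per pixel (512 x 1024).

Angular distance is proportional to arc length only at the equator and
degenerates at the poles. To keep the data in the least-distorted band, one
rigid rotation about the centroid takes the direction of the data's centre
of gravity to inclination $\pi/2$. We use the *minimal* such rotation (axis
= cross product of the COG direction and its equatorial projection), which
perturbs neighbourhoods least; a COG on the polar axis itself is sent to the
$+x$ direction, and a COG at the centroid is an error. The same rotation is
applied to the head cloud so the ellipsoid can be refitted consistently.
Pairwise 3D distances are preserved exactly.

## Clustering and consolidation

Repeated stimulations at (nominally) the same site are grouped by
quality-threshold (QT) clustering on pairwise 3D distances normalized by the
dataset's maximum pairwise distance. The user threshold is therefore a
unitless fraction: 0 keeps every event separate and 1 merges everything,
the two documented endpoints. The candidate cluster for each seed is grown
greedily -- always adding the point that least increases the cluster
diameter while the normalized diameter stays within the threshold -- and the
largest candidate is extracted, ties going to the lowest seed index for
determinism. The diameter (not seed-radius) criterion was chosen so the
threshold reads directly as "largest allowed cluster extent". Threshold 0 is
special-cased to exact singletons so that coincident duplicate events still
count as separate measurements, matching the documented endpoint semantics.

Each cluster collapses to one point at the unweighted mean of its member
positions (the representative location is not specified by any convention;
the mean is symmetric and deterministic), with a value given by one of five
operators: mean, maximum, minimum, population variance
($s = \sum_i (v_i - \mu)^2 / N$, microvolt squared), or *probability*: the
percentage of members strictly above a binarization threshold (40 microvolt
by default). Binarization is strict -- a value exactly at the threshold maps
to 0 -- because only "above" and "below" are ever specified; the
`strict = FALSE` switch is available and the behaviour is documented.
Single-measurement data under the probability operator yield only 0% or
100%.

## Surface fitting

Consolidated data are fitted with $v = S(\theta, \varphi)$ using one of four
non-parametric algorithms:

* **piecewise linear** -- barycentric interpolation on a Delaunay
  triangulation of the sites;
* **piecewise cubic** (default, best goodness of fit in practice) -- a
  $C^1$ Clough--Tocher element on the same triangulation: each triangle is
  split at its barycentre into three cubic Bezier patches; vertex values and
  gradients fix the corner and edge controls, the control across each
  exterior edge enforces a linearly varying normal derivative (the same
  condition on both sides, hence global $C^1$), and the interior ring
  follows from the $C^1$ conditions across the split. Gradients are
  estimated by local least-squares quadratics over the neighbouring sites,
  so the full scheme reproduces quadratic fields exactly;
* **biharmonic** -- the Green's-function spline with basis
  $g(r) = r^2(\ln r - 1)$, one coefficient per site. We augment the system
  with a constant trend (coefficients constrained to sum to zero). The pure
  Green's system cannot reproduce a constant field exactly between sites,
  whereas the augmented one is exactly equivariant under value shifts and
  reproduces constants -- properties the rest of the package relies on.
  Duplicate sites are collapsed by averaging before the solve;
* **lowess** -- locally weighted first-order regression over the nearest
  25% of sites (tricube weights). The span is fixed at 0.25; a query with
  fewer than three in-span points falls back to the global first-order fit.
  Lowess smooths rather than interpolates, which damps MEP noise at the
  price of not returning training values at training sites.

The first three interpolate: they return the training value at every
training site (to numerical precision). Outside the convex hull of the
training sites the surface is *undefined* and evaluates to `NA` -- the map
was never sampled there, and no metric should silently extrapolate. All
downstream sums (surface area, volume integral, RMSE, ROC) exclude
undefined cells, and smoothing (lowess) values are used consistently
wherever that algorithm is selected.

## Map measurements

**Centre of gravity** is the MEP-weighted mean of the raw 3D positions
$\left(\sum_i x_i v_i / \sum_i v_i, \ldots\right)$ -- computed before any
fitting, as is the **peak** (absolute maximum; ties resolved to the lowest
event index). An all-zero map has no COG and raises an error.

**Surface area** and **volume integral** are discrete patch integrals on the
scalp model over a dense angular grid of spacing $s$ (default $\pi/512$
rad). For each grid cell whose value exceeds the threshold (strictly;
default 0), the corners $(\theta, \varphi)$, $(\theta + s, \varphi)$,
$(\theta, \varphi + s)$ are mapped through the ellipsoid, yielding edge
vectors $p, q$, and the cell contributes $\lVert p \times q\rVert$ to SA and
$\lVert p \times q\rVert \, v$ to VI. The cell *value* is sampled at the
cell centre: midpoint sampling makes the area of a thresholded region
converge at second order in $s$ (corner sampling would bias the boundary by
half a pixel). Doubling every map value leaves COG and SA unchanged and
exactly doubles VI.

**Peak discretization** splits multi-hotspot maps (common e.g. in cerebral
palsy) into one region per prominent local maximum: grid cells are flooded
in order of decreasing value, new regions start at unclaimed maxima, and
when two regions meet the shallower is merged unless its prominence (peak
minus meeting level) reaches `min_prominence` times the global maximum
(default 0.1). This persistence-gated watershed is deterministic and needs
no gradient estimates. Per-region COG/peak/SA/VI use only the region's
cells.

All positions are reported both absolutely and relative to a reference
point: the one imported with the dataset, or the head centroid when none is
given. Distances are in mm throughout (voxel spacing is applied on input).

## Comparing sessions

**Continuous**: both maps are fitted with the same algorithm; the report
contains per-axis and Euclidean COG and peak shifts, SA and VI differences
(second minus first), the difference surface on the overlap of the two
hulls, and the RMSE $\sqrt{\tfrac1N \sum_i (P_i - O_i)^2}$ between the raw
values of map A and map B's surface predictions at the same angular
locations. Raw points outside B's hull are dropped and counted; if nothing
overlaps, RMSE is reported as undefined rather than extrapolated -- two
maps sampled on different parts of the head have no likewise points.

**Categorical**: a probability-consolidated map fitted to a surface predicts
at every location the probability (0-100%) of evoking an MEP above the
binarization threshold. Testing events are binarized at the same microvolt
threshold, and for 1001 evenly spaced percentage cutoffs the model's
predictions are binarized as *predicted positive iff probability >= cutoff*
(so cutoff 0 predicts everything positive), tallied into the confusion
counts, and converted to $TPR = A/(A+C)$ and $FPR = 1 - D/(D+B)$. The curve
is forced through $(0,0)$ and $(1,1)$ and integrated by the trapezoidal
rule. AUC 1 means some cutoff reproduces the testing labels exactly, 0
means the model predicts their exact complement, 0.5 is chance. A testing
set that is all-positive or all-negative leaves TPR or FPR undefined and is
rejected with an explicit error.

## The synthetic world

Because vendor session files are proprietary and no public reference data
ships with the package, every pipeline stage is validated against synthetic
fixtures with known ground truth:

* `make_head_phantom()` -- a solid triaxial ellipsoid (default semi-axes
  80 x 95 x 70 mm in a 64^3 volume at 3.5 mm spacing, foreground intensity
  100) with optional additive Gaussian noise and its exact analytic mask.
* `make_gaussian_map()` -- a mapping session on the fitted phantom scalp: a
  square grid of sites at 5 mm spacing (the common 0.5 x 0.5 cm protocol)
  over a +/-25 mm patch, an MEP field falling off as a Gaussian of angular
  distance from a hotspot (peak 2000 microvolt; spatial sd 15 mm, a typical
  hand-muscle hotspot extent and comfortably above the grid's Nyquist
  limit), and 3 samples per site with multiplicative log-normal noise (CV
  0.1, mean-one) plus a 10 microvolt additive floor, clipped at zero. MEP
  noise distributions are not settled in the literature; these choices are
  declared, not claimed, and all randomness sits behind one seed. Site
  coordinates and field values are expressed in the *recovered* angular
  coordinates (see above) so ground truth and pipeline share one coordinate
  system.

What a green test establishes: projection, clustering, consolidation,
fitting, integration and comparison are mutually consistent and recover
known COG/peak/area/AUC ground truth under realistic grid spacing and MEP
variability. What it does not establish: anything about e-field physics,
real MEP amplitude distributions, segmentation of real MRI contrast, or
scalp-to-cortex mapping -- the phantom is geometric, and the head model is
the package's own projection surface.

## Limitations

* Angular projection distorts distances away from the equator; equator
  snapping mitigates but does not remove this.
* The scalp model is fitted to the full head-mask cloud and lies inside the
  scalp; areas are measured on this manifold, so SA/VI are comparable
  within a subject but are not literal scalp areas.
* Between-subject comparison is out of scope (it would require inter-head
  registration).
* The binarization threshold strongly conditions the ROC analysis; no
  recommendation is made for choosing it.
* Vendor binary exports are not parsed; data enter through the neutral CSV
  schema (`x_mm,y_mm,z_mm,mep_uv` plus an optional JSON sidecar).
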