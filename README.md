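# motormap

Quantification and comparison of motor cortex maps recorded with
neuronavigated transcranial magnetic stimulation (TMS).

A TMS mapping session yields stimulation events: 3D scalp coordinates in
scanner mm plus the peak-to-peak motor evoked potential (MEP) amplitude in
microvolt recorded from a target muscle. `motormap` is for researchers and
clinicians who need to turn those point sets into comparable map summaries —
tracking plasticity across sessions, hemispheres, or interventions within a
subject.

## What it computes

The stimulation sites conform to the scalp, so each event is reduced to two
angles about the head centroid *o*:

    theta = arccos((z - z_o) / ||p - o||),   phi = atan2(y - y_o, x - x_o)

The centroid and a back-projection surface come from the subject's
structural scan: the head is segmented, thinned to a point cloud (every 25th
foreground voxel), and a per-axis least-squares ellipsoid with a 4th-order
polynomial radial term (10 weights per axis) maps any `(theta, phi)` back to
3D mm.

Repeated stimulations are grouped by quality-threshold clustering
(normalized-distance threshold in [0, 1]) and consolidated per cluster:
mean / max / min / population variance / probability of exceeding a
binarization threshold (default 40 uV). A continuous surface
`v = S(theta, phi)` is then fitted with one of four non-parametric
algorithms (piecewise cubic, piecewise linear, biharmonic spline, 2D lowess
with span 0.25), and the map is summarized by:

* **COG** — MEP-weighted mean position, `sum(x_i v_i) / sum(v_i)` (raw data)
* **Peak** — position and value of the absolute maximum (raw data)
* **SA** — `sum ||p_i x q_i||` over grid patches above a threshold, mm^2
* **VI** — `sum ||p_i x q_i|| v_i`, uV·mm^2, a proxy for overall excitability
* **RMSE** — `sqrt(mean((P_i - O_i)^2))` between one session's raw values
  and the other session's surface
* **ROC/AUC** — how well a probability-consolidated map predicts a later
  session's binarized responses over a 0–100% cutoff sweep

plus per-hotspot measurements via watershed peak discretization, and
position reports relative to a reference point.

## Worked example

Two synthetic sessions on a head phantom, clustered, consolidated, measured
and compared:

```r
library(motormap)

phantom <- make_head_phantom()
mask    <- segment_head(phantom$scan)
head    <- fit_scalp_ellipsoid(sample_point_cloud(mask))

session1 <- make_gaussian_map(head, seed = 1)$map   # 121 sites x 3 repeats
session2 <- make_gaussian_map(head, seed = 2)$map

map1 <- consolidate(session1, qt_cluster(session1, 0.02), method = "average")
map2 <- consolidate(session2, qt_cluster(session2, 0.02), method = "average")

measure_map(map1, head, algorithm = "cubic")
#> Motor map measurements
#>   COG:  (168.41, 110.55, 110.17) mm  [58.56 mm from reference]
#>   Peak: 2172.6 uV at (170.86, 110.66, 115.29) mm  [61.22 mm from reference]
#>   SA (> 0 uV): 2843.67 mm^2
#>   VI: 2.55813e+06 uV mm^2   [cubic fit]
#>   reference (centroid_default): (109.85, 110.61, 110.23) mm

compare_maps(map1, map2, head, algorithm = "cubic")
#> Motor map comparison (cubic fit, B - A)
#>   dCOG:  (0.00, 0.08, -0.15) mm, |d| = 0.17 mm
#>   dPeak: (-0.25, 5.32, -0.00) mm, |d| = 5.32 mm
#>   dSA: 0.00 mm^2   dVI: 18387.7 uV mm^2
#>   RMSE: 72.389 uV (121 overlapping points)
```

The two sessions sample the same 2000 uV hotspot with 10% multiplicative
MEP noise, so the COG barely moves (0.17 mm), the peak — always the noisier
statistic — shifts 5.3 mm, and the RMSE (72 uV) reflects the per-site noise
level. Map stability in categorical terms:

```r
prob1 <- consolidate(session1, qt_cluster(session1, 0.02),
                     method = "probability", binarization_threshold = 200)
surf  <- fit_surface(project_events(prob1, head), algorithm = "linear")
roc_auc(surf, project_events(session2, head), binarization_threshold = 200)
#> <roc_result> AUC = 0.9967 (363 testing points, 0 dropped outside hull)
#>   binarization threshold: 200 uV
```

An AUC near 1 means session 1's probability map predicts session 2's
responses almost perfectly — the map is stable between the two recordings.

See `vignettes/motor-map-quantification.Rmd` for the model details, the
numerical choices, and what the synthetic fixtures do and do not establish.

## Acceptance script

```sh
Rscript scripts/acceptance.R --seed 1 --out results/acceptance.json
```

recomputes the package's reference quantities from scratch — the probability
consolidation worked examples and the ROC/AUC anchor cases (perfectly
consistent, complemented, and independent random testing labels) — by
running the package's own clustering, consolidation, surface-fitting and ROC
machinery, and writes them as JSON.
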