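Package: motormap
Title: Quantification and Comparison of TMS Motor Cortex Maps
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for quantifying and comparing maps of the human primary
    motor cortex obtained with neuronavigated transcranial magnetic
    stimulation (TMS). Stimulation events carrying 3D scalp coordinates and
    motor evoked potential (MEP) amplitudes are projected onto a 2D angular
    coordinate system through a polynomial ellipsoid fitted to the head
    segmentation of the subject's structural scan. Repeated stimulations are
    grouped by quality-threshold clustering and consolidated (mean, extrema,
    variance or response probability), continuous map surfaces are fitted
    with piecewise linear, piecewise cubic, biharmonic-spline or 2D lowess
    interpolators, and map features (centre of gravity, peak, thresholded
    surface area, volume integral, per-peak discretization) are measured on
    the fitted surface. Maps from the same subject can be compared
    continuously (feature deltas, difference grid, RMSE) or categorically
    (ROC curve and AUC of a probability map predicting a later session).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    interp,
    jsonlite,
    stats,
    utils,
    grDevices,
    graphics
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
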