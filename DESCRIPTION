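Package: pgafm
Title: Quantitative Analysis of Bacterial Peptidoglycan AFM Height Maps
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for quantifying the molecular architecture of the bacterial
    cell wall (peptidoglycan sacculi) from atomic force microscopy height maps.
    Implements an orientational order parameter for glycan chain alignment based
    on ellipse fitting to polar histograms of image gradient orientations,
    adaptive-threshold (Bradley) pore segmentation with area statistics, line
    profile metrics (full width at half maximum, peak spacing) for chain
    cross-sections, spherocylinder surface-fraction geometry, size exclusion
    chromatography calibration and fraction analysis, and a ground-truthed
    synthetic scanning-probe image simulator (linear features, Gaussian tip
    convolution, scan-line offsets, pixel noise) used to validate the whole
    pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    EBImage,
    graphics,
    jsonlite,
    stats,
    tiff,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
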