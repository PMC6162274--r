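Package: curvotaxis
Title: Quantification of Cell-Scale Curvature Sensing on Sinusoidal Landscapes
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Tools to synthesize and assay cell-scale sinusoidal curvature
    landscapes and to quantify how adherent cells read them. Provides
    parametric hills-and-valleys surface models with exact differential
    geometry (mean, Gaussian and principal curvature), areal surface
    metrology (degree-1 rectification, sinusoid form fitting with a
    residual shape statistic, high-pass filtering at a roughness cutoff,
    Sa), isoheight-band segmentation and nuclei-positioning statistics
    with Monte-Carlo and replicate-level tests, migration-trajectory
    analytics (speed by height, watershed basin assignment, valley-to-
    valley transition detection, cell-nucleus offset alignment), nuclear
    morphometrics from voxel masks (volume, iso-surface area, sphericity),
    and a biased persistent-random-walk simulator that generates synthetic
    curvotaxis imaging data so the whole pipeline is testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports: methods, stats, utils, tiff, jsonlite
Suggests: testthat (>= 3.0.0), knitr, rmarkdown
Config/testthat/edition: 3
RoxygenNote: 7.3.3
Collate: 
    'AllClasses.R'
    'AllGenerics.R'
    'curvotaxis-package.R'
    'io.R'
    'methods.R'
    'utils.R'
    'surface.R'
    'metrology.R'
    'morphometrics.R'
    'positioning.R'
    'simulate.R'
    'trajectory.R'
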