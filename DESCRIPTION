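Package: psatools
Title: Quantifying and Simulating the Pupil-Size Artefact in Video Eye Tracking
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for the pupil-size artefact (PSA), the spurious gaze
    deviation a pupil-based video eye tracker reports when the pupil changes
    size while the eye does not rotate. Provides a two-dimensional
    corneal-refraction ray-tracing model that simulates the optical,
    viewing-direction-dependent component of the artefact via a virtual
    look-up-table calibration; a quantification pipeline for gaze/pupil
    traces (pupil-speed filtering with gap padding, seven-point decile
    curves, artefact slopes in degrees per millimeter); a pupil-minus-CR
    gaze-estimation pipeline for monochrome eye images (thresholding,
    connected components, shape criteria, centers of mass, second-order
    polynomial calibration); and synthetic-data generators for traces and
    eye images with exact ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    igraph,
    png,
    stats,
    tibble,
    utils
Suggests:
    ggplot2,
    jsonlite,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
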