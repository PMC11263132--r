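Package: strain4d
Title: Four-Dimensional Ultrasound Strain Analysis of the Left Ventricle
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for quantifying left-ventricular mechanics from 4D
    (3D + time) ultrasound-derived surface meshes. Resamples sparse tracked
    boundary control points into a dense endocardial/epicardial mesh,
    computes circumferential (Green-Lagrange), longitudinal (engineering)
    and endocardial surface-area strain with systolic strain rates, maps
    peak strain onto the AHA 17-segment model, estimates infarct size from
    low-magnitude surface-area strain, derives volumetric function indices
    (ejection fraction, stroke volume, cardiac output) and peak dP/dt from
    pressure traces, and quantifies histological infarct size from labeled
    cross-section masks. Includes a contracting left-ventricle phantom
    generator with analytic ground truth for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    png,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
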