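Package: sfdiresponse
Title: Spatial Frequency Domain Imaging Analysis of Tumor Treatment Response
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulation and analysis pipeline for longitudinal spatial
    frequency domain imaging (SFDI) of murine tumors under chemotherapy.
    Generates raw structured-illumination image stacks for phantoms and
    three-arm treatment cohorts, demodulates and calibrates them into
    diffuse reflectance maps, inverts per-pixel optical properties through a
    two-frequency diffusion-model lookup table, fits scattering power-law and
    hemoglobin chromophore maps, assembles baseline-normalized longitudinal
    cohort tables, and models them with generalized estimating equations and
    linear discriminant classification to separate treatment-responsive from
    treatment-resistant tumors.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tiff,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    MASS,
    ggplot2
Config/testthat/edition: 3
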