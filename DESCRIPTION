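Package: dentinval
Title: Validation of Dentin-Caries Imaging Techniques
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Cross-validation of per-site histological scores of dentin
    reactions to caries across stereomicroscopy, microradiography and
    polarized light microscopy: one-vs-rest confusion matrices, accuracy,
    positive and negative predictive values, Cohen's kappa, arcsine
    (Cohen's h) effect sizes for proportions, and the temporary-gold-standard
    comparison. Includes gray-level photometry of histological sites
    (translucency and radiopacity indices, saturation QC, illumination
    heterogeneity fitting, Pearson correlation with adjusted R-squared) and
    synthetic-data generators for score tables and micrograph patches with
    known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    graphics,
    grDevices,
    minpack.lm,
    png,
    tiff,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    e1071,
    optparse
Config/testthat/edition: 3
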