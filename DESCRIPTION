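Package: plsinvert
Title: Inverse QSPR Modelling and Virtual Screening with GA-PLS
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Target-based virtual screening built on inversion of
    partial least squares (PLS) quantitative structure-property
    relationship models.  Provides descriptor pre-selection filters,
    Kennard-Stone train/test splitting, two-response NIPALS PLS with
    7-fold cross-validation, genetic-algorithm descriptor subset
    selection, applicability-domain diagnostics (leverage, Hotelling
    T-squared, DModX), constrained mixed-integer inversion of the
    fitted model toward reference drug properties, and ranking of
    candidate libraries by Euclidean distance to the inversion
    solution, optionally fused with docking-derived ranks.  Includes a
    synthetic data generator with known latent structure for
    end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    mixOmics,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
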