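Package: svdburden
Title: Latent Total Cerebral Small Vessel Disease Burden and Cognition
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Latent-variable modelling of total MRI-visible cerebral small
    vessel disease (SVD) burden and its associations with general and
    domain-specific cognitive abilities. Provides a calibrated synthetic
    cohort generator with mixed continuous, binary and ordinal markers;
    two-stage polychoric, polyserial and Pearson correlation estimation with
    asymptotic weights; a diagonally weighted least squares (WLSMV-style)
    structural equation modelling engine with a mean-and-variance adjusted
    test statistic, standardized solutions and regression factor scores;
    absolute fit indices (RMSEA, CFI, TLI, SRMR); the Williams test for
    dependent overlapping correlations and Benjamini-Hochberg false discovery
    rate control; and a pipeline that runs the full stepwise covariate grid,
    the orthogonal bifactor model of cognitive ability, and predictor
    comparisons, emitting publication-shaped report tables.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    pracma
Config/testthat/edition: 3
RoxygenNote: 7.3.3
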