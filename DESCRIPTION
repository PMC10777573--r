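Package: eruptcurve
Title: Age-Conditional Reference Centile Curves for Deciduous Tooth Eruption
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Construction of age-conditional reference centile curves for the
    number of erupted deciduous teeth in young children (12-36 months,
    gestational-age-corrected), using distributional regression (GAMLSS) with
    Box-Cox Cole-Green, Box-Cox t and Box-Cox power exponential response
    families, penalized B-spline smoothers for the distribution parameters,
    GAIC model selection, and residual diagnostics (normalized quantile
    residuals, worm plots, Q-statistics). Includes synthetic cohort generators
    calibrated to a published monthly reference table so the full pipeline is
    testable without access to the original cohort data, plus per-child
    screening of observed tooth counts against the fitted curve.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    splines,
    utils,
    grDevices,
    jsonlite,
    ggplot2
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
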