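Package: trcfit
Title: Thermal Response Curves for Freshwater Species Occurrence
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Fits per-species thermal response curves (probability of
    occurrence along a temperature gradient) with binomial quadratic-spline
    models, validates them by repeated split-sample AUC and true skill
    statistic, classifies curve shapes into eight response types
    (unimodal symmetric/skewed, flat, rise-plateau, plateau-decline,
    monotone), derives thermal tolerance statistics (preferred temperature,
    critical temperature, warming tolerance, safety margin), and maps
    projected-warming exposure across river catchments.  Includes a
    synthetic landscape and virtual-species generator so the whole
    pipeline is testable end to end, and a monthly logistic air-to-water
    temperature transform for deriving stream water temperature variables.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    splines,
    stats,
    graphics,
    grDevices,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
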