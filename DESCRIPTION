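Package: circannual
Title: Cosinor Models for Circannual Rhythms in Gene Expression and Blood Counts
Version: 0.1.0
Authors@R: person("Package", "Maintainer", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Detection and characterisation of annual (circannual) rhythms in
    molecular and haematological data. Fits per-feature cosinor models with a
    one-year period, optionally with subject- or family-level random
    intercepts, tests the effect of season by model comparison, classifies
    significant features as winter- or summer-expressed, identifies features
    seasonal across multiple cohorts by BIC model preference and Fisher's
    combined probability, and provides month-based and Fourier-harmonic
    seasonality models for full blood count tables. Includes a synthetic
    cohort generator with known ground truth so the whole pipeline is
    testable without access to any real cohort.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    splines,
    lme4,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
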