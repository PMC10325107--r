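Package: cropbirds
Title: Meta-Analysis of Bird Effects on Crops and Human-Bird Coexistence
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantitative workflow for synthesizing evidence on the coexistence
    of birds and humans in croplands. Computes bias-corrected Hedges' g effect
    sizes from bird-exclosure and crop-loss-mitigation experiments, fits
    multilevel (nested) random-effects meta-analytic models by restricted
    maximum likelihood with moderator and heterogeneity tests, runs a
    publication-bias suite (funnel data, Rosenthal fail-safe number, rank
    correlation, regression test, Duval-Tweedie trim-and-fill), grows
    conditional inference trees over effect-size direction, models survey
    proportions with binomial mixed models ranked and averaged by AICc, and
    builds gridded bivariate tercile prioritization maps of crop benefit and
    bird conservation value. Includes seeded generators for synthetic
    experiment, survey, and grid data so the whole pipeline is testable
    without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    lme4,
    stats,
    utils,
    jsonlite
Suggests:
    metafor,
    readxl,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
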