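Package: phytoshelf
Title: Shelf-Life Estimation for Cucurbitacin-Containing Phytonematicides
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Storage-stability analysis for cucurbitacin-based
    phytonematicides whose active-ingredient trajectories rise and then
    fall during storage and therefore do not conform to the monotone decay
    assumed by Arrhenius reaction-order models. Implements geometric
    (log base 3) time encoding, ordinary-least-squares quadratic and
    linear trajectory fits with relation classification, a
    parabola-symmetry shelf-life construction (extremum, roots, and the
    point where the fitted concentration returns to its initial level),
    integrated rate-law fits of order 0, 1, 2 and general n with an
    Arrhenius-conformity verdict, one-way ANOVA with percent
    total-treatment-variation, a replicate-level synthetic assay-data
    generator emulating the study design, and an end-to-end pipeline with
    a JSON report.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    jsonlite,
    stats,
    tibble,
    utils
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr,
    knitr
Config/testthat/edition: 3
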