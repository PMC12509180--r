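Package: factex
Title: Design, Simulation, Power, and Calibration for Multi-Site
    Factorial Consumer-Exclusion Experiments
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for planning and analysing multi-site randomized
    complete block experiments that factorially exclude plant consumers
    (insects, mollusks, and foliar fungal pathogens) with biocides.
    Builds balanced 2^3 factorial layouts, simulates hierarchical biomass
    and plant-community data with site, block, and plot variance
    components, estimates Monte-Carlo power for main, superadditive, and
    compensatory consumer effects with exact binomial confidence
    intervals, calibrates false-positive rates by within-block
    permutation, and fits the network's pre-registered per-site,
    cross-site, and context-dependency mixed models with stepwise
    interaction simplification.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    lme4,
    stats,
    utils
Suggests:
    optparse,
    pracma,
    testthat (>= 3.0.0),
    withr,
    yaml
Config/testthat/edition: 3
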