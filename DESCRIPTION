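Package: thermorates
Title: Evolutionary Rates of Plant Thermal Tolerance and Climatic Niche
Version: 0.1.0
Authors@R: person("Package", "Maintainer", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Phylogenetic comparative analysis contrasting evolutionary rates
    of plant physiological thermal tolerance (cold tolerance T_min, heat
    tolerance T_max) with the corresponding climatic-niche temperatures (MTCM,
    MTWM). Provides maximum-likelihood Brownian-motion rate estimation,
    likelihood-ratio tests of a common-rate model against separate rates for
    paired traits, fitting and AIC selection of Brownian motion,
    Ornstein-Uhlenbeck, Pagel's lambda and white-noise models, ancestral state
    reconstruction with per-species absolute rates and paired t-tests on log
    rates, phylogenetic generalized least squares regression, climatic-niche
    summarization from occurrence records, and a seeded synthetic-data
    generator (Yule trees, correlated traits, occurrence clouds on gridded
    climate surfaces) so the whole pipeline is testable at desk scale.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    ape,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    nlme,
    withr,
    jsonlite
Config/testthat/edition: 3
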