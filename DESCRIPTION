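Package: fragforage
Title: Optimal Reproductive Strategies of Parasitoids Foraging in
    Fragmented Habitats
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Individual-based, discrete-time simulation of parasitoid
    females foraging for hosts in fragmented habitats under a linear
    longevity-fecundity trade-off with costly phenotypic plasticity and
    linear-operator learning of the host encounter rate.  A steady-state
    (GENITOR-style) genetic algorithm finds, for any habitat
    configuration, the optimal strategy triplet: initial position on the
    trade-off, plasticity range, and memory factor.  Utilities build
    full-factorial habitat designs, batch-optimize them, and analyse the
    optimized strategies with factorial ANOVA and per-level trend
    summaries.  The within-patch dynamics follow a saturating-exponential
    gain curve with marginal-value-theorem patch leaving, modified by a
    remaining-lifespan rule.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils,
    graphics,
    grDevices
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0),
    yaml
Config/testthat/edition: 3
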