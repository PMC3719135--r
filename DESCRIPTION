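Package: grseval
Title: Evaluation of Genetic Risk Score Models Under Interaction and Linkage Disequilibrium
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulation framework for comparing genetic risk score (GRS)
    constructions in case-control studies. Implements the simple count,
    odds-ratio-weighted and explained-variance-weighted scores, a
    liability-threshold simulator with arbitrary product-interaction
    (epistasis) terms, a two-locus additive-penetrance simulator with a
    linked non-causal marker, an analytic heritability decomposition for
    binary traits (marginal and interaction components), and a
    replicate-based evaluation harness reporting power, type-I error,
    C-statistic, AIC and Tukey-adjusted pairwise method contrasts.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
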