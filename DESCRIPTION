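Package: phyloplast
Title: Comparative Phylogenetic Analysis of Larval Developmental Plasticity
    Under Pond Desiccation Risk
Version: 0.1.0
Authors@R:
    person("Package", "Maintainer", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for comparative analyses of amphibian larval development
    under contrasting desiccation risk. Provides derived developmental traits
    (developmental rate, mean growth rate), phenotypic-plasticity statistics
    (percent change and Hedges' d), phylogenetic generalized least squares
    under star and Grafen branch-length covariance structures compared by AIC
    and Akaike weights, a conservative soft-polytomy degrees-of-freedom
    correction for hypothesis tests, an end-to-end analysis pipeline over a
    phylogeny plus a tabular case dataset, and a synthetic-data generator
    (pure-birth trees, Brownian-motion traits with habitat-group effects,
    paired constant/drying treatments with group-dependent plasticity) used
    to validate the statistical machinery.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    ape,
    jsonlite,
    stats,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
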