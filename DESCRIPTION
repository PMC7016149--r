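Package: metanull
Title: Null-Model Inference of Metacommunity Assembly Processes
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Null-model chain for inferring microbial community-assembly
    processes from site-by-OTU tables sampled over time: elements of
    metacommunity structure (coherence, turnover, boundary clumping with
    reciprocal-averaging ordination and fixed-proportional 'r1' nulls),
    incidence-based Raup-Crick beta-diversity, quantitative process
    estimates combining a phylogenetic null (betaMNTD/betaNTI) with an
    abundance-based Raup-Crick null (beta_RCbray), permutation
    multivariate statistics (PERMANOVA, PERMDISP, Mantel, RDA with
    forward selection), and an attribution layer separating dispersal
    limitation from historical contingency and phylogenetically
    non-conserved selection. Includes a synthetic metacommunity
    generator with tunable selection, dispersal and drift so every
    stage can be validated against known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    ape,
    vegan,
    phytools,
    car,
    jsonlite,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    picante,
    biomformat
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
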