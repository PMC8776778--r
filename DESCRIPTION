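Package: overlapnet
Title: Resource-Niche-Overlap Networks for Microbial Communities
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Builds directed resource-competition networks from isolate-by-substrate
    growth matrices (Biolog-style phenotype arrays) via a directed, asymmetric
    niche-overlap statistic; computes node-, triad-, and network-level structural
    metrics; tests for higher-order interactions with a degree-preserving
    configuration-model randomization; and compares network structure across
    kingdoms and nutrient treatments with Welch tests and multiple-testing
    correction. Includes a synthetic-data generator emulating endophytic
    bacterial-fungal communities under NPK nutrient amendment.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    igraph,
    Rcpp,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
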