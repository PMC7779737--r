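Package: clusterbench
Title: Benchmarking Spatial Cluster Detection Methods for Rare Disease
    Incidence
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Simulation toolkit for evaluating spatial cluster detection
    methods on rare-disease incidence data at the administrative-district
    level. Generates random connected high-risk clusters on a district
    adjacency graph, simulates Poisson-distributed ten-year case counts
    under elevated relative risk, runs three detection methods (the
    Besag-Newell local test, the Kulldorff circular spatial scan statistic
    with Monte Carlo inference, and the Besag-York-Mollie disease-mapping
    model with an intrinsic CAR spatial effect fit by MCMC), and scores
    them with a full battery of performance measures (sensitivity,
    specificity, predictive values, exact and minimum power, correct
    classification, diagnostic likelihood ratios and Monte Carlo errors).
    Includes a synthetic lattice geography generator emulating the German
    district system so the whole pipeline runs without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    geosphere,
    graphics,
    igraph,
    jsonlite,
    Rcpp,
    stats,
    tools,
    utils,
    yaml
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
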