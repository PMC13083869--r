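Package: ecoassemble
Title: Eco-Evolutionary Assembly of Ecological Communities with Multiple
    Interaction Types
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Step-wise assembly of ecological communities under generalized
    Lotka-Volterra dynamics with mutualistic, competitive and
    consumer-resource interactions, Type II functional responses, and a
    per-link harvesting cost. New species enter either by evolutionary
    speciation (inheriting the parent's interactions with a bounded number
    of changes) or by invasion with random interaction types. Includes a
    mean-field cost-benefit threshold analysis for mutualistic link
    acquisition, network-structure metrics (connectance, degree entropy,
    modularity) scored against Erdos-Renyi null models, and stochastic
    (Euler-Maruyama) abundance time series with macroecological statistics
    (standardised log-mean abundance distributions, pairwise correlations,
    Wasserstein distances) for comparison against microbial community
    abundance tables.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    deSolve,
    dplyr,
    generics,
    ggplot2,
    graphics,
    igraph,
    jsonlite,
    purrr,
    Rcpp,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
LinkingTo:
    Rcpp
Suggests:
    optparse,
    pracma,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
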