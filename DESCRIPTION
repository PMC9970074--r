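Package: sdmnet
Title: Skills Network Analysis of Shared Decision Making Competence
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Estimates directed skills networks from consultation-level
    physician self-ratings of shared decision making (SDM) skills and uses
    network parameters to predict observer-rated SDM competence. For each of
    the nine SDM-Q-Doc skills a Bayesian multilevel linear regression with
    physician-varying intercept and slopes is fitted via MCMC (JAGS); the
    physician-specific coefficients become edge weights of a directed
    nine-node network, pruned by 95% credible intervals. Node parameters
    (activation, instrength, outstrength) enter confirmatory and exploratory
    Bayesian regressions of observer competence scores (OPTION-12, OPTION-5,
    4HCS). Includes an expectation-maximization imputation step for
    item-level missingness, a synthetic-data generator with analytic ground
    truth for validation, and file-based pipeline orchestration.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    rjags,
    coda,
    igraph,
    jsonlite,
    yaml,
    MASS,
    stats,
    utils,
    tools,
    grDevices,
    graphics
Suggests:
    testthat (>= 3.0.0),
    optparse,
    xml2
Config/testthat/edition: 3
RoxygenNote: 7.3.3
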