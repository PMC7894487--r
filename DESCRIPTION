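Package: natdiv
Title: Diversification Rates and the Naturalization Success of Plant Families
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Family-level analysis of plant naturalization success. Builds
    diversification-rate (method-of-moments stem estimator), range-size and
    horticultural-use predictors from species-level checklists, and fits
    Bayesian phylogenetic generalized linear mixed models (PGLMMs) with a
    Gibbs sampler using inverse-Wishart variance priors. Includes
    Gelman-Rubin convergence diagnostics, effective sample sizes, DIC-based
    stepwise model selection, an order-level GLMM validation variant, and a
    synthetic-data generator with known ground truth for end-to-end testing.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    ape,
    jsonlite,
    stats,
    utils,
    Rcpp
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    coda,
    withr,
    yaml
Config/testthat/edition: 3
RoxygenNote: 7.3.3
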