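Package: dcbnet
Title: Dynamic Copula Bayesian Networks for Longitudinal Household Panels
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for building, learning and checking dynamic Bayesian
    networks whose conditional dependencies are bivariate copulas with
    time-slice specific parameters. Provides a registry of bivariate copula
    families with Kendall tau parameter maps, probability-integral and
    distributional transforms for mixed ordinal data, tie-corrected (and
    weighted) Kendall rank correlation, BIC-scored greedy structure search
    over initial and transition graphs, tau-initialised local optimisation
    and Metropolis MCMC for edge parameters with convergence and posterior
    predictive diagnostics, goodness-of-fit metrics (AIC, BIC, RMSE, NSE,
    NRMSE, MAE/SD), selection and spillover adjustments (stabilised inverse
    probability weights, standardised mean differences, leave-one-out
    community program intensity, community-block bootstrap), and a synthetic
    longitudinal panel generator emulating a household survey with program
    participation, food security, wealth, mother wellbeing and child
    undernutrition processes.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    igraph,
    jsonlite,
    pracma,
    Rcpp,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
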