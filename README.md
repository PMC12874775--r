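# dcbnet — dynamic copula Bayesian networks for longitudinal household panels

`dcbnet` is an R toolkit for mapping time-varying dependence among ordinal
and binary processes observed in longitudinal panels — the setting of
program-evaluation surveys where household program participation, food
security, wealth, mother wellbeing and child undernutrition interact over
survey waves. It is aimed at biostatisticians and epidemiologists who want a
probabilistic *dependence map* rather than a single-exposure causal model.

## The model

The joint density of processes replicated over time slices factorises as

    P(x^(0:T)) = P(x^(0)) * prod_t P(x^(t) | x^(t-1))

with an initial DAG G0 over slice 0 and a transition DAG G→ whose edges run
within a slice or from slice t−1 to t (including autoregressive self-loops).
Every edge's conditional is a bivariate copula with slice-specific parameters
θ_t, evaluated on pseudo-uniform values produced by the probability integral
transform (continuous scales) or the distributional transform (ordinal/binary
scales, with correct tie handling). Dependence is summarised with
tie-corrected Kendall τ-b, which maps in closed form to copula parameters for
many families and supplies the estimation initialiser.

The package provides:

* a registry of ten bivariate copula families (Gaussian, Clayton, Frank,
  Gumbel, Joe, Ali–Mikhail–Haq, Marshall–Olkin, Raftery, Roch–Alegre,
  independence) with CDF, density, conditional h-function, sampler and
  Kendall-τ maps behind one contract;
* structure learning by greedy hill-climbing under the decomposable BIC
  score `loglik − 0.5·log(K)·|Θ|`, learned separately for G0 (K = sequences)
  and G→ (K = transitions), with restarts and time-slice constraints;
* per-edge estimation by τ-initialised multi-restart local optimisation and
  by random-walk Metropolis MCMC (posterior medians, 95% credible intervals,
  split-R̂ / ESS diagnostics, posterior-predictive τ checks), plus family
  selection by log-likelihood, AIC or BIC;
* goodness-of-fit metrics (AIC, BIC, RMSE, NSE, NRMSE = RMSE/SD, MAE/SD) with
  conditional-mean edge prediction;
* selection/spillover adjustments: stabilised inverse-probability weights,
  standardised-mean-difference balance diagnostics, leave-one-out community
  program intensity, community-block bootstrap;
* a synthetic longitudinal panel generator emulating the study structure
  (printed participation margins, slice-specific copula-linked dependence,
  persistence, community clustering, calibrated baseline confounding), so
  the whole pipeline is testable without access-controlled data.

## Worked example

```r
library(dcbnet)

# a synthetic five-wave household panel at the default study-like conditions
panel <- generate_panel(synthetic_config(n_units = 2000, seed = 7))

# Kendall tau trajectory of one program edge across analysis waves
tau_trajectory(panel, c("PS", "FS"))
#>   wave       tau    n        z p_value stars
#> 1 2009 0.6129036 2000 41.07887       0   ***
#> 2 2013 0.7444497 2000 49.89554       0   ***
#> 3 2016 0.7155608 2000 47.95931       0   ***

# learn the dynamic structure under the canonical candidate template
res <- learn_dynamic_structure(panel, study_fixture(), restarts = 3, seed = 7)
structure_f1(res$dag, study_fixture())$f1
#> [1] 0.969697

# fit one edge: family selection, local + Bayesian estimates, diagnostics
uv <- sample_copula(theta_from_tau("joe", 0.5), 2000, seed = 7)
ef <- fit_edge(uv[, 1], uv[, 2], seed = 7,
               mcmc_chains = 2, mcmc_draws = 1500, mcmc_adapt = 500)
ef
#> <edge fit> family: joe
#>   local: theta = 2.7545 (loglik 851.49, tau 0.486)
#>   MCMC median: theta = 2.7621 (tau 0.487, max R-hat 1.0005)
```

The τ trajectory shows per-wave rank dependence with significance stars at
the 10/5/1% levels (the marginal τ of an edge embedded in a network includes
indirect paths, hence values above the single-edge generator targets). The
structure F1 compares learned and planted edge sets; 0.97 here corresponds to
recovering all edges except one weak persistence link. In the edge fit, the
family selection identifies the generating Joe copula, the local optimum and
the posterior median agree to two decimals, and the τ-equivalent (0.487)
sits within sampling error of the generating value 0.5.

A command-line front end covering the same pipeline ships in
`inst/cli/dcbn.R` (subcommands `simulate`, `learn-structure`, `fit`,
`tau-table`, `adjust`, `report`).

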