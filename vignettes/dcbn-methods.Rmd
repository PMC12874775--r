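---
title: "Dynamic copula Bayesian networks: models, estimation and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Dynamic copula Bayesian networks: models, estimation and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dcbnet)
```

## The model

`dcbnet` implements dynamic Bayesian networks whose conditional dependencies
are bivariate copulas with time-slice-specific parameters. A set of processes
(in the package's motivating application: household program-participation
status PS, food security FS, wealth quantile WQ, mother subjective wellbeing
MSW and child undernutrition status CUS) is replicated over time slices
$t = 0, \dots, T$, and the joint density factorises as

$$P(x^{(0:T)}) = P(x^{(0)}) \prod_{t=1}^{T} P(x^{(t)} \mid x^{(t-1)}),$$

with an initial graph $\mathcal{G}_0$ over slice 0 and a transition graph
$G_\rightarrow$ whose edges run either within a slice or from slice $t-1$ to
$t$ (autoregressive persistence edges such as $\mathrm{FS}_{t-1} \to
\mathrm{FS}_t$). Feedback is allowed across time; each slice must stay
acyclic. Every edge's conditional is a bivariate copula density
$c_\theta(F(x_{\mathrm{pa}}), F(x_{\mathrm{child}}))$ evaluated on
pseudo-uniform values, with a separate parameter $\theta_t$ per analysis
slice, so non-stationary dependence is a first-class feature rather than a
violation.

Because the study variables are ordinal or binary, observations are mapped to
$[0,1]$ by the probability integral transform for continuous scales and by
the *distributional transform* $U = F(x^-) + V\,(F(x) - F(x^-))$,
$V \sim \mathrm{Uniform}(0,1)$, for discrete scales, which is the standard
randomised tie-handling device that makes copula likelihoods valid for tied
data.

### Multi-parent nodes

A child with several parents is treated edge-wise: its likelihood
contribution is the sum of bivariate copula log-likelihoods, one per parent
edge, and reporting is per edge. This matches the way the per-edge dependence
estimates are interpreted downstream, keeps the score decomposable (which the
search exploits), and avoids committing to a particular multivariate copula
for which the bivariate catalogue gives no guidance. The cost is that the
initial-slice density is not a single normalised joint for multi-parent
configurations; we consider this the right trade-off for a dependence-mapping
tool and flag it prominently here.

## The copula catalogue

The registry implements ten families behind one contract (CDF, density,
h-function $h(v \mid u) = \partial C / \partial u$, sampler, Kendall-$\tau$
maps, declared parameter domain): independence, Gaussian, Clayton, Frank,
Gumbel, Joe, Ali–Mikhail–Haq, Marshall–Olkin, Raftery and Roch–Alegre. Two
deserve notes:

* **Roch–Alegre** is the two-parameter Archimedean family with generator
  $\varphi(t) = ((1 - \ln t)^{\theta_1} - 1)^{\theta_2}$, $\theta_1 > 0$,
  $\theta_2 \ge 1$ (the published two-parameter catalogue form); density and
  conditional follow from the generic Archimedean identities implemented once
  for all generator families.
* **Marshall–Olkin** has a singular component on the curve
  $u^{\theta_1} = v^{\theta_2}$. `copula_density()` returns the absolutely
  continuous part; consistency tests against finite differences of the CDF
  mask a band around the singular curve, and its $\tau$ uses the closed form
  $\theta_1\theta_2 / (\theta_1 + \theta_2 - \theta_1\theta_2)$.

Kendall's $\tau$ uses closed forms where they exist (Gaussian
$\tfrac{2}{\pi}\arcsin\rho$; Clayton $\theta/(\theta+2)$; Gumbel $1 - 1/\theta$;
Frank via the Debye function; AMH's logarithmic form; Raftery
$2\theta/(3-\theta)$; Marshall–Olkin as above). Families without a closed form
(Joe, Roch–Alegre) use the Archimedean identity
$\tau = 1 + 4\int_0^1 \varphi(t)/\varphi'(t)\,dt$ by adaptive quadrature; the
generic non-Archimedean fallback integrates $4\,E[C(U,V)] - 1$ by
Gauss–Legendre quadrature split along the diagonal, because the Raftery-type
densities have a ridge on $u = v$ where a single product rule converges
poorly.

**$\tau$-inversion for two-parameter families.** The estimation initialiser
needs one point on the $\tau$ level set. Pinning the second parameter at its
domain midpoint leaves much of the $\tau$ range unreachable (for
Marshall–Olkin the midpoint caps $\tau$ at 0.5; for Roch–Alegre it leaves
only $\tau \gtrsim 0.75$), so the package instead inverts Marshall–Olkin on
the symmetric diagonal $\theta_1 = \theta_2 = 2\tau/(1+\tau)$ (covering
$\tau \in (0,1]$) and pins Roch–Alegre's $\theta_2 = 1.2$ (covering
$\tau \in [-0.12, 0.78]$). The optimisers still explore the full 2-D domain.

**Boundary handling.** Empirical pseudo-observations can hit 0 or 1 exactly,
where most densities are undefined; evaluation clamps such values to
$10^{-10}$ inside the interval and warns. Continuous empirical CDFs are
rescaled by $n/(n+1)$ so transforms never reach 1.

## Structure learning

Structures are scored with the graph form of BIC,
$\mathrm{score}(\mathcal{G} : \mathcal{D}) = \ell(\mathcal{D} : \hat\theta,
\mathcal{G}) - \tfrac12 \log(K)\,|\Theta_\mathcal{G}|$, higher is better,
where $\ell$ is the maximised edge-wise copula log-likelihood plus marginal
terms, $K$ is the number of sequences when learning $\mathcal{G}_0$ and the
total number of transitions when learning $G_\rightarrow$, and
$|\Theta_\mathcal{G}|$ counts free copula parameters (not edges — the
difference matters for two-parameter families, and parameters are what the
likelihood actually spends). The two parts are learned separately and their
scores add.

The search is greedy hill-climbing with add/delete/reverse moves restricted
to a constraint template, multiple restarts (the first from the empty graph,
the rest from random subgraphs with edge-inclusion probability 0.3), a
within-slice in-degree cap of 3 per child (persistence self-loops are exempt
— the canonical study graph itself gives the undernutrition node three
within-slice parents plus its own lag), and two numerical safeguards worth
stating:

* per-edge contributions are cached under the *unordered* variable pair for
  within-slice edges — the search catalogue families are exchangeable, so the
  two orientations share one likelihood and orientation ties resolve
  deterministically toward the template orientation rather than by optimiser
  round-off;
* a move must improve the score by at least $10^{-2}$ to be accepted, which
  absorbs restart-to-restart optimiser noise (genuine edges at the study's
  scale contribute tens to hundreds of log-likelihood units).

An AIC variant (`score = "aic"`) and a pure-likelihood variant
(`score = "none"`) are provided for sensitivity checks.

## Parameter estimation

Each edge is estimated twice:

* **Local**: bounded quasi-Newton (`L-BFGS-B`) from the Kendall-$\tau$
  inversion of the empirical $\tau$ plus uniform random restarts over the
  family's working domain (default 100 restarts in `local_fit()`; the search
  uses fewer because its edges are refit many times).
* **Bayesian**: random-walk Metropolis on a logit-transformed parameter scale
  with a uniform prior over the working domain (unbounded natural domains are
  truncated at numerically safe bounds, e.g. Joe $\theta \in [1, 50]$).
  Proposals are componentwise for two-parameter families; step sizes adapt
  toward 20–40% acceptance during warmup and then freeze. Defaults are 4
  chains × 2000 draws after 500 warmup iterations; the bundled tests and the
  acceptance script use 2 chains × 1500 draws for the recovery loops and
  2 × 6000 draws where the strict $\hat R < 1.01$ threshold is asserted,
  because split-$\hat R$ at effective sample sizes of a few hundred
  fluctuates by roughly $\pm 0.01$ even on perfectly mixed chains.

Convergence is summarised by split-$\hat R$ and an autocorrelation-based
effective sample size; the posterior predictive check `ppc_tau()` simulates
replicate data sets from posterior draws and passes when the observed
Kendall $\tau$ falls inside the central 95% predictive interval. Reporting
follows the Bayesian posterior median with a 95% credible interval; local
estimates are retained as diagnostics. Family selection refits a catalogue
per edge and ranks by log-likelihood, AIC or BIC with ties broken toward
fewer parameters.

Edge-level prediction (needed for RMSE/NSE-style skill metrics) uses the
conditional mean $\hat v(u) = E[V \mid U = u] = \int_0^1 (1 - h(v \mid u))\,
dv$ by Gauss–Legendre quadrature, on the pseudo-observation scale. The
conditional *median* would be an equally defensible rule; the choice is
isolated behind `predict_edge()` so it can be swapped. AIC and BIC follow the
standard $-2\ell + 2k$ and $-2\ell + k\log n$ with $\ell$ a log-likelihood
(the literal "likelihood" reading would be dimensionally inconsistent);
NRMSE and MAE/SD normalise by the $n-1$ standard deviation of the observed
values.

## Selection and spillover adjustments

* `stabilized_ipw()` fits a main-effects logistic propensity model on
  pre-program covariates and returns stabilised weights
  $P(A=a)/P(A=a \mid X)$, with optional symmetric percentile truncation
  (default: none; `c(0.01, 0.99)` is the suggested option). Near-perfect
  separation is refused with advice rather than silently producing extreme
  weights.
* `balance_smd()` reports standardised mean differences (weighted moments
  under weights) with Wilcoxon rank-sum p-values as the rank-based companion
  diagnostic.
* `cpi_leave_one_out()` computes the leave-one-out community program
  intensity — the share of *other* households in a unit's community
  participating in any program at a wave ("any" meaning participation
  category different from the control level); singleton communities are
  flagged missing.
* `community_block_bootstrap()` resamples whole communities with replacement
  and reports percentile intervals. Percentile (not BCa) is the deliberate
  default: simplest defensible choice, and the statistics bootstrapped here
  (rank correlations over hundreds of units) are close to median-unbiased.
  Weighted Kendall's $\tau$ uses pairwise weight products with weighted tie
  corrections (reducing exactly to $\tau$-b at unit weights); its
  significance comes from the block bootstrap because weighting invalidates
  the normal-approximation variance.

## The synthetic panel generator

`synthetic_config()` / `generate_panel()` emulate the statistical structure
the network assumes, not any particular real data set: 1900 households (the
approximate cohort size of the motivating survey) in 20 communities (its
sentinel-site count), two pre-program baseline waves plus three analysis
waves, program-participation categories drawn from the printed per-wave
margins of `table1_fixture()` (normalised — the printed 2013/2016 columns sum
to 99.4% and 100.3% by rounding; the fixture stores the cells verbatim and
computes aggregates from cells, which is also why only the 2009 aggregate
rows are asserted exactly), slice-specific edge dependence at the printed
temporal-edge $\tau$ values and persistence at the printed self-loop values.
The two pre-program transitions, which no table covers, use a moderate
persistence of $\tau = 0.5$. Default edge copulas are Gaussian because the
printed $\tau$ ladder spans strong positive and negative values that no
single Archimedean family in the catalogue attains.

Child variables are generated on the latent uniform scale by successive
h-function inversion along parent edges (persistence innermost, the
first-declared within-slice parent outermost) and then discretised through
declared marginals; the latent values, not the discretised categories, feed
child conditionals. Consequences worth understanding when reading test
results:

* a single-parent edge's $\tau$ target holds exactly on the latent scale and
  within discretisation attenuation on the observed scale;
* with multiple parents, inner couplings are attenuated by outer ones, and
  marginal pairwise $\tau$'s include indirect paths — the default
  configuration's observed trajectories therefore do *not* reproduce the
  printed table values cell-by-cell, and recovery tests use single-parent
  configurations where the target is well-defined;
* undernutrition is emitted in eight anthropometric states (normal,
  underweight, stunted, wasted and combinations) ordered as declared and
  collapsed to binary by "any condition", count-preservingly.

What passing tests on these panels show about real data: that the estimators
recover the *kind* of structure the model class assumes (copula-linked
ordinal processes with persistence and clustering). They do not exercise
informative attrition, survey weights, measurement error or geography, all of
which the generator deliberately omits.

`baseline_covariates()` attaches standardised pre-program covariates whose
participant/non-participant standardised mean difference is calibrated to a
target (default 0.18, the strongest imbalance the motivating study reports),
enabling the IPW and balance suites to operate at realistic confounding
strength.

## Problem sizes and numerical choices

The bundled tests and `scripts/acceptance.R` run at sizes chosen to make
sampling noise small relative to the asserted tolerances: $n = 10^4$ pairs
for Monte-Carlo $\tau$ agreement (three standard errors $\approx 0.02$),
$n = 2000$ units for estimation and structure recovery, $n = 20{,}000$ for
null-confounding balance checks (an SMD's sampling SE is $\approx
\sqrt{1/n_1 + 1/n_0}$, and a maximum over six covariates is an extreme-value
statistic — at $n = 2000$ a $\pm 0.05$ band would be violated by
chance alone about a quarter of the time), and 40–100 trials at $B = 150$ for
bootstrap coverage. Quadrature uses 32–64-point Gauss–Legendre rules;
conditional-CDF inversion uses 60 bisection iterations (bracket width
$2^{-60}$), which also yields the generalised inverse for conditionals with
atoms.

## Known limitations

* Multi-parent conditionals are edge-wise compositions, not joint copulas;
  the initial-slice "copula ratio" for multi-parent nodes is therefore not a
  normalised multivariate object.
* Ordered-logit marginals are not implemented; empirical CDFs cover the
  ordinal scales used here.
* Missing data are handled by pairwise deletion within each edge, with no
  imputation.
* The Metropolis sampler is adequate for 1–2 parameter posteriors but no
  substitute for gradient-based samplers in higher dimensions.
* Structure search explores a constraint template, not the unrestricted DAG
  space; reversals of lagged edges are never proposed (time orients them).
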