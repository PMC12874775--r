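# Edge parameter estimation: likelihood evaluation, tau-initialised local
# optimisation, Metropolis MCMC with diagnostics, posterior predictive tau
# checks, and family selection.

test_that("edge log-likelihood sums per-point log densities", {
  u <- c(0.2, 0.5, 0.8); v <- c(0.3, 0.6, 0.7)
  expect_equal(edge_loglik(u, v, copula_params("independence")), 0)
  p <- copula_params("gaussian", 0.5)
  expect_equal(edge_loglik(u, v, p), sum(log(copula_density(p, u, v))))
  expect_equal(edge_loglik(u, v, p, weights = rep(2, 3)),
               2 * edge_loglik(u, v, p))
  # invariant to simultaneous permutation
  o <- c(3, 1, 2)
  expect_equal(edge_loglik(u[o], v[o], p), edge_loglik(u, v, p))
})

test_that("local fit recovers a planted Clayton parameter", {
  hits <- 0
  for (seed in 1:10) {
    d <- copula_pseudo("clayton", 0.5, 2000, seed)  # theta = 2
    fit <- local_fit(d$u, d$v, "clayton", restarts = 5, seed = seed)
    if (fit$params$theta >= 1.7 && fit$params$theta <= 2.3) hits <- hits + 1
  }
  expect_gte(hits, 9)
})

test_that("local fit honours its contract edge cases", {
  d <- copula_pseudo("gaussian", 0.4, 300, 2)
  fit0 <- local_fit(d$u, d$v, "independence")
  expect_equal(fit0$loglik, 0)
  expect_length(fit0$params$theta, 0)
  f1 <- local_fit(d$u, d$v, "gaussian", restarts = 1, seed = 3)
  f10 <- local_fit(d$u, d$v, "gaussian", restarts = 10, seed = 3)
  expect_gte(f10$loglik, f1$loglik)
  expect_error(local_fit(d$u[1:5], d$v[1:5], "gaussian"), "at least 10")
  # determinism
  expect_equal(local_fit(d$u, d$v, "joe", restarts = 5, seed = 9)$params$theta,
               local_fit(d$u, d$v, "joe", restarts = 5, seed = 9)$params$theta)
})

test_that("MCMC covers the generating parameter and matches the local fit", {
  inside <- 0; close_tau <- 0; in_cri <- 0
  for (seed in 1:10) {
    d <- copula_pseudo("gaussian", tau_from_theta(copula_params("gaussian", 0.6)),
                       2000, seed)
    # chains are kept short here, so the strict R-hat threshold can trip on
    # sampling noise; convergence at full length is checked elsewhere
    mc <- suppressWarnings(
      mcmc_fit(d$u, d$v, "gaussian", n_chains = 2, n_draws = 400,
               n_adapt = 250, seed = seed))
    loc <- local_fit(d$u, d$v, "gaussian", restarts = 5, seed = seed)
    if (mc$cri_95[1, 1] <= 0.6 && 0.6 <= mc$cri_95[2, 1]) inside <- inside + 1
    if (abs(mc$tau - loc$tau) <= 0.02) close_tau <- close_tau + 1
    if (loc$params$theta >= mc$cri_95[1, 1] &&
        loc$params$theta <= mc$cri_95[2, 1]) in_cri <- in_cri + 1
  }
  expect_gte(inside, 9)
  expect_gte(close_tau, 9)
  expect_gte(in_cri, 9)
})

test_that("identical seeds give identical chains and near-unit R-hat", {
  d <- copula_pseudo("clayton", 0.4, 400, 5)
  run <- function() mcmc_fit(d$u, d$v, "clayton", n_chains = 2, n_draws = 300,
                             n_adapt = 200, seed = 44)
  a <- run(); b <- run()
  expect_identical(a$draws, b$draws)
  expect_true(all(abs(a$diagnostics$rhat - 1) < 0.05))
  expect_true(a$diagnostics$acceptance_rate > 0.05 &&
              a$diagnostics$acceptance_rate < 0.95)
  expect_true(all(a$cri_95[1, ] <= a$posterior_median$theta &
                  a$posterior_median$theta <= a$cri_95[2, ]))
})

test_that("posterior predictive tau check passes when well specified and fails when not", {
  d <- copula_pseudo("gaussian", 0.5, 1000, 3)
  mc <- mcmc_fit(d$u, d$v, "gaussian", n_chains = 2, n_draws = 300,
                 n_adapt = 200, seed = 3)
  obs <- kendall_tau_b(d$u, d$v)$tau
  passes <- 0
  for (seed in 1:20) {
    pp <- ppc_tau(mc$draws, "gaussian", n_rep = 120, n_obs = 300,
                  observed_tau = obs, seed = seed)
    if (pp$pass) passes <- passes + 1
  }
  expect_gte(passes, 19)
  # grossly mis-specified tau (offset 0.5) must fail
  pp_bad <- ppc_tau(mc$draws, "gaussian", n_rep = 120, n_obs = 300,
                    observed_tau = obs - 0.5, seed = 1)
  expect_false(pp_bad$pass)
  expect_error(ppc_tau(mc$draws, "gaussian", n_rep = 0, n_obs = 100,
                       observed_tau = 0, seed = 1), "at least 100")
})

test_that("posterior draws export as long-format delimited text", {
  d <- copula_pseudo("gaussian", 0.4, 300, 8)
  mc <- suppressWarnings(mcmc_fit(d$u, d$v, "gaussian", n_chains = 2,
                                  n_draws = 100, n_adapt = 100, seed = 8))
  path <- tempfile(fileext = ".csv")
  write_posterior_draws(mc, path)
  tab <- utils::read.csv(path)
  expect_equal(nrow(tab), 200)
  expect_setequal(names(tab), c("chain", "draw", "parameter", "value"))
  expect_equal(sort(unique(tab$chain)), 1:2)
  expect_equal(stats::median(tab$value), unname(mc$posterior_median$theta))
})

test_that("family selection recovers the generator and prefers parsimony", {
  cat4 <- c("gumbel", "clayton", "frank", "gaussian")
  hits <- 0
  for (seed in 1:10) {
    d <- copula_pseudo("gumbel", 0.5, 2000, seed)  # theta = 2
    rk <- select_family(d$u, d$v, cat4, criterion = "aic", restarts = 3,
                        seed = seed)
    if (rk$family[1] == "gumbel") hits <- hits + 1
  }
  expect_gte(hits, 8)
  # independent data: the parameter-free independence family wins by BIC
  wins <- 0
  for (seed in 1:10) {
    uv <- sample_copula(copula_params("independence"), 800, seed = seed)
    rk <- select_family(uv[, 1], uv[, 2],
                        c("independence", "gaussian", "frank"),
                        criterion = "bic", restarts = 3, seed = seed)
    if (rk$family[1] == "independence") wins <- wins + 1
  }
  expect_gte(wins, 9)
  d <- copula_pseudo("gaussian", 0.3, 200, 1)
  expect_equal(select_family(d$u, d$v, "gaussian")$family, "gaussian")
  expect_error(select_family(d$u, d$v, character(0)), "empty")
})

test_that("the full edge-fit record combines selection, estimation and skill", {
  d <- copula_pseudo("clayton", 0.5, 800, 17)
  ef <- fit_edge(d$u, d$v, catalogue = c("clayton", "gaussian", "frank"),
                 restarts = 3, seed = 17, mcmc_chains = 2, mcmc_draws = 300,
                 mcmc_adapt = 200, ppc_rep = 120, edge_label = "X -> Y")
  expect_s3_class(ef, "edge_fit")
  expect_equal(ef$family, "clayton")
  expect_within(ef$mcmc$tau, 0.5, 0.05)
  expect_within(ef$tau_local, 0.5, 0.05)
  expect_true(ef$ppc$pass)
  expect_true(ef$metrics$nse <= 1 && ef$metrics$rmse >= 0)
})
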