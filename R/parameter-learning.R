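# Per-edge copula parameter estimation: tau-initialised multi-restart local
# optimisation (quasi-Newton on the bounded working domain) and random-walk
# Metropolis MCMC on a logit-transformed parameter scale with a uniform prior
# over the working domain.  MCMC is the primary estimate for reporting; the
# local optimum is retained as a diagnostic.

#' Copula log-likelihood of pseudo-observations
#'
#' @param pseudo_u,pseudo_v equal-length vectors strictly inside `(0, 1)`.
#' @param params a [copula_params()] object.
#' @param weights optional non-negative observation weights.
#' @return the (weighted) sum of log copula densities.
#' @export
edge_loglik <- function(pseudo_u, pseudo_v, params, weights = NULL) {
  stopifnot(length(pseudo_u) == length(pseudo_v))
  d <- copula_density(params, pseudo_u, pseudo_v)
  ld <- log(d)
  if (any(!is.finite(ld))) {
    i <- which(!is.finite(ld))[1]
    stopf("non-finite %s log-density at observation %d (u = %.4g, v = %.4g)",
          params$family$name, i, pseudo_u[i], pseudo_v[i])
  }
  if (is.null(weights)) sum(ld) else sum(weights * ld)
}

# Safe objective for optimisers: -loglik, large finite value on failure.
neg_loglik_safe <- function(fam, u, v, weights = NULL) {
  function(theta) {
    if (any(theta < fam$lower | theta > fam$upper)) return(1e10)
    ll <- tryCatch({
      d <- fam$pdf(theta, u, v)
      ld <- log(d)
      if (any(!is.finite(ld))) return(1e10)
      if (is.null(weights)) sum(ld) else sum(weights * ld)
    }, error = function(e) NA_real_, warning = function(w) NA_real_)
    if (!is.finite(ll)) 1e10 else -ll
  }
}

tau_start <- function(fam, u, v) {
  emp <- kendall_tau_b(u, v)$tau
  emp <- max(fam$tau_range[1] + 1e-4, min(fam$tau_range[2] - 1e-4, emp))
  tryCatch(theta_from_tau(fam, emp)$theta,
           error = function(e) (fam$opt_lower + fam$opt_upper) / 2)
}

#' Tau-initialised multi-restart local fit of a copula family
#'
#' The first start is the Kendall-tau inversion of the empirical tau; the
#' remaining starts are uniform draws over the family's working domain.  Each
#' start is refined with bounded quasi-Newton (`L-BFGS-B`); the best optimum
#' is returned.
#'
#' @param pseudo_u,pseudo_v pseudo-observations in `(0, 1)`, `n >= 10`.
#' @param family a `copula_family` or name.
#' @param restarts number of starts (`>= 1`).
#' @param seed integer seed controlling the random starts.
#' @param weights optional observation weights.
#' @return list with `params` ([copula_params()]), `loglik`, `tau`
#'   (tau-equivalent of the estimate), `n_starts_failed`.
#' @export
local_fit <- function(pseudo_u, pseudo_v, family, restarts = 100L, seed = 1L,
                      weights = NULL) {
  fam <- copula_family(family)
  n <- length(pseudo_u)
  if (n < 10) stopf("local_fit needs at least 10 observations")
  stopifnot(restarts >= 1)
  u <- clamp_unit(pseudo_u); v <- clamp_unit(pseudo_v)
  if (fam$n_params == 0) {
    p <- copula_params(fam)
    return(list(params = p, loglik = 0, tau = 0, n_starts_failed = 0L))
  }
  obj <- neg_loglik_safe(fam, u, v, weights)
  starts <- list(tau_start(fam, u, v))
  if (restarts > 1) {
    extra <- with_seed(derive_seed(seed, "local_fit", fam$name), {
      lapply(seq_len(restarts - 1), function(i)
        stats::runif(fam$n_params, fam$opt_lower, fam$opt_upper))
    })
    starts <- c(starts, extra)
  }
  best <- NULL; failed <- 0L
  for (st in starts) {
    fit <- tryCatch(
      stats::optim(st, obj, method = "L-BFGS-B",
                   lower = fam$opt_lower, upper = fam$opt_upper),
      error = function(e) NULL)
    if (is.null(fit) || fit$value >= 1e10) { failed <- failed + 1L; next }
    if (is.null(best) || fit$value < best$value) best <- fit
  }
  if (is.null(best))
    stopf("all %d optimisation start(s) failed for family '%s'",
          length(starts), fam$name)
  params <- copula_params(fam, best$par)
  list(params = params, loglik = -best$value,
       tau = tau_from_theta(params), n_starts_failed = failed)
}

# --- parameter transform for MCMC: bounded domain <-> unbounded scale -------
to_unbounded <- function(fam, theta) {
  stats::qlogis((theta - fam$opt_lower) / (fam$opt_upper - fam$opt_lower))
}
to_bounded <- function(fam, z) {
  fam$opt_lower + (fam$opt_upper - fam$opt_lower) * stats::plogis(z)
}
log_jacobian <- function(fam, z) {
  p <- stats::plogis(z)
  sum(log(fam$opt_upper - fam$opt_lower) + log(p) + log1p(-p))
}

#' Metropolis MCMC fit of a copula family
#'
#' Random-walk Metropolis on the logit-transformed parameter scale with a
#' uniform prior over the family's working domain.  Proposals are
#' componentwise for two-parameter families.  Step sizes adapt during warmup
#' toward a 20-40 percent acceptance rate and are then frozen.
#'
#' @param pseudo_u,pseudo_v pseudo-observations in `(0, 1)`, `n >= 10`.
#' @param family a `copula_family` or name.
#' @param n_chains number of chains (`>= 2`).
#' @param n_draws post-warmup draws per chain.
#' @param n_adapt warmup iterations per chain.
#' @param seed integer seed.
#' @param weights optional observation weights.
#' @return list with `draws` (matrix draws x params, chains stacked),
#'   `chain` (chain index per draw), `posterior_median`, `cri_95` (2.5/97.5
#'   percentiles per parameter), `tau` (tau-equivalent of the posterior
#'   median), `diagnostics` (`rhat`, `ess`, `acceptance_rate`, `n_chains`,
#'   `n_draws`, `converged`).
#' @export
mcmc_fit <- function(pseudo_u, pseudo_v, family, n_chains = 4L,
                     n_draws = 2000L, n_adapt = 500L, seed = 1L,
                     weights = NULL) {
  fam <- copula_family(family)
  if (length(pseudo_u) < 10) stopf("mcmc_fit needs at least 10 observations")
  if (n_chains < 2) stopf("at least 2 chains required for convergence checks")
  if (fam$n_params == 0)
    stopf("the independence family has no parameters to sample")
  u <- clamp_unit(pseudo_u); v <- clamp_unit(pseudo_v)
  obj <- neg_loglik_safe(fam, u, v, weights)
  logpost <- function(z) {
    nll <- obj(to_bounded(fam, z))
    if (nll >= 1e10) -Inf else -nll + log_jacobian(fam, z)
  }
  k <- fam$n_params
  start0 <- tau_start(fam, u, v)
  chains <- vector("list", n_chains)
  acc_rates <- numeric(n_chains)
  for (ch in seq_len(n_chains)) {
    chains[[ch]] <- with_seed(derive_seed(seed, "mcmc", fam$name, ch), {
      z <- to_unbounded(fam, start0) + stats::rnorm(k, 0, 0.1)
      lp <- logpost(z)
      if (!is.finite(lp)) { z <- rep(0, k); lp <- logpost(z) }
      step <- rep(0.5, k)
      draws <- matrix(NA_real_, n_draws, k)
      acc <- integer(k); prop <- integer(k)
      block <- 50L; block_acc <- integer(k); block_n <- integer(k)
      for (it in seq_len(n_adapt + n_draws)) {
        for (j in seq_len(k)) {
          zp <- z; zp[j] <- z[j] + stats::rnorm(1, 0, step[j])
          lpp <- logpost(zp)
          prop[j] <- prop[j] + 1L; block_n[j] <- block_n[j] + 1L
          if (is.finite(lpp) && log(stats::runif(1)) < lpp - lp) {
            z <- zp; lp <- lpp
            acc[j] <- acc[j] + 1L; block_acc[j] <- block_acc[j] + 1L
          }
        }
        if (it <= n_adapt && it %% block == 0) {
          rate <- block_acc / pmax(block_n, 1)
          step <- step * ifelse(rate < 0.20, 0.7, ifelse(rate > 0.40, 1.4, 1))
          block_acc[] <- 0L; block_n[] <- 0L
        }
        if (it > n_adapt) draws[it - n_adapt, ] <- to_bounded(fam, z)
      }
      list(draws = draws, acc_rate = sum(acc) / sum(prop))
    })
    acc_rates[ch] <- chains[[ch]]$acc_rate
  }
  acceptance <- mean(acc_rates)
  if (acceptance < 0.05 || acceptance > 0.95)
    warnf("Metropolis acceptance rate %.2f outside [0.05, 0.95] after adaptation",
          acceptance)
  draw_list <- lapply(chains, `[[`, "draws")
  draws <- do.call(rbind, draw_list)
  colnames(draws) <- fam$param_names
  rhat <- vapply(seq_len(k), function(j)
    split_rhat(sapply(draw_list, function(d) d[, j])), 0)
  ess <- vapply(seq_len(k), function(j)
    ess_chains(sapply(draw_list, function(d) d[, j])), 0)
  names(rhat) <- names(ess) <- fam$param_names
  converged <- all(rhat < 1.01)
  if (!converged)
    warnf("MCMC not converged for family '%s': max R-hat = %.4f", fam$name,
          max(rhat))
  med <- apply(draws, 2, stats::median)
  cri <- apply(draws, 2, stats::quantile, probs = c(0.025, 0.975))
  params_med <- copula_params(fam, med)
  list(draws = draws,
       chain = rep(seq_len(n_chains), each = n_draws),
       posterior_median = params_med,
       cri_95 = cri,
       tau = tau_from_theta(params_med),
       diagnostics = list(rhat = rhat, ess = ess,
                          acceptance_rate = acceptance,
                          n_chains = n_chains, n_draws = n_draws,
                          converged = converged))
}

# Split R-hat (potential scale reduction): each chain split in half.
split_rhat <- function(chain_matrix) {
  n <- nrow(chain_matrix)
  half <- floor(n / 2)
  splits <- cbind(chain_matrix[seq_len(half), , drop = FALSE],
                  chain_matrix[(n - half + 1):n, , drop = FALSE])
  m <- ncol(splits); nn <- nrow(splits)
  means <- colMeans(splits)
  vars <- apply(splits, 2, stats::var)
  W <- mean(vars)
  B <- nn * stats::var(means)
  if (W <= 0) return(1)
  sqrt(((nn - 1) / nn * W + B / nn) / W)
}

# Effective sample size from chain-averaged autocorrelations (initial
# positive-pair truncation).
ess_chains <- function(chain_matrix) {
  n <- nrow(chain_matrix); m <- ncol(chain_matrix)
  max_lag <- min(n - 2, 250)
  acfs <- sapply(seq_len(m), function(j)
    stats::acf(chain_matrix[, j], lag.max = max_lag, plot = FALSE,
               demean = TRUE)$acf[-1])
  rho <- rowMeans(acfs)
  s <- 0
  for (t in seq(1, length(rho) - 1, by = 2)) {
    pair <- rho[t] + rho[t + 1]
    if (!is.finite(pair) || pair < 0) break
    s <- s + pair
  }
  max(1, m * n / (1 + 2 * s))
}

#' Posterior predictive check on Kendall's tau
#'
#' For each replicate a parameter is drawn from the posterior sample, `n_obs`
#' pairs are simulated from the copula and their Kendall tau computed.  The
#' check passes when the observed tau falls inside the central 95 percent
#' predictive interval.
#'
#' @param draws posterior draw matrix (draws x parameters) from [mcmc_fit()].
#' @param family a `copula_family` or name.
#' @param n_rep number of replicates (`>= 100`).
#' @param n_obs pairs per replicate.
#' @param observed_tau the observed Kendall tau for the edge.
#' @param seed integer seed.
#' @return list with `interval` (2.5/97.5 percent predictive bounds),
#'   `percentile` of the observed tau, `pass`, and the replicate `taus`.
#' @export
ppc_tau <- function(draws, family, n_rep = 200L, n_obs = 500L, observed_tau,
                    seed = 1L) {
  if (n_rep < 100) stopf("ppc_tau needs at least 100 replicates")
  fam <- copula_family(family)
  draws <- as.matrix(draws)
  idx <- with_seed(derive_seed(seed, "ppc", fam$name),
                   sample.int(nrow(draws), n_rep, replace = TRUE))
  taus <- vapply(seq_len(n_rep), function(r) {
    p <- copula_params(fam, draws[idx[r], ])
    uv <- sample_copula(p, n_obs, seed = derive_seed(seed, "ppc_rep", r))
    kendall_tau_b(uv[, 1], uv[, 2])$tau
  }, 0)
  interval <- stats::quantile(taus, c(0.025, 0.975))
  list(interval = interval,
       percentile = mean(taus <= observed_tau),
       pass = observed_tau >= interval[1] && observed_tau <= interval[2],
       taus = taus)
}

#' Rank candidate copula families for one edge
#'
#' Each family is fitted by [local_fit()]; the ranking criterion is the
#' log-likelihood, AIC or BIC.  Ties break toward fewer parameters, then
#' alphabetical name.  Families whose fit fails are recorded and excluded.
#'
#' @param pseudo_u,pseudo_v pseudo-observations in `(0, 1)`.
#' @param catalogue character vector of family names.
#' @param criterion `"aic"` (default), `"bic"` or `"loglik"`.
#' @param restarts,seed,weights passed to [local_fit()].
#' @return data frame ranked best-first with columns `family`, `n_params`,
#'   `loglik`, `aic`, `bic`, `theta1`, `theta2`, `tau`; failed families are
#'   listed in the `failed` attribute.
#' @export
select_family <- function(pseudo_u, pseudo_v, catalogue,
                          criterion = c("aic", "bic", "loglik"),
                          restarts = 10L, seed = 1L, weights = NULL) {
  criterion <- match.arg(criterion)
  if (length(catalogue) == 0) stopf("empty family catalogue")
  n <- length(pseudo_u)
  failed <- character(0)
  rows <- list()
  for (nm in catalogue) {
    fit <- tryCatch(local_fit(pseudo_u, pseudo_v, nm, restarts = restarts,
                              seed = seed, weights = weights),
                    error = function(e) NULL)
    if (is.null(fit)) { failed <- c(failed, nm); next }
    k <- fit$params$family$n_params
    ic <- information_criteria(fit$loglik, k, n)
    th <- fit$params$theta
    rows[[nm]] <- data.frame(
      family = copula_family(nm)$name, n_params = k, loglik = fit$loglik,
      aic = ic$aic, bic = ic$bic,
      theta1 = if (k >= 1) th[1] else NA_real_,
      theta2 = if (k >= 2) th[2] else NA_real_,
      tau = fit$tau, stringsAsFactors = FALSE)
  }
  if (!length(rows)) stopf("every candidate family failed to fit")
  out <- do.call(rbind, rows)
  key <- switch(criterion, loglik = -out$loglik, aic = out$aic, bic = out$bic)
  out <- out[order(key, out$n_params, out$family), ]
  rownames(out) <- NULL
  attr(out, "failed") <- failed
  attr(out, "criterion") <- criterion
  out
}

#' Full per-edge fit: family selection, local and MCMC estimates, diagnostics
#'
#' Convenience wrapper producing the complete estimation record for one edge:
#' the best family by the chosen criterion, the tau-initialised local fit, the
#' Metropolis posterior (primary), the posterior predictive tau check and the
#' prediction skill metrics.
#'
#' @inheritParams select_family
#' @param edge_label optional label stored in the result.
#' @param mcmc_chains,mcmc_draws,mcmc_adapt MCMC settings.
#' @param ppc_rep replicates for the posterior predictive tau check.
#' @return an object of class `edge_fit`.
#' @export
fit_edge <- function(pseudo_u, pseudo_v, catalogue = study_families(),
                     criterion = "aic", restarts = 20L, seed = 1L,
                     weights = NULL, edge_label = NULL,
                     mcmc_chains = 4L, mcmc_draws = 1000L, mcmc_adapt = 400L,
                     ppc_rep = 200L) {
  ranking <- select_family(pseudo_u, pseudo_v, catalogue, criterion = criterion,
                           restarts = restarts, seed = seed, weights = weights)
  best <- ranking$family[1]
  loc <- local_fit(pseudo_u, pseudo_v, best, restarts = restarts, seed = seed,
                   weights = weights)
  obs_tau <- kendall_tau_b(pseudo_u, pseudo_v)
  if (best == "independence") {
    mc <- NULL; ppc <- NULL
    metrics_params <- loc$params
  } else {
    mc <- mcmc_fit(pseudo_u, pseudo_v, best, n_chains = mcmc_chains,
                   n_draws = mcmc_draws, n_adapt = mcmc_adapt, seed = seed,
                   weights = weights)
    ppc <- ppc_tau(mc$draws, best, n_rep = ppc_rep, n_obs = length(pseudo_u),
                   observed_tau = obs_tau$tau, seed = seed)
    metrics_params <- mc$posterior_median
  }
  pred <- predict_edge(pseudo_u, metrics_params)
  metrics <- prediction_metrics(pseudo_v, pred)
  structure(list(edge = edge_label, family = best, ranking = ranking,
                 theta_local = loc$params, loglik_local = loc$loglik,
                 tau_local = loc$tau,
                 mcmc = mc, ppc = ppc, tau_observed = obs_tau,
                 metrics = metrics),
            class = "edge_fit")
}

#' @export
print.edge_fit <- function(x, ...) {
  cat(sprintf("<edge fit%s> family: %s\n",
              if (!is.null(x$edge)) paste0(" ", x$edge) else "", x$family))
  cat(sprintf("  local: theta = %s (loglik %.2f, tau %.3f)\n",
              paste(round(x$theta_local$theta, 4), collapse = ", "),
              x$loglik_local, x$tau_local))
  if (!is.null(x$mcmc))
    cat(sprintf("  MCMC median: theta = %s (tau %.3f, max R-hat %.4f)\n",
                paste(round(x$mcmc$posterior_median$theta, 4), collapse = ", "),
                x$mcmc$tau, max(x$mcmc$diagnostics$rhat)))
  invisible(x)
}

#' Export posterior draws as delimited text
#'
#' Writes one row per (chain, draw, parameter) with the sampled value, the
#' long format convenient for external diagnostics tooling.
#'
#' @param mcmc a [mcmc_fit()] result.
#' @param path CSV output path.
#' @return `path`, invisibly.
#' @export
write_posterior_draws <- function(mcmc, path) {
  k <- ncol(mcmc$draws)
  n <- nrow(mcmc$draws)
  per_chain <- n / max(mcmc$chain)
  out <- data.frame(
    chain = rep(mcmc$chain, times = k),
    draw = rep(rep(seq_len(per_chain), max(mcmc$chain)), times = k),
    parameter = rep(colnames(mcmc$draws), each = n),
    value = as.vector(mcmc$draws))
  utils::write.csv(out, path, row.names = FALSE)
  invisible(path)
}

#' The copula families reported for the study's key edges
#'
#' @param with_extras include the additional testing families (Clayton,
#'   Frank, Gumbel).
#' @return character vector of family names.
#' @export
study_families <- function(with_extras = TRUE) {
  core <- c("joe", "amh", "marshall_olkin", "raftery", "roch_alegre",
            "gaussian", "independence")
  if (with_extras) c(core, "clayton", "frank", "gumbel") else core
}
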