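# Shared helpers: independent oracles and small panel builders.

# O(n^2) brute-force Kendall tau-b with tie corrections, kept deliberately
# naive so it stays an independent oracle for the package estimator.
brute_force_tau_b <- function(x, y) {
  n <- length(x)
  conc <- disc <- tx <- ty <- 0
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      dx <- x[i] - x[j]; dy <- y[i] - y[j]
      if (dx == 0 && dy == 0) next
      if (dx == 0) { tx <- tx + 1; next }
      if (dy == 0) { ty <- ty + 1; next }
      if (sign(dx) == sign(dy)) conc <- conc + 1 else disc <- disc + 1
    }
  }
  n0 <- n * (n - 1) / 2
  (conc - disc) / sqrt((n0 - tx_total(x)) * (n0 - tx_total(y)))
}
tx_total <- function(x) {
  tab <- table(x)
  sum(tab * (tab - 1) / 2)
}

# Representative parameter settings per family for property loops (the
# sampling checks use the first two; the density grid uses all three).
family_settings <- function() {
  list(
    independence = list(numeric(0)),
    gaussian = list(-0.5, 0.6, 0.9),
    clayton = list(0.8, 3, 0.2),
    frank = list(-4, 5, 12),
    gumbel = list(1.4, 3, 1.1),
    joe = list(1.5, 3, 5),
    amh = list(-0.7, 0.8, 0.3),
    marshall_olkin = list(c(0.3, 0.8), c(0.6, 0.6), c(0.9, 0.4)),
    raftery = list(0.3, 0.7, 0.5),
    roch_alegre = list(c(0.6, 1.2), c(2, 1.5), c(0.3, 2)))
}

# Single-edge panel: PS -> FS only, per-wave taus, no persistence.
single_edge_config <- function(taus, n_units = 2000L, family = "gaussian",
                               seed = 1L) {
  synthetic_config(
    n_units = n_units,
    edge_specs = list(list(from = "PS", to = "FS", family = family,
                           tau = taus)),
    persistence_specs = list(),
    confounding_smd = 0, seed = seed)
}

# Independence panel: no edges, no persistence.
null_config <- function(n_units = 2000L, seed = 1L) {
  synthetic_config(n_units = n_units, edge_specs = list(),
                   persistence_specs = list(), confounding_smd = 0,
                   seed = seed)
}

# Pseudo-observations simulated straight from a copula (latent scale).
copula_pseudo <- function(family, tau, n, seed) {
  p <- theta_from_tau(family, tau)
  uv <- sample_copula(p, n, seed = seed)
  list(u = uv[, 1], v = uv[, 2], params = p)
}

expect_within <- function(value, target, tol) {
  expect_true(abs(value - target) <= tol,
              label = sprintf("|%.4f - %.4f| <= %.4f", value, target, tol))
}
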