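# Copula family registry: Sklar boundary conditions, density/CDF consistency,
# conditional h-functions, sampling, and Kendall-tau parameter maps.

test_that("Sklar boundary conditions hold for every registered family", {
  set.seed(42)
  pts <- runif(100)
  for (nm in names(family_settings())) {
    for (th in family_settings()[[nm]]) {
      p <- copula_params(nm, th)
      expect_equal(copula_cdf(p, pts, rep(1, 100)), pts, tolerance = 1e-8,
                   label = paste(nm, "C(u,1)"))
      expect_equal(copula_cdf(p, rep(1, 100), pts), pts, tolerance = 1e-8,
                   label = paste(nm, "C(1,v)"))
      expect_equal(copula_cdf(p, pts, rep(0, 100)), rep(0, 100),
                   label = paste(nm, "C(u,0)"))
      expect_equal(copula_cdf(p, rep(0, 100), pts), rep(0, 100),
                   label = paste(nm, "C(0,v)"))
      # 2-increasing on random rectangles
      u1 <- runif(50, 0.02, 0.5); u2 <- u1 + runif(50, 0.01, 0.45)
      v1 <- runif(50, 0.02, 0.5); v2 <- v1 + runif(50, 0.01, 0.45)
      vol <- copula_cdf(p, u2, v2) - copula_cdf(p, u1, v2) -
        copula_cdf(p, u2, v1) + copula_cdf(p, u1, v1)
      expect_true(all(vol >= -1e-9), label = paste(nm, "2-increasing"))
    }
  }
})

test_that("specific closed forms evaluate correctly", {
  # Clayton theta = 2 at (0.5, 0.5): (u^-2 + v^-2 - 1)^(-1/2)
  expect_equal(copula_cdf(copula_params("clayton", 2), 0.5, 0.5),
               (0.5^-2 + 0.5^-2 - 1)^(-1 / 2), tolerance = 1e-12)
  # product copula
  expect_equal(copula_cdf(copula_params("independence"), 0.5, 0.5), 0.25)
  expect_equal(copula_density(copula_params("independence"), 0.3, 0.9), 1)
  # Gaussian independence limit
  expect_equal(copula_density(copula_params("gaussian", 0), 0.3, 0.8), 1)
  expect_equal(conditional_cdf(copula_params("independence"), 0.7, 0.2), 0.7)
})

test_that("density agrees with the finite-difference mixed partial of the CDF", {
  g <- seq(0.05, 0.95, length.out = 21)
  # Richardson-extrapolated central differences: the plain stencil's
  # truncation error exceeds the comparison tolerance where the density is
  # steep (tail-dependent families near corners)
  fd_mixed <- function(p, U, V, h) {
    (copula_cdf(p, U + h, V + h) - copula_cdf(p, U - h, V + h) -
     copula_cdf(p, U + h, V - h) + copula_cdf(p, U - h, V - h)) / (4 * h^2)
  }
  for (nm in names(family_settings())) {
    for (th in family_settings()[[nm]]) {
      p <- copula_params(nm, th)
      U <- rep(g, times = 21); V <- rep(g, each = 21)
      if (nm == "marshall_olkin") {
        # mask a band around the singular curve u^theta1 = v^theta2
        keep <- abs(U^th[1] - V^th[2]) > 0.02
        U <- U[keep]; V <- V[keep]
      }
      if (nm == "raftery") {
        # the density is continuous but non-smooth on u = v; the stencil
        # cannot straddle the diagonal ridge
        keep <- U != V
        U <- U[keep]; V <- V[keep]
      }
      fd <- (4 * fd_mixed(p, U, V, 5e-4) - fd_mixed(p, U, V, 1e-3)) / 3
      expect_lt(max(abs(copula_density(p, U, V) - fd)), 1e-4)
    }
  }
})

test_that("h-function matches the finite difference of the CDF in u", {
  h <- 1e-4
  for (nm in c("clayton", "gaussian", "joe", "raftery", "amh", "roch_alegre")) {
    th <- family_settings()[[nm]][[1]]
    p <- copula_params(nm, th)
    u <- c(0.2, 0.5, 0.8); v <- c(0.3, 0.5, 0.9)
    fd <- (copula_cdf(p, u + h, v) - copula_cdf(p, u - h, v)) / (2 * h)
    expect_equal(conditional_cdf(p, v, u), fd, tolerance = 1e-5)
    # boundary and monotonicity in v
    expect_equal(conditional_cdf(p, 0, 0.4), 0)
    expect_equal(conditional_cdf(p, 1, 0.4), 1)
    hv <- conditional_cdf(p, seq(0.01, 0.99, 0.01), rep(0.37, 99))
    expect_true(all(diff(hv) >= -1e-10))
  }
  # Clayton theta = 2 against the central-difference oracle at (v=0.5|u=0.5)
  p <- copula_params("clayton", 2)
  fd <- (copula_cdf(p, 0.5 + h, 0.5) - copula_cdf(p, 0.5 - h, 0.5)) / (2 * h)
  expect_equal(conditional_cdf(p, 0.5, 0.5), fd, tolerance = 1e-6)
})

test_that("density integrates to one for absolutely continuous families", {
  # integrate over the two triangles u < v and u > v so that densities with a
  # diagonal ridge (Raftery) are handled by the product rule
  gl <- pracma::gaussLegendre(60, 1e-6, 1 - 1e-6)
  U0 <- rep(gl$x, times = 60); Tt <- rep(gl$x, each = 60)
  V0 <- U0 + (1 - U0) * Tt
  W0 <- as.vector(outer(gl$w, gl$w)) * (1 - U0)
  for (nm in c("gaussian", "clayton", "frank", "gumbel", "joe", "amh",
               "raftery", "roch_alegre")) {
    th <- family_settings()[[nm]][[1]]
    p <- copula_params(nm, th)
    total <- sum(W0 * copula_density(p, U0, V0)) +
      sum(W0 * copula_density(p, V0, U0))
    expect_equal(total, 1, tolerance = 2e-3, label = paste(nm, "integral"))
  }
})

test_that("tau round trips through theta within 1e-6 for one-parameter families", {
  ranges <- list(gaussian = c(-0.95, 0.95), clayton = c(0.05, 0.9),
                 frank = c(-0.85, 0.85), gumbel = c(0.02, 0.9),
                 joe = c(0.05, 0.9), amh = c(-0.15, 0.32),
                 raftery = c(0.02, 0.9))
  for (nm in names(ranges)) {
    taus <- seq(ranges[[nm]][1], ranges[[nm]][2], length.out = 25)
    err <- vapply(taus, function(tau)
      abs(tau_from_theta(theta_from_tau(nm, tau)) - tau), 0)
    expect_lt(max(err), 1e-6)
  }
  # two-parameter families return a point on the tau level set
  for (nm in c("marshall_olkin", "roch_alegre")) {
    for (tau in c(0.1, 0.4, 0.7)) {
      if (nm == "roch_alegre" && tau > 0.75) next
      expect_within(tau_from_theta(theta_from_tau(nm, tau)), tau, 1e-6)
    }
  }
})

test_that("closed-form tau maps match their formulas", {
  expect_equal(tau_from_theta(copula_params("clayton", 2)), 0.5)
  expect_equal(tau_from_theta(copula_params("gaussian", 0)), 0)
  expect_equal(tau_from_theta(copula_params("raftery", 0.6)), 0.5)
  expect_equal(tau_from_theta(copula_params("gumbel", 4)), 0.75)
  expect_equal(tau_from_theta(copula_params("marshall_olkin", c(0.5, 0.5))),
               0.25 / 0.75)
  th <- 0.7
  expect_equal(tau_from_theta(copula_params("amh", th)),
               1 - 2 * (th + (1 - th)^2 * log(1 - th)) / (3 * th^2))
  expect_equal(theta_from_tau("clayton", 0.5)$theta, 2)
  expect_equal(theta_from_tau("gumbel", 0)$theta, 1)
})

test_that("numerical tau agrees with closed forms where both exist", {
  for (nm in c("gaussian", "clayton", "frank", "raftery")) {
    th <- family_settings()[[nm]][[2]]
    p <- copula_params(nm, th)
    fam <- copula_family(nm)
    closed <- fam$tau_fn(p$theta)
    # strip the closed form and force the generic numerical path
    p2 <- p; p2$family$tau_fn <- NULL
    expect_within(tau_from_theta(p2), closed, 2e-4)
  }
})

test_that("sampling is seed-reproducible with uniform margins and correct tau", {
  n <- 1e4
  se3 <- 3 * sqrt(2 * (2 * n + 5) / (9 * n * (n - 1)))
  for (nm in names(family_settings())) {
    settings <- family_settings()[[nm]]
    for (th in settings[seq_len(min(2, length(settings)))]) {
      p <- copula_params(nm, th)
      uv <- sample_copula(p, n, seed = 11)
      expect_identical(uv, sample_copula(p, n, seed = 11))
      expect_gt(stats::ks.test(uv[, 1], "punif")$p.value, 0.01)
      expect_gt(stats::ks.test(uv[, 2], "punif")$p.value, 0.01)
      emp <- kendall_tau_b(uv[, 1], uv[, 2])$tau
      expect_within(emp, tau_from_theta(p), se3)
    }
  }
  # Greiner closed form for the Gaussian at rho = 0.9
  uv <- sample_copula(copula_params("gaussian", 0.9), n, seed = 2)
  expect_within(kendall_tau_b(uv[, 1], uv[, 2])$tau, (2 / pi) * asin(0.9), 0.03)
})

test_that("domain and input violations are rejected with informative errors", {
  expect_error(copula_params("clayton", -1), "outside domain")
  expect_error(copula_params("amh", 1.5), "outside domain")
  expect_error(copula_params("gaussian", c(0.5, 0.2)), "takes 1 parameter")
  expect_error(copula_cdf(copula_params("gaussian", 0.5), NaN, 0.5), "NaN")
  expect_error(copula_cdf(copula_params("gaussian", 0.5), 1.2, 0.5),
               "unit interval")
  expect_error(theta_from_tau("clayton", -0.3), "attainable range")
  expect_error(theta_from_tau("amh", 0.8), "attainable range")
  expect_error(copula_family("nonsense"), "unknown copula family")
  expect_warning(copula_density(copula_params("gaussian", 0.5), 0, 0.5),
                 "clamped")
})

test_that("registry serialises to JSON and back-references its families", {
  js <- jsonlite::fromJSON(registry_to_json())
  expect_setequal(js$name, list_copula_families())
  expect_true(all(js$n_params[js$name == "marshall_olkin"] == 2))
  expect_true(js$supports_closed_form_tau[js$name == "gaussian"])
  expect_false(js$supports_closed_form_tau[js$name == "joe"])
})
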