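# Bivariate copula family registry.
#
# Each family is an S3 object holding its parameter domain, closed-form
# CDF / density / h-function, and Kendall-tau maps.  Archimedean families are
# built from their generator phi and inverse-generator psi (with first and
# second derivatives), from which density and conditional follow:
#   C(u,v)  = psi(phi(u) + phi(v))
#   h(v|u)  = psi'(s) / psi'(phi(u)),        s = phi(u) + phi(v)
#   c(u,v)  = psi''(s) / (psi'(phi(u)) psi'(phi(v)))

.copula_registry <- new.env(parent = emptyenv())

new_copula_family <- function(name, n_params, lower, upper,
                              opt_lower = lower, opt_upper = upper,
                              tau_range, has_closed_tau,
                              cdf, pdf, hfun,
                              tau_fn = NULL, tau_inverse = NULL,
                              phi = NULL, dphi = NULL,
                              param_names = paste0("theta", seq_len(max(n_params, 1L))),
                              note = "") {
  structure(list(name = name, n_params = n_params,
                 lower = lower, upper = upper,
                 opt_lower = opt_lower, opt_upper = opt_upper,
                 tau_range = tau_range,
                 supports_closed_form_tau = has_closed_tau,
                 cdf = cdf, pdf = pdf, hfun = hfun,
                 tau_fn = tau_fn, tau_inverse = tau_inverse,
                 phi = phi, dphi = dphi,
                 param_names = param_names, note = note),
            class = "copula_family")
}

register_family <- function(fam) assign(fam$name, fam, envir = .copula_registry)

#' Look up a bivariate copula family by name
#'
#' The registry covers the independence, Gaussian, Clayton, Frank, Gumbel,
#' Joe, Ali-Mikhail-Haq (AMH), Marshall-Olkin, Raftery and Roch-Alegre
#' families.  Each family exposes its CDF, density, conditional h-function,
#' sampler and Kendall-tau parameter maps behind a common interface.
#'
#' @param name family name (case-insensitive; `-` and `.` map to `_`).
#' @return an object of class `copula_family`.
#' @examples
#' fam <- copula_family("clayton")
#' fam$n_params
#' @export
copula_family <- function(name) {
  if (inherits(name, "copula_family")) return(name)
  key <- gsub("[-. ]", "_", tolower(name))
  if (!exists(key, envir = .copula_registry, inherits = FALSE))
    stopf("unknown copula family '%s'; registered: %s", name,
          paste(sort(ls(.copula_registry)), collapse = ", "))
  get(key, envir = .copula_registry)
}

#' List registered copula families
#' @return character vector of family names.
#' @export
list_copula_families <- function() sort(ls(.copula_registry))

#' @export
print.copula_family <- function(x, ...) {
  cat(sprintf("<copula family '%s'> %d parameter(s)\n", x$name, x$n_params))
  if (x$n_params > 0)
    cat(sprintf("  domain: %s\n", paste(sprintf("%s in [%g, %g]",
        x$param_names, x$lower, x$upper), collapse = ", ")))
  cat(sprintf("  Kendall tau range: [%g, %g]%s\n", x$tau_range[1], x$tau_range[2],
      if (x$supports_closed_form_tau) " (closed form)" else " (numerical)"))
  invisible(x)
}

#' Bundle a copula family with a parameter vector
#'
#' @param family a `copula_family` object or family name.
#' @param theta numeric vector of parameters, checked against the family's
#'   declared domain.
#' @return an object of class `copula_params`.
#' @examples
#' copula_params("gaussian", 0.5)
#' @export
copula_params <- function(family, theta = numeric(0)) {
  fam <- copula_family(family)
  theta <- as.numeric(theta)
  if (length(theta) != fam$n_params)
    stopf("family '%s' takes %d parameter(s), got %d", fam$name, fam$n_params,
          length(theta))
  if (any(!is.finite(theta)))
    stopf("non-finite parameter for family '%s'", fam$name)
  bad <- which(theta < fam$lower | theta > fam$upper)
  if (length(bad))
    stopf("parameter %s = %g outside domain [%g, %g] of family '%s'",
          fam$param_names[bad[1]], theta[bad[1]], fam$lower[bad[1]],
          fam$upper[bad[1]], fam$name)
  structure(list(family = fam, theta = theta), class = "copula_params")
}

#' @export
print.copula_params <- function(x, ...) {
  cat(sprintf("<%s copula>", x$family$name))
  if (length(x$theta))
    cat(" ", paste(sprintf("%s = %.4f", x$family$param_names, x$theta),
                   collapse = ", "))
  cat("\n")
  invisible(x)
}

check_pair <- function(u, v, what = "input") {
  if (any(is.na(u)) || any(is.na(v)))
    stopf("NaN/NA %s supplied to copula evaluation", what)
  if (any(u < 0 | u > 1) || any(v < 0 | v > 1))
    stopf("%s outside the closed unit interval", what)
}

#' Copula cumulative distribution function
#'
#' @param params a [copula_params()] object.
#' @param u,v numeric vectors in `[0, 1]` (recycled to common length).
#' @return `C(u, v)`, a probability.
#' @examples
#' copula_cdf(copula_params("clayton", 2), 0.5, 0.5)
#' @export
copula_cdf <- function(params, u, v) {
  stopifnot(inherits(params, "copula_params"))
  n <- max(length(u), length(v))
  u <- rep_len(as.numeric(u), n); v <- rep_len(as.numeric(v), n)
  check_pair(u, v)
  pmin(pmax(params$family$cdf(params$theta, u, v), 0), 1)
}

#' Copula density
#'
#' Values at exactly 0 or 1 are clamped a small distance inside the unit
#' square (with a warning), since empirical pseudo-observations can touch the
#' boundary where many densities are undefined.
#'
#' @inheritParams copula_cdf
#' @return the copula density `c(u, v)`, non-negative.
#' @export
copula_density <- function(params, u, v) {
  stopifnot(inherits(params, "copula_params"))
  n <- max(length(u), length(v))
  u <- rep_len(as.numeric(u), n); v <- rep_len(as.numeric(v), n)
  check_pair(u, v)
  u <- clamp_unit(u, warn = TRUE); v <- clamp_unit(v, warn = TRUE)
  pmax(params$family$pdf(params$theta, u, v), 0)
}

#' Conditional copula CDF (h-function)
#'
#' Returns `h(v | u) = dC(u, v) / du`, the conditional distribution of the
#' second coordinate given the first.
#'
#' @param params a [copula_params()] object.
#' @param v evaluation points in `[0, 1]`.
#' @param given_u conditioning values in `(0, 1)`.
#' @return probabilities `h(v | u)`.
#' @export
conditional_cdf <- function(params, v, given_u) {
  stopifnot(inherits(params, "copula_params"))
  n <- max(length(v), length(given_u))
  v <- rep_len(as.numeric(v), n); u <- rep_len(as.numeric(given_u), n)
  check_pair(u, v)
  u <- clamp_unit(u, warn = TRUE)
  out <- params$family$hfun(params$theta, u, v)
  out[v <= 0] <- 0; out[v >= 1] <- 1
  pmin(pmax(out, 0), 1)
}

#' Inverse conditional copula CDF
#'
#' Solves `h(v | u) = w` for `v` by monotone bisection; used for conditional
#' sampling and synthetic data generation.  For families whose conditional has
#' atoms (e.g. Marshall-Olkin) the generalised inverse
#' `inf { v : h(v|u) >= w }` is returned.
#'
#' @param params a [copula_params()] object.
#' @param w target probabilities in `[0, 1]`.
#' @param given_u conditioning values in `(0, 1)`.
#' @param iterations bisection iterations (each halves the bracket).
#' @return values `v` in `(0, 1)`.
#' @export
inverse_conditional_cdf <- function(params, w, given_u, iterations = 60L) {
  stopifnot(inherits(params, "copula_params"))
  n <- max(length(w), length(given_u))
  w <- rep_len(as.numeric(w), n); u <- rep_len(as.numeric(given_u), n)
  check_pair(u, w)
  u <- clamp_unit(u); w <- clamp_unit(w)
  if (params$family$name == "independence") return(w)
  lo <- rep(0, n); hi <- rep(1, n)
  for (i in seq_len(iterations)) {
    mid <- (lo + hi) / 2
    below <- params$family$hfun(params$theta, u, mid) < w
    lo[below] <- mid[below]
    hi[!below] <- mid[!below]
  }
  clamp_unit((lo + hi) / 2)
}

#' Sample from a bivariate copula
#'
#' Draws the first coordinate uniformly and the second by inverting the
#' conditional h-function, which is valid for every registered family.
#'
#' @param params a [copula_params()] object.
#' @param n number of pairs.
#' @param seed integer seed; the same seed reproduces the same sample.
#' @return a two-column matrix of pseudo-observations with columns `u`, `v`.
#' @examples
#' uv <- sample_copula(copula_params("gaussian", 0.6), 500, seed = 1)
#' @export
sample_copula <- function(params, n, seed) {
  stopifnot(inherits(params, "copula_params"), n >= 1)
  with_seed(derive_seed(seed, "sample", params$family$name), {
    u <- stats::runif(n)
    w <- stats::runif(n)
    v <- inverse_conditional_cdf(params, w, u)
    cbind(u = u, v = v)
  })
}

#' Kendall's tau implied by copula parameters
#'
#' Uses the family's closed form when one exists (Gaussian, Clayton, Frank,
#' Gumbel, AMH, Raftery, Marshall-Olkin); otherwise computes
#' `tau = 1 + 4 * integral(phi(t)/phi'(t))` for Archimedean generators, or the
#' double integral `4 E[C(U,V)] - 1` by Gauss-Legendre quadrature.
#'
#' @param params a [copula_params()] object.
#' @return Kendall's tau in `[-1, 1]`.
#' @export
tau_from_theta <- function(params) {
  stopifnot(inherits(params, "copula_params"))
  fam <- params$family
  if (!is.null(fam$tau_fn)) return(fam$tau_fn(params$theta))
  if (!is.null(fam$phi)) {   # Archimedean: 1 + 4 int_0^1 phi/phi'
    ig <- function(t) {
      r <- fam$phi(params$theta, t) / fam$dphi(params$theta, t)
      r[!is.finite(r)] <- 0
      r
    }
    val <- tryCatch(stats::integrate(ig, 0, 1, rel.tol = 1e-9,
                                     subdivisions = 400L)$value,
                    error = function(e)
                      stopf("numerical tau failed for family '%s': %s",
                            fam$name, conditionMessage(e)))
    return(max(-1, min(1, 1 + 4 * val)))
  }
  # generic fallback: tau = 4 E[C(U,V)] - 1, integrated separately over the
  # two triangles u < v and u > v (several families have a density ridge on
  # the diagonal where a single product rule converges poorly)
  gl <- gauss_legendre(48, 1e-9, 1 - 1e-9)
  tri <- function(swap) {
    U <- rep(gl$x, times = 48); Tt <- rep(gl$x, each = 48)
    V <- U + (1 - U) * Tt            # v in (u, 1)
    W <- as.vector(outer(gl$w, gl$w)) * (1 - U)
    a <- if (swap) V else U; b <- if (swap) U else V
    sum(W * fam$cdf(params$theta, a, b) * fam$pdf(params$theta, a, b))
  }
  max(-1, min(1, 4 * (tri(FALSE) + tri(TRUE)) - 1))
}

#' Copula parameters matching a target Kendall's tau
#'
#' Inverts the tau map.  One-parameter families use the closed-form inverse
#' where available and monotone root finding otherwise.  For two-parameter
#' families the second parameter is fixed at the midpoint of its working
#' domain and the first is solved on the resulting tau level set.
#'
#' @param family a `copula_family` or family name.
#' @param tau target Kendall's tau, inside the family's attainable range.
#' @return a [copula_params()] object whose [tau_from_theta()] equals `tau`.
#' @examples
#' theta_from_tau("clayton", 0.5)$theta  # == 2
#' @export
theta_from_tau <- function(family, tau) {
  fam <- copula_family(family)
  if (fam$n_params == 0) {
    if (abs(tau) > 1e-8)
      stopf("independence family only attains tau = 0, not %g", tau)
    return(copula_params(fam))
  }
  rng <- fam$tau_range
  if (tau < rng[1] - 1e-9 || tau > rng[2] + 1e-9)
    stopf("tau = %g outside attainable range [%g, %g] of family '%s'",
          tau, rng[1], rng[2], fam$name)
  tau <- max(rng[1], min(rng[2], tau))
  if (!is.null(fam$tau_inverse)) return(copula_params(fam, fam$tau_inverse(tau)))
  if (fam$n_params == 1) {
    f <- function(th) tau_from_theta(copula_params(fam, th)) - tau
    lo <- fam$opt_lower; hi <- fam$opt_upper
    root <- stats::uniroot(f, lower = lo, upper = hi, tol = 1e-10,
                           extendInt = "no")$root
    return(copula_params(fam, root))
  }
  th2 <- (fam$opt_lower[2] + fam$opt_upper[2]) / 2
  f <- function(th1) tau_from_theta(copula_params(fam, c(th1, th2))) - tau
  flo <- f(fam$opt_lower[1]); fhi <- f(fam$opt_upper[1])
  if (flo * fhi > 0)
    stopf("tau = %g not attainable by family '%s' with %s fixed at %g",
          tau, fam$name, fam$param_names[2], th2)
  root <- stats::uniroot(f, lower = fam$opt_lower[1], upper = fam$opt_upper[1],
                         tol = 1e-8)$root
  copula_params(fam, c(root, th2))
}

# ---------------------------------------------------------------------------
# Archimedean machinery

make_archimedean <- function(name, lower, upper, opt_lower, opt_upper,
                             tau_range, has_closed_tau,
                             psi, dpsi, d2psi, phi, dphi,
                             tau_fn = NULL, tau_inverse = NULL, note = "") {
  cdf <- function(theta, u, v) {
    out <- psi(theta, phi(theta, clamp_unit(u)) + phi(theta, clamp_unit(v)))
    out[u <= 0 | v <= 0] <- 0
    out[u >= 1] <- v[u >= 1]
    out[v >= 1] <- u[v >= 1]
    out
  }
  pdf <- function(theta, u, v) {
    pu <- phi(theta, u); pv <- phi(theta, v)
    d2psi(theta, pu + pv) / (dpsi(theta, pu) * dpsi(theta, pv))
  }
  hfun <- function(theta, u, v) {
    v <- clamp_unit(v)
    dpsi(theta, phi(theta, u) + phi(theta, v)) / dpsi(theta, phi(theta, u))
  }
  new_copula_family(name, length(lower), lower, upper, opt_lower, opt_upper,
                    tau_range, has_closed_tau, cdf, pdf, hfun,
                    tau_fn = tau_fn, tau_inverse = tau_inverse,
                    phi = phi, dphi = dphi, note = note)
}

# ---------------------------------------------------------------------------
# Families

## Independence: C = uv
register_family(new_copula_family(
  "independence", 0L, numeric(0), numeric(0),
  tau_range = c(0, 0), has_closed_tau = TRUE,
  cdf = function(theta, u, v) u * v,
  pdf = function(theta, u, v) rep(1, length(u)),
  hfun = function(theta, u, v) v,
  tau_fn = function(theta) 0,
  note = "product copula"))

## Gaussian: theta = rho in (-1, 1); CDF by Plackett's identity
##   C(u,v) = uv + int_0^rho phi2(x, y; r) dr  with x = qnorm(u), y = qnorm(v)
.gauss_gl <- pracma::gaussLegendre(32, 0, 1)
register_family(new_copula_family(
  "gaussian", 1L, -1 + 1e-12, 1 - 1e-12, -0.999, 0.999,
  tau_range = c(-1, 1), has_closed_tau = TRUE,
  cdf = function(theta, u, v) {
    r <- theta[1]
    ui <- clamp_unit(u, 1e-12); vi <- clamp_unit(v, 1e-12)
    x <- stats::qnorm(ui); y <- stats::qnorm(vi)
    rr <- .gauss_gl$x * r; wt <- .gauss_gl$w * r
    acc <- numeric(length(ui))
    for (k in seq_along(rr)) {
      s <- rr[k]
      acc <- acc + wt[k] * exp(-(x^2 - 2 * s * x * y + y^2) / (2 * (1 - s^2))) /
        (2 * pi * sqrt(1 - s^2))
    }
    out <- ui * vi + acc
    out[u <= 0 | v <= 0] <- 0
    out[u >= 1] <- v[u >= 1]; out[v >= 1] <- u[v >= 1]
    out
  },
  pdf = function(theta, u, v) {
    r <- theta[1]
    x <- stats::qnorm(u); y <- stats::qnorm(v)
    exp(-(r^2 * (x^2 + y^2) - 2 * r * x * y) / (2 * (1 - r^2))) / sqrt(1 - r^2)
  },
  hfun = function(theta, u, v) {
    r <- theta[1]
    stats::pnorm((stats::qnorm(clamp_unit(v)) - r * stats::qnorm(u)) /
                 sqrt(1 - r^2))
  },
  tau_fn = function(theta) (2 / pi) * asin(theta[1]),
  tau_inverse = function(tau) sin(pi * tau / 2),
  note = "elliptical; tau = (2/pi) arcsin(rho)"))

## Clayton: theta > 0; phi(t) = (t^-theta - 1)/theta
register_family(make_archimedean(
  "clayton", 1e-8, 200, 1e-4, 50,
  tau_range = c(0, 1), has_closed_tau = TRUE,
  psi = function(th, s) (1 + th[1] * s)^(-1 / th[1]),
  dpsi = function(th, s) -(1 + th[1] * s)^(-1 / th[1] - 1),
  d2psi = function(th, s) (1 + th[1]) * (1 + th[1] * s)^(-1 / th[1] - 2),
  phi = function(th, t) (t^(-th[1]) - 1) / th[1],
  dphi = function(th, t) -t^(-th[1] - 1),
  tau_fn = function(th) th[1] / (th[1] + 2),
  tau_inverse = function(tau) 2 * tau / (1 - tau),
  note = "lower tail dependent; tau = theta/(theta+2)"))

## Frank: theta in [-50, 50], theta = 0 is the independence limit
frank_debye1 <- function(th) {
  # D1(theta) = (1/theta) int_0^theta t/(exp(t)-1) dt
  stats::integrate(function(t) ifelse(t == 0, 1, t / expm1(t)), 0, th,
                   rel.tol = 1e-10)$value / th
}
register_family(local({
  psi  <- function(th, s) {
    if (abs(th[1]) < 1e-8) return(exp(-s))
    -log1p(exp(-s) * expm1(-th[1])) / th[1]
  }
  dpsi <- function(th, s) {
    if (abs(th[1]) < 1e-8) return(-exp(-s))
    a <- exp(-s) * expm1(-th[1])
    a / (th[1] * (1 + a))
  }
  d2psi <- function(th, s) {
    if (abs(th[1]) < 1e-8) return(exp(-s))
    a <- exp(-s) * expm1(-th[1])
    -a / (th[1] * (1 + a)^2)
  }
  phi  <- function(th, t) {
    if (abs(th[1]) < 1e-8) return(-log(t))
    -log(expm1(-th[1] * t) / expm1(-th[1]))
  }
  dphi <- function(th, t) {
    if (abs(th[1]) < 1e-8) return(-1 / t)
    th[1] * exp(-th[1] * t) / expm1(-th[1] * t)
  }
  make_archimedean("frank", -50, 50, -50, 50,
    tau_range = c(-1, 1), has_closed_tau = TRUE,
    psi = psi, dpsi = dpsi, d2psi = d2psi, phi = phi, dphi = dphi,
    tau_fn = function(th) {
      if (abs(th[1]) < 1e-8) return(0)
      1 - (4 / th[1]) * (1 - frank_debye1(th[1]))
    },
    tau_inverse = function(tau) {
      if (abs(tau) < 1e-10) return(0)
      f <- function(th) 1 - (4 / th) * (1 - frank_debye1(th)) - tau
      stats::uniroot(f, interval = c(1e-6, 50) * sign(tau), tol = 1e-10)$root
    },
    note = "radially symmetric; tau via the first Debye function")
}))

## Gumbel: theta >= 1; phi(t) = (-log t)^theta
register_family(make_archimedean(
  "gumbel", 1, 200, 1, 50,
  tau_range = c(0, 1), has_closed_tau = TRUE,
  psi = function(th, s) exp(-s^(1 / th[1])),
  dpsi = function(th, s) -exp(-s^(1 / th[1])) * s^(1 / th[1] - 1) / th[1],
  d2psi = function(th, s) {
    a <- 1 / th[1]
    exp(-s^a) * (a^2 * s^(2 * a - 2) + a * (1 - a) * s^(a - 2))
  },
  phi = function(th, t) (-log(t))^th[1],
  dphi = function(th, t) -th[1] * (-log(t))^(th[1] - 1) / t,
  tau_fn = function(th) 1 - 1 / th[1],
  tau_inverse = function(tau) 1 / (1 - tau),
  note = "upper tail dependent; tau = 1 - 1/theta"))

## Joe: theta >= 1; phi(t) = -log(1 - (1-t)^theta)
register_family(make_archimedean(
  "joe", 1, 100, 1, 50,
  tau_range = c(0, 1), has_closed_tau = FALSE,
  psi = function(th, s) 1 - (-expm1(-s))^(1 / th[1]),
  dpsi = function(th, s) {
    g <- -expm1(-s)
    -(1 / th[1]) * g^(1 / th[1] - 1) * exp(-s)
  },
  d2psi = function(th, s) {
    a <- 1 / th[1]; g <- -expm1(-s); e <- exp(-s)
    -a * (a - 1) * g^(a - 2) * e^2 + a * g^(a - 1) * e
  },
  phi = function(th, t) -log1p(-(1 - t)^th[1]),
  dphi = function(th, t) -th[1] * (1 - t)^(th[1] - 1) / (1 - (1 - t)^th[1]),
  note = "strong upper tail dependence; tau by generator quadrature"))

## Ali-Mikhail-Haq: theta in [-1, 1); psi(s) = (1-theta)/(exp(s) - theta)
register_family(make_archimedean(
  "amh", -1, 1 - 1e-9, -0.999, 0.999,
  tau_range = c((5 - 8 * log(2)) / 3, 1 / 3), has_closed_tau = TRUE,
  psi = function(th, s) (1 - th[1]) / (exp(s) - th[1]),
  dpsi = function(th, s) -(1 - th[1]) * exp(s) / (exp(s) - th[1])^2,
  d2psi = function(th, s) (1 - th[1]) * exp(s) * (exp(s) + th[1]) /
    (exp(s) - th[1])^3,
  phi = function(th, t) log((1 - th[1] * (1 - t)) / t),
  dphi = function(th, t) (th[1] - 1) / (t * (1 - th[1] * (1 - t))),
  tau_fn = function(th) {
    t1 <- th[1]
    if (abs(t1) < 1e-6) return(2 * t1 / 9)
    1 - 2 * (t1 + (1 - t1)^2 * log1p(-t1)) / (3 * t1^2)
  },
  tau_inverse = function(tau) {
    if (abs(tau) < 1e-10) return(0)
    f <- function(t1) {
      if (abs(t1) < 1e-6) return(2 * t1 / 9 - tau)
      1 - 2 * (t1 + (1 - t1)^2 * log1p(-t1)) / (3 * t1^2) - tau
    }
    stats::uniroot(f, lower = -1 + 1e-9, upper = 1 - 1e-9, tol = 1e-12)$root
  },
  note = "bounded dependence: tau in [(5 - 8 log 2)/3, 1/3)"))

## Marshall-Olkin: theta1, theta2 in (0, 1];
##   C = min(u^(1-theta1) v, u v^(1-theta2)); has a singular component on the
##   curve u^theta1 = v^theta2 so its absolutely continuous density does not
##   integrate to 1.
register_family(new_copula_family(
  "marshall_olkin", 2L, c(1e-8, 1e-8), c(1, 1), c(1e-3, 1e-3), c(0.999, 0.999),
  tau_range = c(0, 1), has_closed_tau = TRUE,
  cdf = function(theta, u, v) {
    pmin(u^(1 - theta[1]) * v, u * v^(1 - theta[2]))
  },
  pdf = function(theta, u, v) {
    upper <- u^theta[1] > v^theta[2]   # region where C = u^(1-theta1) v
    ifelse(upper, (1 - theta[1]) * u^(-theta[1]), (1 - theta[2]) * v^(-theta[2]))
  },
  hfun = function(theta, u, v) {
    v <- clamp_unit(v)
    upper <- u^theta[1] > v^theta[2]
    ifelse(upper, (1 - theta[1]) * u^(-theta[1]) * v, v^(1 - theta[2]))
  },
  tau_fn = function(theta) {
    theta[1] * theta[2] / (theta[1] + theta[2] - theta[1] * theta[2])
  },
  tau_inverse = function(tau) {
    # symmetric point theta1 = theta2 = t on the tau level set: tau = t/(2-t)
    t <- 2 * tau / (1 + tau)
    c(max(t, 1e-8), max(t, 1e-8))
  },
  note = "singular component on u^theta1 = v^theta2; density is the a.c. part"))

## Raftery: theta in [0, 1)
raftery_halves <- function(theta, u, v) {
  # C for the half-plane u <= v; callers symmetrise.
  d <- (1 - theta) / (1 + theta); e1 <- 1 / (1 - theta)
  u + d * u^e1 * (v^e1 - v^(-theta / (1 - theta)))
}
register_family(new_copula_family(
  "raftery", 1L, 0, 1 - 1e-9, 0, 0.999,
  tau_range = c(0, 1), has_closed_tau = TRUE,
  cdf = function(theta, u, v) {
    th <- theta[1]
    ui <- clamp_unit(u, 1e-12); vi <- clamp_unit(v, 1e-12)
    out <- ifelse(ui <= vi, raftery_halves(th, ui, vi), raftery_halves(th, vi, ui))
    out[u <= 0 | v <= 0] <- 0
    out[u >= 1] <- v[u >= 1]; out[v >= 1] <- u[v >= 1]
    out
  },
  pdf = function(theta, u, v) {
    th <- theta[1]; d <- (1 - th) / (1 + th); e1 <- 1 / (1 - th)
    a <- pmin(u, v); b <- pmax(u, v)
    d * e1 * a^(th / (1 - th)) *
      (e1 * b^(th / (1 - th)) + (th / (1 - th)) * b^(-1 / (1 - th) ))
  },
  hfun = function(theta, u, v) {
    th <- theta[1]; d <- (1 - th) / (1 + th); e1 <- 1 / (1 - th)
    v <- clamp_unit(v)
    ifelse(u <= v,
      1 + d * e1 * u^(th / (1 - th)) * (v^e1 - v^(-th / (1 - th))),
      d * v^e1 * (e1 * u^(th / (1 - th)) + (th / (1 - th)) * u^(-1 / (1 - th))))
  },
  tau_fn = function(theta) 2 * theta[1] / (3 - theta[1]),
  tau_inverse = function(tau) 3 * tau / (2 + tau),
  note = "asymmetric, right-skewed probability mass; tau = 2 theta/(3 - theta)"))

## Roch-Alegre: two-parameter Archimedean generator
##   phi(t) = ((1 - log t)^theta1 - 1)^theta2,  theta1 > 0, theta2 >= 1
register_family(local({
  w_of   <- function(th, s) (s^(1 / th[2]) + 1)^(1 / th[1])
  dw_of  <- function(th, s) {
    (1 / (th[1] * th[2])) * (s^(1 / th[2]) + 1)^(1 / th[1] - 1) *
      s^(1 / th[2] - 1)
  }
  d2w_of <- function(th, s) {
    a <- 1 / th[1]; b <- 1 / th[2]
    (a * b) * ((a - 1) * b * (s^b + 1)^(a - 2) * s^(2 * b - 2) +
               (b - 1) * (s^b + 1)^(a - 1) * s^(b - 2))
  }
  psi   <- function(th, s) exp(1 - w_of(th, s))
  dpsi  <- function(th, s) -dw_of(th, s) * psi(th, s)
  d2psi <- function(th, s) (dw_of(th, s)^2 - d2w_of(th, s)) * psi(th, s)
  phi   <- function(th, t) ((1 - log(t))^th[1] - 1)^th[2]
  dphi  <- function(th, t) {
    -th[2] * ((1 - log(t))^th[1] - 1)^(th[2] - 1) * th[1] *
      (1 - log(t))^(th[1] - 1) / t
  }
  fam <- make_archimedean("roch_alegre",
    lower = c(1e-8, 1), upper = c(100, 100),
    opt_lower = c(0.02, 1), opt_upper = c(10, 10),
    tau_range = c(-0.12, 0.78), has_closed_tau = FALSE,
    psi = psi, dpsi = dpsi, d2psi = d2psi, phi = phi, dphi = dphi,
    note = "generator phi(t) = ((1 - log t)^theta1 - 1)^theta2")
  # tau inversion pins theta2 = 1.2, where theta1 in [0.02, 10] sweeps the
  # declared tau range; the optimiser still explores the full 2-D domain.
  fam$tau_inverse <- function(tau) {
    th2 <- 1.2
    f <- function(th1) {
      ig <- function(t) fam$phi(c(th1, th2), t) / fam$dphi(c(th1, th2), t)
      1 + 4 * stats::integrate(ig, 0, 1, rel.tol = 1e-9)$value - tau
    }
    c(stats::uniroot(f, lower = 0.02, upper = 10, tol = 1e-9)$root, th2)
  }
  fam
}))

# ---------------------------------------------------------------------------
# Registry serialization

#' Serialize the family registry to a JSON descriptor
#'
#' @param path optional file path; when `NULL` the JSON string is returned.
#' @return JSON text describing each family (name, arity, domain, tau range).
#' @export
registry_to_json <- function(path = NULL) {
  fams <- lapply(list_copula_families(), function(nm) {
    f <- copula_family(nm)
    list(name = f$name, n_params = f$n_params,
         lower = f$lower, upper = f$upper,
         tau_range = f$tau_range,
         supports_closed_form_tau = f$supports_closed_form_tau)
  })
  js <- jsonlite::toJSON(fams, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  if (!is.null(path)) { writeLines(js, path); invisible(path) } else js
}
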