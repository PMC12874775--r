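# Internal helpers shared across modules.

#' Clamp values into the open unit interval
#'
#' Pseudo-observations produced by empirical transforms can hit exactly 0 or 1,
#' where most copula densities are undefined; evaluation routines clamp such
#' values a small distance inside the interval.
#'
#' @param x numeric vector.
#' @param eps half-width of the excluded boundary band.
#' @param warn emit a warning when any value is actually clamped.
#' @return `x` with values forced into `[eps, 1 - eps]`.
#' @keywords internal
clamp_unit <- function(x, eps = 1e-10, warn = FALSE) {
  out <- pmin(pmax(x, eps), 1 - eps)
  if (warn && any(out != x, na.rm = TRUE)) {
    warning(sprintf("%d value(s) at the unit-interval boundary clamped to the interior",
                    sum(out != x, na.rm = TRUE)))
  }
  out
}

# Deterministic child seed derived from a base seed and string labels, so that
# independent randomisation streams (e.g. per node and wave) never collide and
# everything still flows from one user seed.  Stays below 2^31 - 1.
derive_seed <- function(seed, ...) {
  labels <- paste(c(...), collapse = "\r")
  h <- as.double(seed %% 2147483647L)
  for (code in utf8ToInt(labels)) h <- (h * 31 + code) %% 2147483647
  as.integer(h)
}

# Evaluate `code` under `seed` and restore the caller's RNG state afterwards.
with_seed <- function(seed, code) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

# Gauss-Legendre nodes/weights on [a, b].
gauss_legendre <- function(n, a = 0, b = 1) {
  gl <- pracma::gaussLegendre(n, a, b)
  list(x = gl$x, w = gl$w)
}

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)
warnf <- function(fmt, ...) warning(sprintf(fmt, ...), call. = FALSE)
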