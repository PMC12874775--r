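# Per-node marginal models and transforms to pseudo-uniform values.
#
# Copula modelling needs observations on the uniform scale.  Continuous
# variables use the probability integral transform through an empirical CDF;
# ordinal/binary variables use the distributional transform, which randomises
# within each CDF jump so that tied values become proper pseudo-uniforms.

#' Estimate a marginal distribution model for one variable
#'
#' @param values observed vector (numeric, factor or character for discrete
#'   scales; numeric for continuous). `NA`s are dropped with a message.
#' @param scale one of `"binary"`, `"ordinal"`, `"continuous"`.
#' @param weights optional non-negative observation weights.
#' @param levels optional explicit ordered support for discrete scales;
#'   unobserved levels receive mass zero.
#' @return an object of class `marginal_model` carrying, for discrete scales,
#'   the per-level mass, CDF `F(x)` and left limit `F(x-)`; for continuous
#'   scales the sorted sample defining an empirical CDF rescaled by
#'   `n / (n + 1)` so transforms stay strictly below 1.
#' @examples
#' estimate_marginal(c(0, 1, 1, 1), "binary")
#' @export
estimate_marginal <- function(values, scale = c("binary", "ordinal", "continuous"),
                              weights = NULL, levels = NULL) {
  scale <- match.arg(scale)
  keep <- !is.na(values)
  if (!is.null(weights)) {
    stopifnot(length(weights) == length(values))
    if (any(weights < 0, na.rm = TRUE)) stopf("negative weights")
    keep <- keep & !is.na(weights)
    weights <- weights[keep]
    if (sum(weights) <= 0) stopf("weights sum to zero")
  }
  values <- values[keep]
  if (length(values) == 0) stopf("all values missing")
  if (is.null(weights)) weights <- rep(1, length(values))

  if (scale == "continuous") {
    if (length(unique(values)) < 2)
      stopf("continuous marginal needs at least 2 distinct values")
    o <- order(values)
    structure(list(scale = scale, sorted = values[o],
                   sorted_w = weights[o], n = length(values)),
              class = "marginal_model")
  } else {
    lev <- if (!is.null(levels)) levels
           else if (is.factor(values)) base::levels(values)
           else sort(unique(values))
    if (!all(as.character(values) %in% as.character(lev)))
      stopf("values outside the declared support")
    idx <- match(as.character(values), as.character(lev))
    mass <- vapply(seq_along(lev), function(k) sum(weights[idx == k]), 0)
    mass <- mass / sum(mass)
    Fx <- cumsum(mass)
    Fx[length(Fx)] <- 1
    structure(list(scale = scale, levels = lev, mass = mass,
                   F = Fx, F_minus = c(0, Fx[-length(Fx)]),
                   n = length(values)),
              class = "marginal_model")
  }
}

#' @export
print.marginal_model <- function(x, ...) {
  if (x$scale == "continuous") {
    cat(sprintf("<continuous marginal> empirical CDF on %d observations\n", x$n))
  } else {
    cat(sprintf("<%s marginal> %d level(s)\n", x$scale, length(x$levels)))
    print(stats::setNames(round(x$mass, 4), as.character(x$levels)))
  }
  invisible(x)
}

level_index <- function(values, model) {
  idx <- match(as.character(values), as.character(model$levels))
  if (any(is.na(idx) & !is.na(values)))
    stopf("value '%s' outside the marginal support",
          as.character(values[is.na(idx) & !is.na(values)][1]))
  idx
}

#' Probability integral transform
#'
#' Maps observations to `F(x)`.  Continuous scales use the empirical CDF with
#' the `n/(n+1)` rescaling; discrete scales return the right-continuous CDF
#' value of each level (use [distributional_transform()] for tie-broken
#' pseudo-uniforms).
#'
#' @param values observations within the model support.
#' @param model a [estimate_marginal()] result.
#' @return vector in `(0, 1]`, monotone in the input.
#' @export
pit_transform <- function(values, model) {
  stopifnot(inherits(model, "marginal_model"))
  if (model$scale == "continuous") {
    r <- findInterval(values, model$sorted)   # number of sorted values <= x
    if (any(values < model$sorted[1], na.rm = TRUE))
      stopf("value below the observed support")
    r / (model$n + 1)
  } else {
    model$F[level_index(values, model)]
  }
}

#' Distributional transform for discrete data
#'
#' Returns `U = F(x-) + V (F(x) - F(x-))` with independent `V ~ Uniform(0,1)`
#' per observation, the standard randomised transform that turns tied ordinal
#' data into pseudo-uniform values.
#'
#' @param values observations within the model support.
#' @param model a discrete-scale [estimate_marginal()] result.
#' @param seed integer seed for the uniform randomisation stream.
#' @return vector in `(0, 1)`; exactly uniform when `values` are drawn from
#'   the model.
#' @export
distributional_transform <- function(values, model, seed) {
  stopifnot(inherits(model, "marginal_model"))
  if (model$scale == "continuous")
    stopf("distributional_transform is for discrete scales; use pit_transform")
  idx <- level_index(values, model)
  with_seed(derive_seed(seed, "distributional_transform"), {
    V <- stats::runif(length(values))
    model$F_minus[idx] + V * (model$F[idx] - model$F_minus[idx])
  })
}

# Pseudo-uniform values for any scale: distributional transform for discrete,
# PIT for continuous.  The seed stream is keyed by (node, wave) labels so each
# variable/slice gets an independent randomisation.
pseudo_uniform <- function(values, model, seed, key = character(0)) {
  if (model$scale == "continuous") clamp_unit(pit_transform(values, model))
  else clamp_unit(distributional_transform(values, model,
                                           derive_seed(seed, key)))
}
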