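# Goodness-of-fit panel: information criteria and prediction-skill metrics
# (RMSE, NSE, NRMSE = RMSE/SD, MAE/SD) with conditional-mean edge prediction.

#' Akaike and Bayesian information criteria
#'
#' `AIC = -2 loglik + 2 k` and `BIC = -2 loglik + k log(n)`.
#'
#' @param loglik maximised log-likelihood.
#' @param k number of free parameters.
#' @param n number of observations (`>= 1`).
#' @return list with `aic` and `bic`.
#' @examples
#' information_criteria(-10, 2, 100)
#' @export
information_criteria <- function(loglik, k, n) {
  stopifnot(n >= 1, k >= 0)
  list(aic = -2 * loglik + 2 * k, bic = -2 * loglik + k * log(n))
}

#' Conditional-mean prediction along a copula edge
#'
#' Predicts the child pseudo-value as `E[V | U = u]`, computed from the
#' conditional CDF by the identity `E[V | u] = integral_0^1 (1 - h(v|u)) dv`
#' evaluated with Gauss-Legendre quadrature.
#'
#' @param pseudo_u parent pseudo-observations in `(0, 1)`.
#' @param params a [copula_params()] object.
#' @param n_nodes quadrature nodes.
#' @return predicted child pseudo-values in `(0, 1)`.
#' @examples
#' predict_edge(c(0.2, 0.8), copula_params("independence"))  # 0.5, 0.5
#' @export
predict_edge <- function(pseudo_u, params, n_nodes = 64L) {
  stopifnot(inherits(params, "copula_params"))
  u <- clamp_unit(as.numeric(pseudo_u))
  gl <- gauss_legendre(n_nodes, 0, 1)
  out <- numeric(length(u))
  H <- vapply(seq_along(gl$x), function(k)
    conditional_cdf(params, rep(gl$x[k], length(u)), u), numeric(length(u)))
  H <- matrix(H, nrow = length(u))
  out <- 1 - as.numeric(H %*% gl$w)
  if (any(!is.finite(out)))
    stopf("conditional-mean integration failed for family '%s'",
          params$family$name)
  clamp_unit(out)
}

#' Prediction skill metrics: RMSE, NSE, NRMSE, MAE/SD
#'
#' `RMSE = sqrt(mean((y - yhat)^2))`; `NSE = 1 - sum((y - yhat)^2) /
#' sum((y - ybar)^2)` (1 = perfect, 0 = mean predictor); `NRMSE = RMSE /
#' SD(y)` and `MAE/SD` use the `n - 1` standard deviation of the observed
#' values.
#'
#' @param observed,predicted equal-length numeric vectors, `n >= 2`;
#'   `observed` must not be constant.
#' @return list with `rmse`, `nse`, `nrmse`, `mae_sd`, `n`.
#' @examples
#' prediction_metrics(c(0, 1, 2), c(0, 1, 1))
#' @export
prediction_metrics <- function(observed, predicted) {
  observed <- as.numeric(observed); predicted <- as.numeric(predicted)
  if (length(observed) != length(predicted)) stopf("length mismatch")
  n <- length(observed)
  if (n < 2) stopf("need at least 2 observations")
  if (stats::sd(observed) == 0)
    stopf("degenerate input: constant observed vector (NSE undefined)")
  err <- observed - predicted
  rmse <- sqrt(mean(err^2))
  nse <- 1 - sum(err^2) / sum((observed - mean(observed))^2)
  sdy <- stats::sd(observed)
  list(rmse = rmse, nse = nse, nrmse = rmse / sdy,
       mae_sd = mean(abs(err)) / sdy, n = n)
}

#' Full fit-metrics record for a fitted edge
#'
#' @param loglik maximised log-likelihood.
#' @param k free parameter count.
#' @param observed,predicted vectors for the skill metrics.
#' @return list combining [information_criteria()] and
#'   [prediction_metrics()] with `loglik`, `k`.
#' @export
fit_metrics <- function(loglik, k, observed, predicted) {
  ic <- information_criteria(loglik, k, length(observed))
  pm <- prediction_metrics(observed, predicted)
  c(list(loglik = loglik, k = k), ic, pm)
}
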