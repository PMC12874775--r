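# Selection and spillover toolkit: stabilised inverse-probability weights
# from baseline covariates, standardised-mean-difference balance diagnostics,
# leave-one-out community program intensity, and community-block bootstrap.

#' Stabilised inverse-probability weights from baseline covariates
#'
#' Fits a main-effects logistic propensity model `participation ~ covariates`
#' and returns stabilised weights `P(A = a) / P(A = a | X)` for each unit's
#' observed status, optionally truncated at symmetric percentiles.
#'
#' @param baseline_covariates data frame of pre-program covariates.
#' @param participation binary 0/1 vector aligned with the covariate rows.
#' @param truncate optional length-2 percentile bounds, e.g. `c(0.01, 0.99)`.
#' @return an object of class `weight_set`: `weights` (positive), `propensity`,
#'   `stabilized = TRUE`, `truncation`.
#' @export
stabilized_ipw <- function(baseline_covariates, participation,
                           truncate = NULL) {
  a <- as.integer(participation)
  stopifnot(nrow(baseline_covariates) == length(a))
  if (!all(a %in% c(0L, 1L))) stopf("participation must be binary 0/1")
  if (length(unique(a)) < 2) stopf("both participation classes must be present")
  dat <- cbind(.a = a, baseline_covariates)
  fit <- suppressWarnings(stats::glm(.a ~ ., data = dat,
                                     family = stats::binomial()))
  p <- stats::fitted(fit)
  if (any(p < 1e-8) || any(p > 1 - 1e-8))
    stopf(paste("perfect or near-perfect separation in the propensity model;",
                "consider truncation or penalised estimation"))
  pa <- mean(a)
  w <- ifelse(a == 1, pa / p, (1 - pa) / (1 - p))
  if (!is.null(truncate)) {
    stopifnot(length(truncate) == 2)
    q <- stats::quantile(w, truncate)
    w <- pmin(pmax(w, q[1]), q[2])
  }
  structure(list(weights = w, propensity = p, participation = a,
                 stabilized = TRUE, truncation = truncate,
                 model = fit),
            class = "weight_set")
}

#' @export
print.weight_set <- function(x, ...) {
  cat(sprintf("<stabilised IPW> n = %d, mean weight = %.3f, range [%.3f, %.3f]\n",
              length(x$weights), mean(x$weights), min(x$weights),
              max(x$weights)))
  invisible(x)
}

#' Standardised mean differences between two groups
#'
#' `SMD = (mean_1 - mean_0) / pooled SD`; with weights, weighted moments are
#' used.  Covariates whose pooled SD is zero are flagged `degenerate`.
#' Wilcoxon rank-sum p-values are reported alongside as the rank-based
#' balance test (unweighted only).
#'
#' @param covariates data frame of numeric covariates.
#' @param groups binary 0/1 group indicator.
#' @param weights optional positive weights.
#' @return data frame with `covariate`, `smd`, `degenerate`, `wilcoxon_p`.
#' @export
balance_smd <- function(covariates, groups, weights = NULL) {
  g <- as.integer(groups)
  stopifnot(nrow(covariates) == length(g))
  if (!any(g == 0) || !any(g == 1)) stopf("both groups must be non-empty")
  w <- if (is.null(weights)) rep(1, length(g)) else as.numeric(weights)
  wmean <- function(x, w) sum(w * x) / sum(w)
  wvar <- function(x, w) {
    m <- wmean(x, w)
    sum(w * (x - m)^2) / (sum(w) - 1)
  }
  rows <- lapply(names(covariates), function(nm) {
    x <- as.numeric(covariates[[nm]])
    v1 <- wvar(x[g == 1], w[g == 1]); v0 <- wvar(x[g == 0], w[g == 0])
    pooled <- sqrt((v1 + v0) / 2)
    smd <- if (pooled == 0) NA_real_
           else (wmean(x[g == 1], w[g == 1]) - wmean(x[g == 0], w[g == 0])) / pooled
    wp <- if (is.null(weights) && pooled > 0)
      suppressWarnings(stats::wilcox.test(x[g == 1], x[g == 0])$p.value)
    else NA_real_
    data.frame(covariate = nm, smd = smd, degenerate = pooled == 0,
               wilcoxon_p = wp, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Leave-one-out community program intensity
#'
#' For unit `i` in community `g` of size `n_g`, the proportion of the other
#' `n_g - 1` units participating at the given wave; `NA` (flagged missing)
#' when the community has a single unit.
#'
#' @param panel a [panel_dataset()].
#' @param wave wave label.
#' @param program_indicator name of the participation variable; a unit counts
#'   as participating when its value differs from `control_level`.
#' @param control_level the non-participating category (default `"C"`).
#' @return data frame `unit_id`, `community_id`, `wave`, `cpi`,
#'   `community_size`.
#' @export
cpi_leave_one_out <- function(panel, wave, program_indicator = "PS",
                              control_level = "C") {
  stopifnot(inherits(panel, "panel_dataset"))
  df <- panel$data
  if (!program_indicator %in% names(df))
    stopf("unknown program indicator '%s'", program_indicator)
  d <- df[as.character(df$wave) == as.character(wave), ]
  if (nrow(d) == 0) stopf("wave '%s' absent from panel", wave)
  part <- as.integer(as.character(d[[program_indicator]]) != control_level)
  tot <- tapply(part, d$community_id, sum)
  size <- tapply(part, d$community_id, length)
  g <- as.character(d$community_id)
  n_g <- as.numeric(size[g])
  cpi <- ifelse(n_g > 1, (as.numeric(tot[g]) - part) / (n_g - 1), NA_real_)
  data.frame(unit_id = d$unit_id, community_id = d$community_id,
             wave = as.character(wave), cpi = cpi, community_size = n_g,
             stringsAsFactors = FALSE)
}

#' Community-block bootstrap
#'
#' Resamples communities with replacement (keeping all units of each sampled
#' community, relabelled per draw) and recomputes a statistic, yielding a
#' percentile confidence interval that respects within-community clustering.
#'
#' @param panel a [panel_dataset()].
#' @param statistic function taking a resampled [panel_dataset()] and
#'   returning a single number.
#' @param B number of bootstrap replicates (`>= 100`).
#' @param seed integer seed.
#' @param conf confidence level for the percentile interval.
#' @return list with `point` (statistic on the original panel), `ci`,
#'   `replicates`, `n_failed`.
#' @export
community_block_bootstrap <- function(panel, statistic, B = 500L, seed = 1L,
                                      conf = 0.95) {
  stopifnot(inherits(panel, "panel_dataset"), B >= 100)
  comms <- unique(panel$data$community_id)
  if (length(comms) < 2) stopf("need at least 2 communities")
  point <- statistic(panel)
  split_rows <- split(seq_len(nrow(panel$data)),
                      as.character(panel$data$community_id))
  reps <- with_seed(derive_seed(seed, "block_bootstrap"), {
    vapply(seq_len(B), function(b) {
      pick <- sample(as.character(comms), length(comms), replace = TRUE)
      rows <- unlist(lapply(seq_along(pick), function(k) split_rows[[pick[k]]]),
                     use.names = FALSE)
      dat <- panel$data[rows, ]
      cd <- panel$coded[rows, ]
      # relabel duplicated communities/units so (unit, wave) stays unique
      copy_idx <- rep(seq_along(pick),
                      vapply(pick, function(cm) length(split_rows[[cm]]), 0L))
      dat$unit_id <- paste0(dat$unit_id, ".", copy_idx)
      dat$community_id <- paste0(dat$community_id, ".", copy_idx)
      cd$unit_id <- dat$unit_id; cd$community_id <- dat$community_id
      bp <- panel
      bp$data <- dat; bp$coded <- cd
      tryCatch(statistic(bp), error = function(e) NA_real_)
    }, 0)
  })
  n_failed <- sum(is.na(reps))
  if (n_failed > 0.10 * B)
    stopf("statistic failed in %d of %d bootstrap replicates", n_failed, B)
  if (n_failed > 0)
    message(sprintf("dropped %d failed bootstrap replicate(s)", n_failed))
  reps_ok <- reps[!is.na(reps)]
  alpha <- (1 - conf) / 2
  list(point = point,
       ci = stats::quantile(reps_ok, c(alpha, 1 - alpha)),
       replicates = reps, n_failed = n_failed)
}
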