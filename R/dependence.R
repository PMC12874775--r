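# Kendall rank correlation (tau-b) with tie correction, optional weights,
# and per-wave trajectories along network edges.

#' Tie-corrected Kendall rank correlation (tau-b)
#'
#' Computes tau-b by pairwise enumeration with tie corrections.  With weights,
#' each pair `(i, j)` contributes weight `w_i * w_j` to the concordance sums
#' and to the tie corrections, an estimator that reduces exactly to the
#' classical tau-b at unit weights.  Significance for the unweighted case uses
#' the normal approximation `z = 3 tau sqrt(n (n - 1)) / sqrt(2 (2 n + 5))`;
#' for weighted data the normal variance is invalid and `p_value` is `NA`
#' (use [community_block_bootstrap()] instead).
#'
#' @param x,y equal-length vectors (numeric or ordered factors), `n >= 2`.
#' @param weights optional non-negative weights.
#' @return an object of class `tau_estimate` with fields `tau`, `n_pairs`,
#'   `z_stat`, `p_value`, `weighted`, `n`.
#' @examples
#' kendall_tau_b(c(1, 2, 3), c(1, 2, 3))$tau  # 1
#' @export
kendall_tau_b <- function(x, y, weights = NULL) {
  x <- as.numeric(x); y <- as.numeric(y)
  if (length(x) != length(y)) stopf("x and y must have equal length")
  keep <- !(is.na(x) | is.na(y))
  if (!is.null(weights)) keep <- keep & !is.na(weights)
  x <- x[keep]; y <- y[keep]
  n <- length(x)
  if (n < 2) stopf("need at least 2 complete pairs")
  if (length(unique(x)) < 2 || length(unique(y)) < 2)
    stopf("degenerate input: constant vector")
  weighted <- !is.null(weights)
  w <- if (weighted) weights[keep] else rep(1, n)
  if (any(w < 0)) stopf("negative weights")
  s <- .kendall_pair_sums(x, y, w)
  denom <- sqrt((s[["W"]] - s[["tx"]] - s[["txy"]]) *
                (s[["W"]] - s[["ty"]] - s[["txy"]]))
  if (denom <= 0) stopf("degenerate input: no untied pairs")
  tau <- unname(s[["num"]] / denom)
  if (!weighted) {
    z <- 3 * tau * sqrt(n * (n - 1)) / sqrt(2 * (2 * n + 5))
    p <- 2 * stats::pnorm(-abs(z))
  } else {
    z <- NA_real_; p <- NA_real_
  }
  structure(list(tau = tau, n_pairs = n * (n - 1) / 2, n = n,
                 z_stat = z, p_value = p, weighted = weighted),
            class = "tau_estimate")
}

#' @export
print.tau_estimate <- function(x, ...) {
  cat(sprintf("tau-b = %.4f%s (n = %d%s)\n", x$tau, significance_stars(x$p_value),
              x$n, if (x$weighted) ", weighted" else ""))
  invisible(x)
}

#' Significance stars at the 10/5/1 percent levels
#' @param p p-value (may be `NA`).
#' @return `"***"`, `"**"`, `"*"` or `""`.
#' @export
significance_stars <- function(p) {
  vapply(p, function(pi) {
    if (is.na(pi)) "" else if (pi < 0.01) "***" else if (pi < 0.05) "**"
    else if (pi < 0.10) "*" else ""
  }, "")
}

#' Kendall tau trajectory of a network edge across waves
#'
#' For a within-slice edge (`lag = 0`) tau is computed per wave on complete
#' pairs of that wave.  For a persistence (self-loop) edge (`lag = 1`) each
#' trajectory entry pairs the value at one wave with the value at the next
#' wave for units observed in both, labelled `"waveA -> waveB"`.
#'
#' @param panel a [panel_dataset()].
#' @param edge length-2 character vector `c(from, to)` of variable names.
#' @param waves waves to use (default: the panel's analysis waves).
#' @param weights optional named vector of unit weights (names = unit ids).
#' @param lag 0 for contemporaneous, 1 for the transition pairing.
#' @return data frame with one row per wave (or transition): `wave`, `tau`,
#'   `n`, `z`, `p_value`, `stars`.
#' @export
tau_trajectory <- function(panel, edge, waves = NULL, weights = NULL, lag = 0L) {
  stopifnot(inherits(panel, "panel_dataset"), length(edge) == 2)
  df <- panel$data
  waves <- if (is.null(waves)) panel$waves else as.character(waves)
  missing_w <- setdiff(waves, unique(as.character(df$wave)))
  if (length(missing_w))
    stopf("wave(s) %s absent from panel", paste(missing_w, collapse = ", "))
  for (v in edge) if (!v %in% names(df)) stopf("variable '%s' not in panel", v)
  unit_w <- function(ids) {
    if (is.null(weights)) rep(1, length(ids))
    else unname(weights[as.character(ids)])
  }
  cd <- panel$coded
  rows <- list()
  if (lag == 0) {
    for (wv in waves) {
      d <- cd[as.character(cd$wave) == wv, ]
      est <- kendall_tau_b(d[[edge[1]]], d[[edge[2]]],
                           weights = if (is.null(weights)) NULL
                                     else unit_w(d$unit_id))
      rows[[wv]] <- data.frame(wave = wv, tau = est$tau, n = est$n,
                               z = est$z_stat, p_value = est$p_value,
                               stars = significance_stars(est$p_value))
    }
  } else {
    if (length(waves) < 2) stopf("lagged trajectory needs at least 2 waves")
    for (k in seq_len(length(waves) - 1)) {
      d0 <- cd[as.character(cd$wave) == waves[k], c("unit_id", edge[1])]
      d1 <- cd[as.character(cd$wave) == waves[k + 1], c("unit_id", edge[2])]
      names(d0)[2] <- "x0"; names(d1)[2] <- "x1"
      m <- merge(d0, d1, by = "unit_id")
      est <- kendall_tau_b(m$x0, m$x1,
                           weights = if (is.null(weights)) NULL
                                     else unit_w(m$unit_id))
      lab <- paste(waves[k], "->", waves[k + 1])
      rows[[lab]] <- data.frame(wave = lab, tau = est$tau, n = est$n,
                                z = est$z_stat, p_value = est$p_value,
                                stars = significance_stars(est$p_value))
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Tau trajectory table for a set of edges
#'
#' Convenience wrapper producing an edge-by-wave table of `tau` with
#' significance stars, the layout used for reporting temporal edges and
#' self-loops.
#'
#' @param panel a [panel_dataset()].
#' @param edges data frame with columns `from`, `to`, `lag`.
#' @param waves waves to use (default: the panel's analysis waves).
#' @param weights optional named unit weights.
#' @return data frame, one row per edge, one column per wave/transition.
#' @export
tau_table <- function(panel, edges, waves = NULL, weights = NULL) {
  stopifnot(all(c("from", "to", "lag") %in% names(edges)))
  rows <- lapply(seq_len(nrow(edges)), function(i) {
    tr <- tau_trajectory(panel, c(edges$from[i], edges$to[i]), waves = waves,
                         weights = weights, lag = edges$lag[i])
    vals <- stats::setNames(sprintf("%.3f%s", tr$tau, tr$stars), tr$wave)
    c(edge = paste(edges$from[i], "->", edges$to[i]), vals)
  })
  nm <- unique(unlist(lapply(rows, names)))
  out <- as.data.frame(do.call(rbind, lapply(rows, function(r) r[nm])),
                       stringsAsFactors = FALSE)
  names(out) <- nm
  out
}
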