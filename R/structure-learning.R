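# Score-based structure learning: greedy hill-climbing with add/delete/
# reverse moves over a constraint template, scored by the graph form of BIC,
#   score(G : D) = loglik - 0.5 log(K) |Theta_G|,
# learned separately for the initial graph (K = number of sequences) and the
# transition graph (K = total number of transitions).  The likelihood
# decomposes over edges (each child-parent pair is a bivariate copula fit on
# pseudo-observations), so per-edge contributions are computed once and
# cached during search.

# Pseudo-observation cache: list by wave, each a data.frame keyed by unit_id
# with one pseudo-uniform column per variable.
pseudo_cache <- function(panel, vars, seed) {
  out <- list()
  for (wv in panel$waves) {
    rows <- which(as.character(panel$coded$wave) == wv)
    d <- data.frame(unit_id = panel$coded$unit_id[rows])
    for (v in vars) {
      ok <- !is.na(panel$coded[[v]][rows])
      if (!any(ok)) { d[[v]] <- NA_real_; next }
      val <- rep(NA_real_, length(rows))
      val[ok] <- panel_pseudo(panel, rows[ok], v, wv, seed)
      d[[v]] <- val
    }
    out[[wv]] <- d
  }
  out
}

# Stacked (u, v) records for one candidate edge.
edge_records <- function(cache, waves, from, to, lag, part) {
  if (part == "initial") {
    d <- cache[[waves[1]]]
    u <- d[[from]]; v <- d[[to]]
  } else {
    u <- c(); v <- c()
    for (t in 2:length(waves)) {
      dt <- cache[[waves[t]]]
      if (lag == 1) {
        d0 <- cache[[waves[t - 1]]]
        m <- match(dt$unit_id, d0$unit_id)
        u <- c(u, d0[[from]][m]); v <- c(v, dt[[to]])
      } else {
        u <- c(u, dt[[from]]); v <- c(v, dt[[to]])
      }
    }
  }
  keep <- !(is.na(u) | is.na(v))
  list(u = u[keep], v = v[keep])
}

# Best penalised contribution of one edge over the search catalogue.  With
# `allow_null` the parameter-free independence fit (contribution 0) is a
# candidate, which is how the search leaves unsupported edges out; scoring an
# explicitly requested graph instead always commits to a parametric family.
edge_contribution <- function(cache, waves, from, to, lag, part, penalty_per_param,
                              catalogue, restarts, seed, weights = NULL,
                              allow_null = TRUE) {
  rec <- edge_records(cache, waves, from, to, lag, part)
  if (length(rec$u) < 10)
    stopf("edge %s -> %s has fewer than 10 complete records", from, to)
  best <- if (allow_null)
    list(score = 0, family = "independence", loglik = 0, k = 0L)
  else list(score = -Inf, family = NULL, loglik = NA_real_, k = NA_integer_)
  for (nm in catalogue) {
    # the restart seed uses unordered endpoints so that the two orientations
    # of an exchangeable-copula edge get bit-identical likelihoods and ties
    # resolve deterministically toward the template orientation
    fit <- tryCatch(local_fit(rec$u, rec$v, nm, restarts = restarts,
                              seed = derive_seed(seed, "edge", min(from, to),
                                                 max(from, to), lag),
                              weights = weights),
                    error = function(e) NULL)
    if (is.null(fit)) next
    k <- fit$params$family$n_params
    sc <- fit$loglik - penalty_per_param * k
    if (sc > best$score)
      best <- list(score = sc, family = nm, loglik = fit$loglik, k = k,
                   theta = fit$params$theta)
  }
  if (is.null(best$family))
    stopf("every family failed on edge %s -> %s", from, to)
  best
}

marginal_loglik <- function(panel, vars, waves, part) {
  use_waves <- if (part == "initial") waves[1] else waves[-1]
  ll <- 0
  for (wv in use_waves) {
    rows <- which(as.character(panel$coded$wave) == wv)
    for (v in vars) {
      s <- panel$schema[[v]]
      if (is.null(s) || s$scale == "continuous") next
      x <- panel$coded[[v]][rows]
      x <- x[!is.na(x)]
      if (!length(x)) next
      m <- estimate_marginal(x, s$scale, levels = sort(unique(x)))
      ll <- ll + sum(log(m$mass[level_index(x, m)]))
    }
  }
  ll
}

part_K <- function(panel, part) {
  w <- panel$waves
  if (part == "initial") {
    sum(as.character(panel$coded$wave) == w[1])
  } else {
    k <- 0
    for (t in 2:length(w)) {
      ids0 <- panel$coded$unit_id[as.character(panel$coded$wave) == w[t - 1]]
      ids1 <- panel$coded$unit_id[as.character(panel$coded$wave) == w[t]]
      k <- k + length(intersect(ids0, ids1))
    }
    k
  }
}

penalty_per_param <- function(K, score = c("bic", "aic", "none")) {
  switch(match.arg(score), bic = 0.5 * log(K), aic = 1, none = 0)
}

#' BIC score of a dynamic graph part
#'
#' Computes `score = loglik - 0.5 log(K) |Theta|` where the log-likelihood is
#' the sum of the maximised per-edge copula log-likelihoods plus the marginal
#' log-likelihoods of the scored records, `K` is the number of sequences
#' (initial part) or transitions (transition part), and `|Theta|` the number
#' of free copula parameters.
#'
#' @param panel a [panel_dataset()].
#' @param dag a validated [dynamic_dag()].
#' @param part `"initial"` scores `g0_edges` on the first analysis wave;
#'   `"transition"` scores `transition_edges` on stacked consecutive wave
#'   pairs.
#' @param catalogue family names tried per edge (best penalised fit kept).
#' @param restarts,seed passed to the per-edge [local_fit()].
#' @param score `"bic"` (default), `"aic"`, or `"none"` (pure likelihood).
#' @return an object of class `score_report`: `loglik`, `penalty`, `bic`,
#'   `K`, `n_free_params` and the per-edge fit table.
#' @export
bic_score <- function(panel, dag, part = c("initial", "transition"),
                      catalogue = c("gaussian", "clayton", "gumbel", "frank"),
                      restarts = 2L, seed = 1L, score = "bic") {
  part <- match.arg(part)
  validate_dag(dag)
  edges <- if (part == "initial") {
    if (nrow(dag$g0_edges)) cbind(dag$g0_edges, lag = 0L)
    else data.frame(from = character(0), to = character(0), lag = integer(0))
  } else dag$transition_edges
  vars <- intersect(dag$variables, names(panel$schema))
  cache <- pseudo_cache(panel, vars, seed)
  K <- part_K(panel, part)
  ppp <- penalty_per_param(K, score)
  tot_ll <- marginal_loglik(panel, vars, panel$waves, part)
  n_free <- 0L
  fits <- list()
  for (i in seq_len(nrow(edges))) {
    ec <- edge_contribution(cache, panel$waves, edges$from[i], edges$to[i],
                            edges$lag[i], part, ppp, catalogue, restarts, seed,
                            allow_null = FALSE)
    tot_ll <- tot_ll + ec$loglik
    n_free <- n_free + ec$k
    fits[[i]] <- data.frame(from = edges$from[i], to = edges$to[i],
                            lag = edges$lag[i], family = ec$family,
                            loglik = ec$loglik, k = ec$k,
                            stringsAsFactors = FALSE)
  }
  pen <- ppp * n_free
  structure(list(loglik = tot_ll, penalty = pen, bic = tot_ll - pen,
                 K = K, n_free_params = n_free,
                 edges = if (length(fits)) do.call(rbind, fits) else NULL,
                 part = part, score = score),
            class = "score_report")
}

#' @export
print.score_report <- function(x, ...) {
  cat(sprintf("<score report, %s part> loglik %.2f - penalty %.2f = %.2f (K = %d, |Theta| = %d)\n",
              x$part, x$loglik, x$penalty, x$bic, x$K, x$n_free_params))
  invisible(x)
}

edge_key <- function(from, to, lag) paste(from, to, lag, sep = "|")

valid_edge_set <- function(state, vars, exo, max_parents) {
  if (nrow(state) == 0) return(TRUE)
  if (any(state$to %in% exo)) return(FALSE)
  # the in-degree cap applies to within-slice parents; autoregressive lag
  # edges are structural persistence terms and are exempt
  indeg <- table(state$to[state$lag == 0])
  if (length(indeg) && any(indeg > max_parents)) return(FALSE)
  within <- state[state$lag == 0, ]
  if (nrow(within)) {
    if (any(within$from == within$to)) return(FALSE)
    g <- igraph::graph_from_data_frame(within[, c("from", "to")],
                                       directed = TRUE,
                                       vertices = data.frame(name = vars))
    if (!igraph::is_dag(g)) return(FALSE)
  }
  TRUE
}

#' Greedy hill-climbing structure search for one graph part
#'
#' Starting from a (possibly random) valid subgraph of the constraint
#' template, repeatedly applies the best strictly-improving add, delete or
#' reverse move until none improves the score, over multiple random restarts;
#' the best-scoring structure is returned.  Because the score decomposes over
#' edges, per-edge contributions are fitted once and cached.
#'
#' @param panel a [panel_dataset()].
#' @param constraints a [dynamic_dag()] template whose edges are the
#'   candidate set (reversals of within-slice candidates are also considered;
#'   lagged edges are never reversed).
#' @param part `"initial"` or `"transition"`.
#' @param restarts number of restarts (`>= 1`); the first starts empty, the
#'   rest from random subgraphs with edge-inclusion probability 0.3.
#' @param seed integer seed (search is deterministic given it).
#' @param catalogue,fit_restarts per-edge fitting controls.
#' @param max_parents in-degree cap per child.
#' @param score `"bic"`, `"aic"` or `"none"`.
#' @param trace log each accepted move via `message()`.
#' @return list with `dag` (the learned [dynamic_dag()]), `report` (a
#'   [bic_score()]-style `score_report`), and `edges`.
#' @export
greedy_search <- function(panel, constraints, part = c("initial", "transition"),
                          restarts = 5L, seed = 1L,
                          catalogue = c("gaussian", "clayton", "gumbel", "frank"),
                          fit_restarts = 2L, max_parents = 3L, score = "bic",
                          trace = FALSE) {
  part <- match.arg(part)
  stopifnot(restarts >= 1)
  validate_dag(constraints)
  vars <- constraints$variables
  exo <- constraints$exogenous_nodes
  cand <- if (part == "initial") cbind(constraints$g0_edges, lag = 0L)
          else constraints$transition_edges
  if (nrow(cand)) {
    rev0 <- cand[cand$lag == 0 & !(cand$from %in% exo) &
                 !(cand$from %in% constraints$baseline_vars), , drop = FALSE]
    if (nrow(rev0)) {
      rev0 <- data.frame(from = rev0$to, to = rev0$from, lag = 0L,
                         stringsAsFactors = FALSE)
      cand <- unique(rbind(cand, rev0[!rev0$to %in% exo, ]))
    }
  }
  rownames(cand) <- NULL
  svars <- intersect(vars, names(panel$schema))
  cache <- pseudo_cache(panel, svars, seed)
  K <- part_K(panel, part)
  ppp <- penalty_per_param(K, score)
  contrib <- new.env(parent = emptyenv())
  get_contrib <- function(i) {
    # within-slice contributions are cached under the unordered pair: the
    # search catalogue families are exchangeable, so both orientations share
    # one likelihood and orientation ties resolve by template order
    key <- if (cand$lag[i] == 0)
      edge_key(min(cand$from[i], cand$to[i]),
               max(cand$from[i], cand$to[i]), 0L)
    else edge_key(cand$from[i], cand$to[i], cand$lag[i])
    if (!exists(key, envir = contrib))
      assign(key, edge_contribution(cache, panel$waves, cand$from[i],
                                    cand$to[i], cand$lag[i], part, ppp,
                                    catalogue, fit_restarts, seed),
             envir = contrib)
    get(key, envir = contrib)
  }
  rev_index <- function(i) {
    if (cand$lag[i] == 1) return(NA_integer_)
    j <- which(cand$from == cand$to[i] & cand$to == cand$from[i] & cand$lag == 0)
    if (length(j)) j[1] else NA_integer_
  }
  # minimum score improvement to accept a move: absorbs optimiser noise so
  # equivalent-likelihood reorientations cannot flip edges
  tol_improve <- 1e-2
  climb <- function(in_state) {
    repeat {
      best_delta <- tol_improve; best_move <- NULL
      for (i in seq_len(nrow(cand))) {
        if (in_state[i]) {
          # delete
          st <- cand[in_state & seq_len(nrow(cand)) != i, , drop = FALSE]
          d <- -get_contrib(i)$score
          if (d > best_delta && valid_edge_set(st, vars, exo, max_parents)) {
            best_delta <- d; best_move <- list(op = "delete", i = i)
          }
          # reverse
          j <- rev_index(i)
          if (!is.na(j) && !in_state[j]) {
            keep <- in_state; keep[i] <- FALSE; keep[j] <- TRUE
            st <- cand[keep, , drop = FALSE]
            d <- get_contrib(j)$score - get_contrib(i)$score
            if (d > best_delta && valid_edge_set(st, vars, exo, max_parents)) {
              best_delta <- d; best_move <- list(op = "reverse", i = i, j = j)
            }
          }
        } else {
          st <- rbind(cand[in_state, , drop = FALSE], cand[i, , drop = FALSE])
          d <- get_contrib(i)$score
          if (d > best_delta && valid_edge_set(st, vars, exo, max_parents)) {
            best_delta <- d; best_move <- list(op = "add", i = i)
          }
        }
      }
      if (is.null(best_move)) break
      if (trace)
        message(sprintf("%s %s -> %s (delta = %.3f)", best_move$op,
                        cand$from[best_move$i], cand$to[best_move$i],
                        best_delta))
      if (best_move$op == "add") in_state[best_move$i] <- TRUE
      else if (best_move$op == "delete") in_state[best_move$i] <- FALSE
      else { in_state[best_move$i] <- FALSE; in_state[best_move$j] <- TRUE }
    }
    in_state
  }
  state_score <- function(in_state) {
    idx <- which(in_state)
    sum(vapply(idx, function(i) get_contrib(i)$score, 0))
  }
  best_state <- NULL; best_val <- -Inf
  for (r in seq_len(restarts)) {
    init <- if (r == 1) rep(FALSE, nrow(cand)) else
      with_seed(derive_seed(seed, "restart", part, r), {
        st <- stats::runif(nrow(cand)) < 0.3
        # repair to validity by dropping conflicting edges in random order
        ord <- sample(which(st))
        keep <- rep(FALSE, nrow(cand))
        for (i in ord) {
          keep[i] <- TRUE
          if (!valid_edge_set(cand[keep, , drop = FALSE], vars, exo,
                              max_parents)) keep[i] <- FALSE
        }
        keep
      })
    final <- climb(init)
    val <- state_score(final)
    if (val > best_val) { best_val <- val; best_state <- final }
  }
  chosen <- cand[best_state, , drop = FALSE]
  rownames(chosen) <- NULL
  dag <- if (part == "initial")
    dynamic_dag(vars, g0_edges = chosen[, c("from", "to")],
                exogenous_nodes = exo, baseline_vars = constraints$baseline_vars)
  else
    dynamic_dag(vars, transition_edges = chosen,
                exogenous_nodes = exo, baseline_vars = constraints$baseline_vars)
  validate_dag(dag)
  fits <- if (nrow(chosen)) do.call(rbind, lapply(which(best_state), function(i) {
    ec <- get_contrib(i)
    data.frame(from = cand$from[i], to = cand$to[i], lag = cand$lag[i],
               family = ec$family, loglik = ec$loglik, k = ec$k,
               stringsAsFactors = FALSE)
  })) else NULL
  mll <- marginal_loglik(panel, svars, panel$waves, part)
  tot_ll <- mll + sum(if (is.null(fits)) 0 else fits$loglik)
  n_free <- sum(if (is.null(fits)) 0L else fits$k)
  report <- structure(list(loglik = tot_ll, penalty = ppp * n_free,
                           bic = tot_ll - ppp * n_free, K = K,
                           n_free_params = n_free, edges = fits,
                           part = part, score = score),
                      class = "score_report")
  list(dag = dag, report = report, edges = chosen)
}

#' Learn the full dynamic structure (initial + transition graphs)
#'
#' Runs [greedy_search()] twice — on the first analysis wave for the initial
#' graph and on stacked consecutive wave pairs for the transition graph — and
#' merges the results into one dynamic DAG.  The total score is the sum of
#' the two parts (the score decomposes over them).
#'
#' @inheritParams greedy_search
#' @return list with `dag`, `initial` and `transition` search results, and
#'   `total_score`.
#' @export
learn_dynamic_structure <- function(panel, constraints, restarts = 5L,
                                    seed = 1L, ...) {
  if (length(panel$waves) < 2)
    stopf("structure learning needs a panel with at least 2 analysis waves")
  g0 <- greedy_search(panel, constraints, part = "initial",
                      restarts = restarts, seed = seed, ...)
  tr <- greedy_search(panel, constraints, part = "transition",
                      restarts = restarts, seed = seed, ...)
  dag <- dynamic_dag(constraints$variables,
                     g0_edges = g0$dag$g0_edges,
                     transition_edges = tr$dag$transition_edges,
                     exogenous_nodes = constraints$exogenous_nodes,
                     baseline_vars = constraints$baseline_vars)
  validate_dag(dag)
  list(dag = dag, initial = g0, transition = tr,
       total_score = g0$report$bic + tr$report$bic)
}

#' Edge-set F1 between a learned and a reference dynamic DAG
#'
#' Precision/recall/F1 over the union of initial and transition edge sets,
#' with edges identified by (from, to, lag, part).
#'
#' @param learned,reference [dynamic_dag()] objects.
#' @return list with `precision`, `recall`, `f1`, `tp`, `fp`, `fn`.
#' @export
structure_f1 <- function(learned, reference) {
  keys <- function(d) c(
    if (nrow(d$g0_edges)) paste("g0", d$g0_edges$from, d$g0_edges$to),
    if (nrow(d$transition_edges)) paste("tr", d$transition_edges$from,
                                        d$transition_edges$to,
                                        d$transition_edges$lag))
  kl <- keys(learned); kr <- keys(reference)
  tp <- length(intersect(kl, kr)); fp <- length(setdiff(kl, kr))
  fn <- length(setdiff(kr, kl))
  prec <- if (tp + fp == 0) 0 else tp / (tp + fp)
  rec <- if (tp + fn == 0) 0 else tp / (tp + fn)
  f1 <- if (prec + rec == 0) 0 else 2 * prec * rec / (prec + rec)
  list(precision = prec, recall = rec, f1 = f1, tp = tp, fp = fp, fn = fn)
}
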