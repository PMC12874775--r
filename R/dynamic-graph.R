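# Two-graph dynamic DAG structure: an initial graph over slice 0 and a
# transition graph whose edges run either within a slice or from slice t-1 to
# slice t.  Feedback is allowed across time; each slice must stay acyclic.

#' Construct a dynamic DAG
#'
#' @param variables ordered character vector of process names (one node per
#'   process per slice).
#' @param g0_edges data frame (`from`, `to`) of directed within-slice edges
#'   active at slice 0, or `NULL`.
#' @param transition_edges data frame (`from`, `to`, `lag`) with `lag = 1` for
#'   edges from slice t-1 to slice t and `lag = 0` for within-slice edges at
#'   slices t >= 1, or `NULL`.
#' @param exogenous_nodes variables treated as exogenous (never receiving
#'   learned parents; e.g. a community spillover proxy).
#' @param baseline_vars variables instantiated only at slice 0 (pre-program
#'   baseline measurements feeding the initial slice).
#' @return an object of class `dynamic_dag`.
#' @export
dynamic_dag <- function(variables, g0_edges = NULL, transition_edges = NULL,
                        exogenous_nodes = character(0),
                        baseline_vars = character(0)) {
  empty0 <- data.frame(from = character(0), to = character(0),
                       stringsAsFactors = FALSE)
  emptyT <- cbind(empty0, lag = integer(0))
  g0 <- if (is.null(g0_edges) || nrow(g0_edges) == 0) empty0 else
    data.frame(from = as.character(g0_edges$from),
               to = as.character(g0_edges$to), stringsAsFactors = FALSE)
  tr <- if (is.null(transition_edges) || nrow(transition_edges) == 0) emptyT else
    data.frame(from = as.character(transition_edges$from),
               to = as.character(transition_edges$to),
               lag = as.integer(transition_edges$lag),
               stringsAsFactors = FALSE)
  structure(list(variables = as.character(variables), g0_edges = g0,
                 transition_edges = tr,
                 exogenous_nodes = as.character(exogenous_nodes),
                 baseline_vars = as.character(baseline_vars)),
            class = "dynamic_dag")
}

#' @export
print.dynamic_dag <- function(x, ...) {
  cat(sprintf("<dynamic DAG> %d variable(s): %s\n", length(x$variables),
              paste(x$variables, collapse = ", ")))
  cat(sprintf("  G0: %d edge(s); transition: %d edge(s) (%d lagged)\n",
              nrow(x$g0_edges), nrow(x$transition_edges),
              sum(x$transition_edges$lag == 1)))
  invisible(x)
}

slice_cycle_check <- function(edges, vars, label) {
  if (nrow(edges) == 0) return(invisible(NULL))
  g <- igraph::graph_from_data_frame(edges, directed = TRUE,
                                     vertices = data.frame(name = vars))
  if (!igraph::is_dag(g)) {
    # name one offending cycle for the error message
    comp <- igraph::components(g, mode = "strong")
    bad <- names(comp$membership)[comp$membership ==
                                    which(comp$csize > 1)[1]]
    stopf("within-slice cycle in %s among: %s", label,
          paste(bad, collapse = ", "))
  }
  invisible(NULL)
}

#' Validate a dynamic DAG against the time-slice constraints
#'
#' Checks that (i) no slice contains a directed cycle, (ii) cross-time edges
#' have lag exactly 1 (slice t-1 to t), and (iii) no variable has a
#' within-slice self-edge.  Lagged self-loops (autoregressive persistence
#' edges) are allowed.
#'
#' @param dag a [dynamic_dag()].
#' @return the validated dag, invisibly the same object; errors name the
#'   offending edge or cycle.
#' @export
validate_dag <- function(dag) {
  stopifnot(inherits(dag, "dynamic_dag"))
  vars <- dag$variables
  for (e in list(dag$g0_edges, dag$transition_edges)) {
    bad <- setdiff(c(e$from, e$to), vars)
    if (length(bad)) stopf("edge endpoint(s) not in variables: %s",
                           paste(unique(bad), collapse = ", "))
  }
  if (any(dag$g0_edges$from == dag$g0_edges$to))
    stopf("within-slice self-edge in G0: %s",
          dag$g0_edges$from[dag$g0_edges$from == dag$g0_edges$to][1])
  tr0 <- dag$transition_edges[dag$transition_edges$lag == 0, ]
  if (any(tr0$from == tr0$to))
    stopf("within-slice self-edge in transition graph: %s",
          tr0$from[tr0$from == tr0$to][1])
  if (any(!dag$transition_edges$lag %in% c(0L, 1L))) {
    bad <- dag$transition_edges[!dag$transition_edges$lag %in% c(0L, 1L), ][1, ]
    stopf("cross-time edges may only run from slice t-1 to t; edge %s -> %s has lag %d",
          bad$from, bad$to, bad$lag)
  }
  slice_cycle_check(dag$g0_edges, vars, "G0")
  slice_cycle_check(tr0, vars, "transition slice")
  if (nrow(dag$g0_edges) && any(dag$g0_edges$to %in% dag$exogenous_nodes) ||
      nrow(dag$transition_edges) &&
        any(dag$transition_edges$to %in% dag$exogenous_nodes))
    stopf("exogenous node receives an edge")
  invisible(dag)
}

#' Unroll a dynamic DAG over time slices
#'
#' Slice 0 carries the initial-graph edges (plus baseline parents); slices
#' `1 .. n_slices - 1` carry the transition edges, with lag-1 edges connecting
#' consecutive slices.
#'
#' @param dag a validated [dynamic_dag()].
#' @param n_slices number of slices (`>= 1`).
#' @return an object of class `unrolled_dag` with `nodes` (data frame
#'   `variable`, `slice`, `node`) and `edges` (data frame `from`, `to`).
#' @export
unroll <- function(dag, n_slices) {
  validate_dag(dag)
  stopifnot(n_slices >= 1)
  node_name <- function(v, s) paste0(v, "[", s, "]")
  nodes <- do.call(rbind, lapply(seq_len(n_slices) - 1L, function(s) {
    vs <- if (s == 0) dag$variables else setdiff(dag$variables, dag$baseline_vars)
    data.frame(variable = vs, slice = s, node = node_name(vs, s),
               stringsAsFactors = FALSE)
  }))
  edges <- list()
  if (nrow(dag$g0_edges))
    edges[["g0"]] <- data.frame(from = node_name(dag$g0_edges$from, 0),
                                to = node_name(dag$g0_edges$to, 0),
                                stringsAsFactors = FALSE)
  if (n_slices > 1 && nrow(dag$transition_edges)) {
    for (s in seq_len(n_slices - 1)) {
      te <- dag$transition_edges
      edges[[paste0("t", s)]] <- data.frame(
        from = node_name(te$from, s - te$lag),
        to = node_name(te$to, s), stringsAsFactors = FALSE)
    }
  }
  edges <- if (length(edges)) do.call(rbind, edges) else
    data.frame(from = character(0), to = character(0))
  edges <- edges[edges$from %in% nodes$node & edges$to %in% nodes$node, ]
  rownames(edges) <- NULL
  g <- igraph::graph_from_data_frame(edges, directed = TRUE,
                                     vertices = nodes$node)
  if (!igraph::is_dag(g)) stopf("unrolled graph contains a cycle")
  structure(list(nodes = nodes, edges = edges, n_slices = n_slices),
            class = "unrolled_dag")
}

#' @export
print.unrolled_dag <- function(x, ...) {
  cat(sprintf("<unrolled DAG> %d node(s), %d edge(s), %d slice(s)\n",
              nrow(x$nodes), nrow(x$edges), x$n_slices))
  invisible(x)
}

#' Count joint configurations of an unrolled network
#'
#' @param dag an [unroll()] result.
#' @param states_per_node either a single state count applied to every node or
#'   a named count map by variable name.
#' @return product of the per-node state counts.
#' @examples
#' d <- dynamic_dag(c("A", "B"))
#' count_configurations(unroll(d, 2), 2)  # 16
#' @export
count_configurations <- function(dag, states_per_node) {
  stopifnot(inherits(dag, "unrolled_dag"))
  k <- if (length(states_per_node) == 1 && is.null(names(states_per_node)))
    rep(as.numeric(states_per_node), nrow(dag$nodes))
  else {
    m <- as.numeric(states_per_node[dag$nodes$variable])
    if (any(is.na(m))) stopf("state count missing for variable(s): %s",
      paste(unique(dag$nodes$variable[is.na(m)]), collapse = ", "))
    m
  }
  if (any(k < 1)) stopf("every node needs at least 1 state")
  prod(k)
}

#' Canonical study graph fixture
#'
#' The household-survey network over five processes: program participation
#' (PS), food security (FS), wealth quantile (WQ), mother subjective wellbeing
#' (MSW) and child undernutrition status (CUS).  Within-slice edges:
#' PS->FS, PS->WQ, PS->MSW, WQ->FS, FS->CUS, WQ->CUS, MSW->CUS (present in G0
#' and repeated in every transition slice).  Cross-slice self-loops: CUS, FS
#' and WQ persistence.  Optionally a leave-one-out community program intensity
#' (CPI) node with candidate edges into each process, and baseline variables
#' feeding the initial slice.
#'
#' @param include_cpi add the exogenous CPI node and its candidate edges.
#' @param include_baseline add baseline FS/WQ/CUS parents of slice 0.
#' @return a validated [dynamic_dag()].
#' @export
study_fixture <- function(include_cpi = FALSE, include_baseline = FALSE) {
  within <- data.frame(
    from = c("PS", "PS", "PS", "WQ", "FS", "WQ", "MSW"),
    to   = c("FS", "WQ", "MSW", "FS", "CUS", "CUS", "CUS"),
    stringsAsFactors = FALSE)
  loops <- data.frame(from = c("CUS", "FS", "WQ"), to = c("CUS", "FS", "WQ"),
                      lag = 1L, stringsAsFactors = FALSE)
  vars <- c("PS", "FS", "WQ", "MSW", "CUS")
  exo <- character(0); base <- character(0)
  g0 <- within
  tr <- rbind(cbind(within, lag = 0L), loops)
  if (include_cpi) {
    vars <- c(vars, "CPI"); exo <- c(exo, "CPI")
    cpi <- data.frame(from = "CPI", to = c("PS", "FS", "WQ", "MSW", "CUS"),
                      stringsAsFactors = FALSE)
    g0 <- rbind(g0, cpi)
    tr <- rbind(tr, cbind(cpi, lag = 0L))
  }
  if (include_baseline) {
    base <- c("FS.base", "WQ.base", "CUS.base")
    vars <- c(vars, base); exo <- c(exo, base)
    g0 <- rbind(g0, data.frame(from = base, to = c("FS", "WQ", "CUS"),
                               stringsAsFactors = FALSE))
  }
  validate_dag(dynamic_dag(vars, g0, tr, exogenous_nodes = exo,
                           baseline_vars = base))
}

#' Export a dynamic DAG as edge-list JSON
#'
#' @param dag a [dynamic_dag()].
#' @param path optional output path.
#' @return JSON text (or `path` invisibly when written).
#' @export
dag_to_json <- function(dag, path = NULL) {
  obj <- list(
    variables = dag$variables,
    exogenous_nodes = dag$exogenous_nodes,
    baseline_vars = dag$baseline_vars,
    edges = rbind(
      if (nrow(dag$g0_edges)) cbind(dag$g0_edges, lag = 0L, graph = "g0"),
      if (nrow(dag$transition_edges)) cbind(dag$transition_edges, graph = "transition")))
  js <- jsonlite::toJSON(obj, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  if (!is.null(path)) { writeLines(js, path); invisible(path) } else js
}

#' Import a dynamic DAG from edge-list JSON written by [dag_to_json()]
#' @param path JSON file path or JSON text.
#' @return a [dynamic_dag()].
#' @export
dag_from_json <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  e <- obj$edges
  dynamic_dag(obj$variables,
              g0_edges = if (!is.null(e)) e[e$graph == "g0", c("from", "to")],
              transition_edges = if (!is.null(e))
                e[e$graph == "transition", c("from", "to", "lag")],
              exogenous_nodes = obj$exogenous_nodes %||% character(0),
              baseline_vars = obj$baseline_vars %||% character(0))
}

#' Render a dynamic DAG as DOT text
#'
#' @param dag a [dynamic_dag()].
#' @param path optional output path.
#' @return DOT source text.
#' @export
dag_to_dot <- function(dag, path = NULL) {
  lines <- c("digraph dcbn {", "  rankdir=LR;")
  for (i in seq_len(nrow(dag$g0_edges)))
    lines <- c(lines, sprintf("  \"%s\" -> \"%s\" [label=\"g0\"];",
                              dag$g0_edges$from[i], dag$g0_edges$to[i]))
  for (i in seq_len(nrow(dag$transition_edges)))
    lines <- c(lines, sprintf("  \"%s\" -> \"%s\" [label=\"lag %d\"%s];",
                              dag$transition_edges$from[i],
                              dag$transition_edges$to[i],
                              dag$transition_edges$lag[i],
                              if (dag$transition_edges$lag[i] == 1)
                                ", style=dashed" else ""))
  lines <- c(lines, "}")
  txt <- paste(lines, collapse = "\n")
  if (!is.null(path)) { writeLines(txt, path); invisible(path) } else txt
}
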