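# Synthetic longitudinal household panel generator.
#
# Emulates the statistical structure the dynamic copula network assumes: a
# program-participation process with printed per-wave category margins,
# copula-linked child processes with slice-specific dependence, autoregressive
# persistence across waves (including two pre-program baseline waves), and
# community clustering.  All variables are emitted as ordinal categories
# discretised from latent uniform values, so the generator's dependence
# targets are exact on the latent scale and recoverable (up to discretisation
# attenuation) on the observed scale.

#' Printed program-participation margins and aggregation rules
#'
#' The per-wave percentages of the eight participation categories
#' (C, P, E, H, PE, PH, EH, PEH) for the 2009, 2013 and 2016 waves, stored
#' verbatim as printed, together with the aggregation map
#' `PSNP = P + PE + PH + PEH`, `HEP = H + EH + PH + PEH`,
#' `EAP = E + EH + PE + PEH`.  The 2013/2016 printed aggregates disagree with
#' their component sums by rounding; aggregates here are always computed from
#' the category cells.
#'
#' @return list with `margins` (3 x 8 percentage matrix, rows = waves),
#'   `aggregates` (component map) and `aggregate_percent` (computed from the
#'   cells).
#' @export
table1_fixture <- function() {
  cats <- c("C", "P", "E", "H", "PE", "PH", "EH", "PEH")
  m <- rbind(
    `2009` = c(65.0, 22.0, 9.0, 0.0, 4.0, 0.0, 0.0, 0.0),
    `2013` = c(14.0, 0.4, 1.0, 54.0, 0.0, 14.0, 12.0, 4.0),
    `2016` = c(16.0, 0.2, 0.0, 51.0, 0.1, 9.0, 20.0, 4.0))
  colnames(m) <- cats
  aggregates <- list(PSNP = c("P", "PE", "PH", "PEH"),
                     HEP = c("H", "EH", "PH", "PEH"),
                     EAP = c("E", "EH", "PE", "PEH"))
  agg <- t(vapply(aggregates, function(parts) rowSums(m[, parts, drop = FALSE]),
                  numeric(nrow(m))))
  list(margins = m, aggregates = aggregates, aggregate_percent = agg)
}

#' Default child-undernutrition state labels
#'
#' Eight anthropometric states: normal (N), underweight (U), stunted (S),
#' wasted (W) and their combinations, ordered by number of conditions; the
#' binary collapse maps N to 0 and every other state to 1.
#' @return character vector of the 8 labels.
#' @export
cus_state_labels <- function() c("N", "U", "S", "W", "US", "UW", "SW", "USW")

#' Collapse 8-state undernutrition labels to binary
#' @param values vector of state labels.
#' @return integer vector, 0 = normal, 1 = any undernutrition condition.
#' @export
collapse_cus <- function(values) {
  v <- as.character(values)
  bad <- setdiff(unique(v[!is.na(v)]), cus_state_labels())
  if (length(bad)) stopf("unknown undernutrition state(s): %s",
                         paste(bad, collapse = ", "))
  as.integer(v != "N")
}

default_edge_specs <- function() {
  # slice-specific Kendall tau targets per within-slice edge, one value per
  # analysis wave; the Gaussian family attains the full printed range of
  # positive and negative dependencies
  list(
    list(from = "PS",  to = "FS",  family = "gaussian", tau = c(0.392, 0.517, 0.624)),
    list(from = "PS",  to = "WQ",  family = "gaussian", tau = c(0.588, 0.745, 0.855)),
    list(from = "PS",  to = "MSW", family = "gaussian", tau = c(0.454, 0.444, 0.828)),
    list(from = "WQ",  to = "FS",  family = "gaussian", tau = c(0.561, 0.712, 0.572)),
    list(from = "FS",  to = "CUS", family = "gaussian", tau = c(-0.33, -0.418, -0.60)),
    list(from = "WQ",  to = "CUS", family = "gaussian", tau = c(-0.376, -0.788, -0.675)),
    list(from = "MSW", to = "CUS", family = "gaussian", tau = c(0.622, 0.634, 0.613)))
}

default_persistence_specs <- function() {
  # per-transition tau for the four consecutive wave pairs
  # (2002->2006, 2006->2009, 2009->2013, 2013->2016); the two pre-program
  # transitions use a moderate persistence of 0.5
  list(
    CUS = list(family = "gaussian", tau = c(0.5, 0.5, 0.481, 0.614)),
    FS  = list(family = "gaussian", tau = c(0.5, 0.5, 0.064, 0.846)),
    WQ  = list(family = "gaussian", tau = c(0.5, 0.5, 0.541, 0.755)))
}

default_marginals <- function() {
  list(
    FS  = list(levels = 1:4, probs = c(0.25, 0.30, 0.25, 0.20)),
    WQ  = list(levels = 1:5, probs = rep(0.2, 5)),
    MSW = list(levels = 1:5, probs = c(0.10, 0.20, 0.35, 0.25, 0.10)),
    CUS = list(levels = cus_state_labels(),
               probs = c(0.55, 0.10, 0.18, 0.04, 0.06, 0.02, 0.03, 0.02)))
}

#' Generative specification for a synthetic household panel
#'
#' Defaults encode the study-like conditions: 1900 households in 20
#' communities, two pre-program baseline waves plus three analysis waves,
#' program-participation margins from [table1_fixture()] (normalised to sum
#' to one), slice-specific edge dependencies at the printed temporal-edge tau
#' values and persistence at the printed self-loop tau values.
#'
#' @param n_units number of households.
#' @param n_communities number of communities (units assigned uniformly).
#' @param baseline_waves,analysis_waves ordered wave labels.
#' @param ps_margins matrix (analysis waves x 8) of participation-category
#'   probabilities or percentages; rows are normalised to sum to 1.
#' @param edge_specs list of within-slice edge specs: `from`, `to`, `family`,
#'   and either `tau` (one per analysis wave, inverted per wave) or `theta`
#'   (list of parameter vectors per wave).
#' @param persistence_specs named list (by variable) of self-loop specs with
#'   `family` and `tau` (one per consecutive wave pair over all waves).
#' @param marginals named list of `list(levels, probs)` per child variable.
#' @param confounding_smd target standardised mean difference of baseline
#'   covariates between eventual participants and non-participants.
#' @param seed integer seed.
#' @return an object of class `synthetic_config`.
#' @export
synthetic_config <- function(n_units = 1900L, n_communities = 20L,
                             baseline_waves = c("2002", "2006"),
                             analysis_waves = c("2009", "2013", "2016"),
                             ps_margins = table1_fixture()$margins,
                             edge_specs = default_edge_specs(),
                             persistence_specs = default_persistence_specs(),
                             marginals = default_marginals(),
                             confounding_smd = 0.18,
                             seed = 1L) {
  stopifnot(n_units >= 2, n_communities >= 1)
  ps_margins <- as.matrix(ps_margins)
  if (nrow(ps_margins) != length(analysis_waves))
    stopf("ps_margins must have one row per analysis wave")
  ps_margins <- ps_margins / rowSums(ps_margins)
  if (any(abs(rowSums(ps_margins) - 1) > 1e-9)) stopf("margins fail to normalise")
  waves <- c(baseline_waves, analysis_waves)
  n_trans <- length(waves) - 1
  for (v in names(persistence_specs)) {
    sp <- persistence_specs[[v]]
    if (!is.null(sp$tau) && length(sp$tau) != n_trans)
      stopf("persistence spec for %s needs %d tau values (one per wave pair)",
            v, n_trans)
  }
  for (e in edge_specs) {
    if (!is.null(e$tau) && length(e$tau) != length(analysis_waves))
      stopf("edge %s->%s needs one tau per analysis wave", e$from, e$to)
  }
  for (m in marginals) {
    if (abs(sum(m$probs) - 1) > 1e-9) stopf("marginal probs must sum to 1")
  }
  structure(list(n_units = as.integer(n_units),
                 n_communities = as.integer(n_communities),
                 baseline_waves = baseline_waves,
                 analysis_waves = analysis_waves, waves = waves,
                 ps_margins = ps_margins, edge_specs = edge_specs,
                 persistence_specs = persistence_specs, marginals = marginals,
                 confounding_smd = confounding_smd,
                 seed = as.integer(seed)),
            class = "synthetic_config")
}

#' @export
print.synthetic_config <- function(x, ...) {
  cat(sprintf("<synthetic config> %d units, %d communities, waves %s\n",
              x$n_units, x$n_communities, paste(x$waves, collapse = ", ")))
  cat(sprintf("  %d edge spec(s), %d persistence spec(s), seed %d\n",
              length(x$edge_specs), length(x$persistence_specs), x$seed))
  invisible(x)
}

edge_theta <- function(spec, wave_idx) {
  if (!is.null(spec$theta)) return(copula_params(spec$family, spec$theta[[wave_idx]]))
  tau <- spec$tau[wave_idx]
  if (abs(tau) < 1e-12) return(copula_params("independence"))
  theta_from_tau(spec$family, tau)
}

discretise <- function(u, levels, probs) {
  cuts <- cumsum(probs)
  idx <- findInterval(u, cuts, left.open = TRUE) + 1L
  levels[pmin(idx, length(levels))]
}

#' Generate a synthetic longitudinal panel
#'
#' Each wave draws the program-participation latent uniform from the wave's
#' category margins; every child variable's latent uniform is produced by
#' successively inverting the conditional h-functions of its parent edges
#' (persistence innermost, then within-slice parents so the first-declared
#' parent couples outermost), then discretised through its declared marginal.
#' The latent (rank) values, not the discretised categories, feed child
#' conditionals, so a single-parent edge's dependence target holds exactly on
#' the latent scale; with multiple parents the inner couplings are attenuated
#' by the outer ones.
#'
#' @param config a [synthetic_config()].
#' @return a [panel_dataset()] with variables `PS`, `FS`, `WQ`, `MSW`, `CUS`
#'   (8-state labels) and `CUS_bin`; baseline waves carry `FS`, `WQ`, `CUS`
#'   only.  The orientation flag of `CUS` is `-1` after collapsing, matching
#'   the convention that higher coded values mean less undernutrition after
#'   harmonisation is applied externally; here `CUS_bin` is 1 = undernourished.
#' @export
generate_panel <- function(config) {
  stopifnot(inherits(config, "synthetic_config"))
  n <- config$n_units
  waves <- config$waves
  n_base <- length(config$baseline_waves)
  edge_by_child <- split(config$edge_specs,
                         vapply(config$edge_specs, `[[`, "", "to"))
  # latent uniforms per variable per wave
  lat <- list()
  recs <- list()
  with_seed(derive_seed(config$seed, "panel"), {
    community <- sample(rep_len(seq_len(config$n_communities), n))
    for (t in seq_along(waves)) {
      wv <- waves[t]
      is_analysis <- t > n_base
      a_idx <- t - n_base
      lat[[wv]] <- list()
      if (is_analysis) {
        u_ps <- stats::runif(n)
        lat[[wv]][["PS"]] <- u_ps
      }
      for (v in c("WQ", "MSW", "FS", "CUS")) {   # parent-respecting order
        if (!is_analysis && !v %in% names(config$persistence_specs)) next
        if (v == "MSW" && !is_analysis) next
        w <- stats::runif(n)
        # persistence edge applied first (innermost coupling)
        if (t > 1 && v %in% names(config$persistence_specs)) {
          sp <- config$persistence_specs[[v]]
          prev <- lat[[waves[t - 1]]][[v]]
          if (!is.null(prev)) {
            tau <- sp$tau[t - 1]
            if (abs(tau) > 1e-12) {
              p <- theta_from_tau(sp$family, tau)
              w <- inverse_conditional_cdf(p, w, prev)
            }
          }
        }
        # within-slice parents (analysis waves only) applied in reverse
        # declared order, so the first-declared parent couples outermost
        if (is_analysis && v %in% names(edge_by_child)) {
          specs <- edge_by_child[[v]]
          for (k in rev(seq_along(specs))) {
            sp <- specs[[k]]
            if (is.null(lat[[wv]][[sp$from]])) next
            p <- edge_theta(sp, a_idx)
            if (p$family$name != "independence")
              w <- inverse_conditional_cdf(p, w, lat[[wv]][[sp$from]])
          }
        }
        lat[[wv]][[v]] <- w
      }
      # discretise and record
      row <- data.frame(unit_id = seq_len(n), community_id = community,
                        wave = wv, stringsAsFactors = FALSE)
      if (is_analysis) {
        cats <- colnames(config$ps_margins)
        row$PS <- discretise(lat[[wv]][["PS"]], cats,
                             config$ps_margins[a_idx, ])
      } else row$PS <- NA_character_
      for (v in c("FS", "WQ", "MSW", "CUS")) {
        if (is.null(lat[[wv]][[v]])) { row[[v]] <- NA; next }
        m <- config$marginals[[v]]
        row[[v]] <- discretise(lat[[wv]][[v]], m$levels, m$probs)
      }
      row$CUS_bin <- if (all(is.na(row$CUS))) NA_integer_ else
        collapse_cus(row$CUS)
      recs[[wv]] <- row
    }
  })
  data <- do.call(rbind, recs)
  rownames(data) <- NULL
  ps_levels <- colnames(config$ps_margins)
  schema <- list(
    PS  = var_schema("ordinal", levels = ps_levels),
    FS  = var_schema("ordinal", levels = config$marginals$FS$levels),
    WQ  = var_schema("ordinal", levels = config$marginals$WQ$levels),
    MSW = var_schema("ordinal", levels = config$marginals$MSW$levels),
    CUS = var_schema("ordinal", levels = config$marginals$CUS$levels),
    CUS_bin = var_schema("binary", levels = c(0L, 1L)))
  panel_dataset(data, schema, waves = config$analysis_waves,
                baseline_waves = config$baseline_waves)
}

#' Serialize a synthetic configuration to JSON
#'
#' @param config a [synthetic_config()].
#' @param path optional output path.
#' @return JSON text, or `path` invisibly when written.
#' @export
config_to_json <- function(config, path = NULL) {
  stopifnot(inherits(config, "synthetic_config"))
  obj <- unclass(config)
  obj$ps_margins <- list(categories = colnames(config$ps_margins),
                         rows = apply(config$ps_margins, 1, as.numeric,
                                      simplify = FALSE))
  js <- jsonlite::toJSON(obj, auto_unbox = TRUE, digits = NA, pretty = TRUE,
                         null = "null")
  if (!is.null(path)) { writeLines(js, path); invisible(path) } else js
}

#' Read a synthetic configuration written by [config_to_json()]
#' @param path JSON file path or JSON text.
#' @return a [synthetic_config()].
#' @export
config_from_json <- function(path) {
  o <- jsonlite::read_json(path, simplifyVector = FALSE)
  chr <- function(x) vapply(x, as.character, "")
  m <- do.call(rbind, lapply(o$ps_margins$rows, function(r)
    as.numeric(unlist(r))))
  dimnames(m) <- list(chr(o$analysis_waves), chr(o$ps_margins$categories))
  fix_spec <- function(s) {
    out <- list(family = s$family)
    if (!is.null(s$from)) { out$from <- s$from; out$to <- s$to }
    if (!is.null(s$tau)) out$tau <- as.numeric(unlist(s$tau))
    if (!is.null(s$theta)) out$theta <- lapply(s$theta, function(t)
      as.numeric(unlist(t)))
    out[intersect(names(s), names(out))]
  }
  synthetic_config(
    n_units = o$n_units, n_communities = o$n_communities,
    baseline_waves = chr(o$baseline_waves),
    analysis_waves = chr(o$analysis_waves),
    ps_margins = m, edge_specs = lapply(o$edge_specs, fix_spec),
    persistence_specs = lapply(o$persistence_specs, fix_spec),
    marginals = lapply(o$marginals, function(mm) {
      lv <- unlist(mm$levels)
      if (!anyNA(suppressWarnings(as.numeric(lv)))) {
        lv <- as.numeric(lv)
        if (all(lv == round(lv))) lv <- as.integer(lv)
      }
      list(levels = lv, probs = as.numeric(unlist(mm$probs)))
    }),
    confounding_smd = o$confounding_smd, seed = o$seed)
}

#' Baseline covariates with controllable confounding
#'
#' Generates pre-program covariates (baseline food security, wealth and
#' undernutrition scores, household size, mother's age and education, all on
#' standardised scales) whose means differ between eventual participants and
#' non-participants by a target standardised mean difference, enabling
#' propensity-weighting and balance diagnostics on synthetic data.
#' Participation is taken from the panel's first analysis wave
#' (`PS != "C"`).
#'
#' @param panel a [generate_panel()] result.
#' @param smd_target target standardised mean difference for the most
#'   imbalanced covariate (others get half the shift).
#' @param seed integer seed.
#' @return data frame keyed by `unit_id` with `participation` and six
#'   standardised covariates.
#' @export
baseline_covariates <- function(panel, smd_target = 0.18, seed = 1L) {
  stopifnot(inherits(panel, "panel_dataset"))
  w0 <- panel$waves[1]
  d <- panel$data[as.character(panel$data$wave) == w0, ]
  a <- as.integer(as.character(d$PS) != "C")
  n <- nrow(d)
  covs <- c("wq_base", "fs_base", "cus_base", "hh_size", "mother_age",
            "mother_edu")
  shift <- c(1, 0.5, 0.5, 0.5, 0.5, 0.5) * smd_target
  out <- with_seed(derive_seed(seed, "baseline_covariates"), {
    m <- vapply(seq_along(covs), function(k)
      stats::rnorm(n) + shift[k] * a, numeric(n))
    colnames(m) <- covs
    as.data.frame(m)
  })
  cbind(data.frame(unit_id = d$unit_id, participation = a), out)
}
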