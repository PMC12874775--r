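# Long-format longitudinal panel container.
#
# A panel couples the raw records (one row per unit x wave) with a variable
# schema declaring, for each modelled variable, its measurement scale, ordered
# support and orientation.  Orientation harmonisation (e.g. flipping a scale
# so that higher always means "more of the named condition") is applied once
# here, at load time, by coding each variable as its level index times the
# declared orientation; all downstream rank statistics consume the coded
# values and never re-orient.

#' Declare a variable schema entry
#'
#' @param scale `"binary"`, `"ordinal"` or `"continuous"`.
#' @param levels ordered support for discrete scales.
#' @param orientation `+1` or `-1`; `-1` reverses the coded direction.
#' @return a schema entry list.
#' @export
var_schema <- function(scale = c("ordinal", "binary", "continuous"),
                       levels = NULL, orientation = 1) {
  scale <- match.arg(scale)
  if (scale != "continuous" && is.null(levels))
    stopf("discrete schema entries need explicit ordered levels")
  stopifnot(orientation %in% c(-1, 1))
  list(scale = scale, levels = levels, orientation = orientation)
}

#' Construct a panel dataset
#'
#' @param data data frame with columns `unit_id`, `community_id`, `wave`, plus
#'   one column per schema variable (extra columns are carried through).
#' @param schema named list of [var_schema()] entries.
#' @param waves ordered character vector of analysis waves.
#' @param baseline_waves optional ordered character vector of pre-program
#'   waves present in `data`.
#' @return an object of class `panel_dataset` with the raw `data`, the
#'   harmonised numeric `coded` values and the schema.
#' @export
panel_dataset <- function(data, schema, waves, baseline_waves = character(0)) {
  req <- c("unit_id", "community_id", "wave")
  miss <- setdiff(req, names(data))
  if (length(miss)) stopf("panel data lacks column(s): %s",
                          paste(miss, collapse = ", "))
  if (anyDuplicated(data[, c("unit_id", "wave")]))
    stopf("(unit_id, wave) pairs must be unique")
  waves <- as.character(waves)
  vars <- names(schema)
  miss <- setdiff(vars, names(data))
  if (length(miss)) stopf("schema variable(s) missing from data: %s",
                          paste(miss, collapse = ", "))
  coded <- data[, req]
  for (v in vars) {
    s <- schema[[v]]
    if (s$scale == "continuous") {
      coded[[v]] <- s$orientation * as.numeric(data[[v]])
    } else {
      idx <- match(as.character(data[[v]]), as.character(s$levels))
      if (any(is.na(idx) & !is.na(data[[v]])))
        stopf("variable '%s' has values outside its declared levels", v)
      coded[[v]] <- s$orientation * idx
    }
  }
  structure(list(data = data, coded = coded, schema = schema,
                 waves = waves, baseline_waves = as.character(baseline_waves)),
            class = "panel_dataset")
}

#' @export
print.panel_dataset <- function(x, ...) {
  cat(sprintf("<panel> %d records, %d units, %d communities; waves: %s\n",
              nrow(x$data), length(unique(x$data$unit_id)),
              length(unique(x$data$community_id)),
              paste(x$waves, collapse = ", ")))
  if (length(x$baseline_waves))
    cat(sprintf("  baseline waves: %s\n", paste(x$baseline_waves, collapse = ", ")))
  cat(sprintf("  variables: %s\n", paste(names(x$schema), collapse = ", ")))
  invisible(x)
}

# Harmonised numeric values of one variable on a subset of rows.
panel_coded <- function(panel, rows, var) {
  if (!var %in% names(panel$coded)) stopf("variable '%s' not in panel", var)
  panel$coded[[var]][rows]
}

# Pseudo-uniform values of a variable on given rows; marginals are estimated
# per wave on the coded scale, discrete variables get the distributional
# transform keyed by (variable, wave, seed).
panel_pseudo <- function(panel, rows, var, wave, seed) {
  x <- panel_coded(panel, rows, var)
  s <- panel$schema[[var]]
  scale <- if (is.null(s)) "continuous" else s$scale
  if (scale == "continuous") {
    m <- estimate_marginal(x, "continuous")
    clamp_unit(pit_transform(x, m))
  } else {
    m <- estimate_marginal(x, scale, levels = sort(unique(x)))
    clamp_unit(distributional_transform(x, m, derive_seed(seed, var, wave)))
  }
}

#' Write a panel to delimited text with a JSON schema sidecar
#'
#' @param panel a [panel_dataset()].
#' @param path CSV output path; the sidecar is written to `<path>.schema.json`.
#' @param header_comment optional comment lines prefixed with `#`.
#' @return `path`, invisibly.
#' @export
write_panel <- function(panel, path, header_comment = NULL) {
  con <- file(path, "w")
  on.exit(close(con))
  if (!is.null(header_comment))
    writeLines(paste0("# ", header_comment), con)
  utils::write.csv(panel$data, con, row.names = FALSE)
  meta <- list(
    waves = panel$waves, baseline_waves = panel$baseline_waves,
    schema = lapply(panel$schema, function(s)
      list(scale = s$scale, levels = s$levels, orientation = s$orientation)))
  jsonlite::write_json(meta, paste0(path, ".schema.json"), auto_unbox = TRUE,
                       digits = NA, null = "null")
  invisible(path)
}

#' Read a panel written by [write_panel()]
#'
#' @param path CSV path with a `<path>.schema.json` sidecar.
#' @return a [panel_dataset()].
#' @export
read_panel <- function(path) {
  meta <- jsonlite::read_json(paste0(path, ".schema.json"), simplifyVector = TRUE)
  df <- utils::read.csv(path, comment.char = "#", stringsAsFactors = FALSE)
  schema <- lapply(meta$schema, function(s)
    var_schema(s$scale, levels = s$levels, orientation = s$orientation))
  panel_dataset(df, schema, waves = meta$waves,
                baseline_waves = meta$baseline_waves %||% character(0))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
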