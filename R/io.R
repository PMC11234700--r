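# Model configs are structured YAML with top-level keys `parameters`,
# `tree`, `settings` (schema version ceatree-model/1.0; a JSON-schema
# document ships under inst/schema/). Results serialise to plain CSV/JSON:
# comma-separated, dot decimal, header row, full double precision so files
# round-trip exactly.

CONFIG_SCHEMA <- "ceatree-model/1.0"

config_error <- function(problems) {
  structure(
    class = c("ceatree_config_error", "error", "condition"),
    list(message = paste0("invalid model config:\n",
                          paste0("  - ", problems, collapse = "\n")),
         call = NULL, problems = problems)
  )
}

# Structural (schema-level) checks on a parsed config list; returns a
# character vector of problems.
config_violations <- function(cfg) {
  problems <- character(0)
  note <- function(...) problems <<- c(problems, paste0(...))
  if (!is.list(cfg)) return("config is not a mapping")
  for (key in c("parameters", "tree", "settings")) {
    if (is.null(cfg[[key]])) note("missing top-level key '", key, "'")
  }
  if (!is.null(cfg$schema) && !identical(cfg$schema, CONFIG_SCHEMA)) {
    note("unsupported schema '", cfg$schema, "' (expected ", CONFIG_SCHEMA, ")")
  }
  if (!is.null(cfg$parameters)) {
    for (i in seq_along(cfg$parameters)) {
      p <- cfg$parameters[[i]]
      for (key in c("name", "kind", "base")) {
        if (is.null(p[[key]])) note("parameter #", i, ": missing '", key, "'")
      }
      if (!is.null(p$kind) && !p$kind %in% PARAM_KINDS) {
        note("parameter #", i, ": unknown kind '", p$kind, "'")
      }
      if (!is.null(p$dist) && !is.null(p$dist$family) &&
          !p$dist$family %in% DIST_FAMILIES) {
        note("parameter #", i, ": unknown distribution family '",
             p$dist$family, "'")
      }
    }
  }
  if (!is.null(cfg$tree)) {
    if (is.null(cfg$tree$strategies) || length(cfg$tree$strategies) < 1L) {
      note("tree: missing or empty 'strategies'")
    } else {
      check_node <- function(nd, where) {
        if (is.null(nd$kind) || !nd$kind %in% c("chance", "terminal")) {
          note(where, ": node kind must be 'chance' or 'terminal'")
          return(invisible())
        }
        if (nd$kind == "terminal") {
          # missing cost/effect is legal here; validate_tree reports it
          return(invisible())
        }
        if (is.null(nd$branches) || length(nd$branches) < 1L) {
          note(where, ": chance node without branches")
          return(invisible())
        }
        for (j in seq_along(nd$branches)) {
          b <- nd$branches[[j]]
          if (is.null(b$prob)) note(where, " branch #", j, ": missing 'prob'")
          if (is.null(b$node)) note(where, " branch #", j, ": missing 'node'")
          else check_node(b$node, paste0(where, " branch #", j))
        }
      }
      for (i in seq_along(cfg$tree$strategies)) {
        s <- cfg$tree$strategies[[i]]
        if (is.null(s$label)) note("strategy #", i, ": missing 'label'")
        check_node(s, paste0("strategy #", i))
      }
    }
  }
  if (!is.null(cfg$settings)) {
    if (is.null(cfg$settings$wtp)) note("settings: missing 'wtp'")
  }
  problems
}

node_from_list <- function(nd) {
  if (nd$kind == "terminal") {
    terminal_node(nd$label %||% "terminal",
                  cost = if (is.null(nd$cost)) NULL else as.character(nd$cost),
                  effect = if (is.null(nd$effect)) NULL else as.character(nd$effect))
  } else {
    chance_node(nd$label %||% "chance",
                lapply(nd$branches, function(b) {
                  branch(as.character(b$prob), node_from_list(b$node))
                }))
  }
}

node_to_list <- function(node) {
  if (node$node_kind == "terminal") {
    out <- list(kind = "terminal", label = node$label)
    if (!is.null(node$cost)) out$cost <- node$cost
    if (!is.null(node$effect)) out$effect <- node$effect
    out
  } else {
    list(kind = "chance", label = node$label,
         branches = lapply(node$branches, function(b) {
           list(prob = b$prob, node = node_to_list(b$node))
         }))
  }
}

#' Read a model config
#'
#' Loads a YAML model config (`parameters`, `tree`, `settings`), enforces
#' the config schema, and assembles a [cua_model()]. Schema violations
#' raise a `ceatree_config_error` carrying the full problem report.
#'
#' @param path Path to a YAML file.
#' @return A [cua_model()].
#' @export
#' @examples
#' path <- system.file("extdata", "acl_indonesia.yaml", package = "ceatree")
#' model <- read_model(path)
read_model <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  cfg <- yaml::read_yaml(path)
  problems <- config_violations(cfg)
  if (length(problems) > 0L) stop(config_error(problems))
  params <- parameter_set(lapply(cfg$parameters, function(p) {
    parameter(p$name, p$kind, as.numeric(p$base),
              low = as.numeric(p$low %||% p$base),
              high = as.numeric(p$high %||% p$base),
              dist = if (is.null(p$dist)) NULL else
                dist_spec(p$dist$family, p$dist$mean, p$dist$se))
  }))
  strategies <- lapply(cfg$tree$strategies, function(s) {
    structure_strategy(node_from_list(s), s$label)
  })
  tree <- decision_tree(cfg$tree$label %||% "model", strategies)
  st <- cfg$settings
  settings <- analysis_settings(
    wtp = st$wtp,
    discount_rate = st$discount_rate %||% 0.03,
    horizon_months = st$horizon_months %||% 18,
    effectiveness_mode = st$effectiveness_mode %||% "utility_at_horizon",
    psa_draws = st$psa_draws %||% 5000,
    seed = st$seed %||% 1L
  )
  cua_model(tree, params, settings)
}

#' Write a model config
#'
#' @param model A [cua_model()].
#' @param path Output YAML path.
#' @return `path`, invisibly.
#' @export
write_model <- function(model, path) {
  stopifnot(inherits(model, "cua_model"))
  params <- lapply(unname(as.list(model$params)), function(p) {
    out <- list(name = p$name, kind = p$kind, base = p$base,
                low = p$low, high = p$high)
    if (!is.null(p$dist)) {
      out$dist <- list(family = p$dist$family)
      if (!is.null(p$dist$mean)) out$dist$mean <- p$dist$mean
      if (!is.null(p$dist$se)) out$dist$se <- p$dist$se
    }
    out
  })
  strategies <- lapply(names(model$tree$strategies), function(s) {
    nl <- node_to_list(model$tree$strategies[[s]])
    nl$label <- s
    nl
  })
  st <- model$settings
  cfg <- list(
    schema = CONFIG_SCHEMA,
    parameters = params,
    tree = list(label = model$tree$label, strategies = strategies),
    settings = list(wtp = st$wtp, discount_rate = st$discount_rate,
                    horizon_months = st$horizon_months,
                    effectiveness_mode = st$effectiveness_mode,
                    psa_draws = st$psa_draws, seed = st$seed)
  )
  yaml::write_yaml(cfg, path, precision = 15)
  invisible(path)
}

# Full-precision CSV: values survive a write/read round trip.
write_result_csv <- function(df, path) {
  out <- as.data.frame(df)
  for (i in seq_along(out)) {
    if (is.numeric(out[[i]])) {
      out[[i]] <- vapply(out[[i]], function(x) {
        if (is.na(x)) NA_character_ else format(x, digits = 15, scientific = FALSE)
      }, character(1))
    }
  }
  utils::write.csv(out, path, row.names = FALSE, quote = TRUE, na = "")
  invisible(path)
}

#' Write a CEA table to CSV
#' @param table A [cea_table()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_cea_csv <- function(table, path) write_result_csv(table, path)

#' Write PSA samples to CSV
#' @param samples A `psa_samples` tibble.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_psa_csv <- function(samples, path) write_result_csv(samples, path)

#' Write CEAC curves to CSV
#' @param curve A `ceac_curve` tibble.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_ceac_csv <- function(curve, path) write_result_csv(curve, path)

#' Write a tornado result to CSV
#' @param result A `tornado_result` tibble.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_tornado_csv <- function(result, path) write_result_csv(result, path)

#' Write a threshold result to JSON
#' @param result A `threshold_result`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_threshold_json <- function(result, path) {
  jsonlite::write_json(unclass(result), path, auto_unbox = TRUE, digits = NA,
                       na = "null")
  invisible(path)
}
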