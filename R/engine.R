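# Tree evaluation: expected-value rollback, path enumeration (the
# brute-force oracle used by the test suite) and discounting.

#' Analysis settings
#'
#' @param wtp Willingness-to-pay threshold, US$ per QALY.
#' @param discount_rate Annual discount rate (fraction per year). Applied
#'   only in `time_integrated` mode; see `effectiveness_mode`.
#' @param horizon_months Model horizon in months.
#' @param effectiveness_mode `"utility_at_horizon"` (default): the effect of
#'   a path is its terminal utility, so strategy effects are on the utility
#'   scale. `"time_integrated"`: effect is utility accrued over the horizon,
#'   `u * (1 - (1+r)^-T) / log(1+r)` QALYs for horizon `T` years at rate
#'   `r` (continuously discounted; `u * T` when `r = 0`).
#' @param psa_draws Default number of PSA draws.
#' @param seed Default random seed for stochastic analyses.
#' @return An `analysis_settings` list.
#' @export
analysis_settings <- function(wtp,
                              discount_rate = 0.03,
                              horizon_months = 18,
                              effectiveness_mode = c("utility_at_horizon",
                                                     "time_integrated"),
                              psa_draws = 5000,
                              seed = 1L) {
  effectiveness_mode <- match.arg(effectiveness_mode)
  stopifnot(is.numeric(wtp), wtp >= 0,
            is.numeric(discount_rate), discount_rate > -1,
            is.numeric(horizon_months), horizon_months > 0,
            is.numeric(psa_draws), psa_draws >= 1)
  structure(
    list(wtp = wtp, discount_rate = discount_rate,
         horizon_months = horizon_months,
         effectiveness_mode = effectiveness_mode,
         psa_draws = as.integer(psa_draws), seed = as.integer(seed)),
    class = "analysis_settings"
  )
}

#' Discount factor
#'
#' Present-value factor `(1 + rate)^(-t_years)`.
#'
#' @param t_years Time in years (non-negative).
#' @param rate Annual discount rate, `> -1`.
#' @return Discount factor(s).
#' @export
#' @examples
#' discount_factor(1, 0.03) # 1 / 1.03
discount_factor <- function(t_years, rate) {
  stopifnot(all(t_years >= 0), rate > -1)
  (1 + rate)^(-t_years)
}

# QALYs accrued per unit utility over the horizon, by effectiveness mode.
effect_multiplier <- function(settings) {
  if (settings$effectiveness_mode == "utility_at_horizon") return(1)
  T <- settings$horizon_months / 12
  r <- settings$discount_rate
  if (r == 0) T else (1 - (1 + r)^(-T)) / log(1 + r)
}

# Pre-parse all expressions of a tree once; per-draw evaluation then only
# calls eval() on cached language objects.
prepare_tree <- function(tree) {
  prep_node <- function(node) {
    if (node$node_kind == "terminal") {
      node$cost_lang <- parse_model_expr(node$cost)
      node$effect_lang <- parse_model_expr(node$effect)
    } else if (node$node_kind == "chance") {
      for (i in seq_along(node$branches)) {
        b <- node$branches[[i]]
        node$branches[[i]]$prob_lang <-
          if (identical(b$prob, "complement")) "complement"
          else parse_model_expr(b$prob)
        node$branches[[i]]$node <- prep_node(b$node)
      }
    }
    node
  }
  tree$strategies <- lapply(tree$strategies, prep_node)
  tree
}

# Expected (cost, effect) of one prepared strategy subtree given parameter
# values. Returns NULL if any resolved branch probability falls outside
# [0, 1] (used by run_psa to reject infeasible draws).
eval_strategy <- function(node, env, mult) {
  if (node$node_kind == "terminal") {
    return(c(eval(node$cost_lang, env),
             eval(node$effect_lang, env) * mult))
  }
  nb <- length(node$branches)
  probs <- numeric(nb)
  comp <- 0L
  for (i in seq_len(nb)) {
    pl <- node$branches[[i]]$prob_lang
    if (identical(pl, "complement")) comp <- i else probs[i] <- eval(pl, env)
  }
  if (comp > 0L) probs[comp] <- 1 - sum(probs[-comp])
  if (any(probs < -PROB_SUM_TOL) || any(probs > 1 + PROB_SUM_TOL)) return(NULL)
  out <- c(0, 0)
  for (i in seq_len(nb)) {
    child <- eval_strategy(node$branches[[i]]$node, env, mult)
    if (is.null(child)) return(NULL)
    out <- out + probs[i] * child
  }
  out
}

#' Roll back a decision tree to expected cost and effect per strategy
#'
#' Computes, for every strategy, the probability-weighted expectation of the
#' terminal payoffs: `E[cost] = sum p(path) cost(path)` and likewise for the
#' effect. Refuses to evaluate a model whose [validate_tree()] report is
#' non-empty.
#'
#' @param tree A [decision_tree()].
#' @param params A [parameter_set()].
#' @param settings An [analysis_settings()].
#' @return A tibble with columns `strategy`, `cost` (US$), `effect` (QALY),
#'   class `strategy_outcomes`.
#' @export
rollback <- function(tree, params, settings) {
  report <- validate_tree(tree, params)
  if (!is_valid(report)) {
    stop("model failed validation:\n",
         paste0("  - ", unclass(report), collapse = "\n"), call. = FALSE)
  }
  prep <- prepare_tree(tree)
  env <- list2env(as.list(param_values(params)))
  mult <- effect_multiplier(settings)
  out <- lapply(names(prep$strategies), function(s) {
    ce <- eval_strategy(prep$strategies[[s]], env, mult)
    tibble::tibble(strategy = s, cost = ce[1], effect = ce[2])
  })
  res <- do.call(rbind, out)
  class(res) <- c("strategy_outcomes", class(res))
  res
}

#' Enumerate all root-to-leaf paths of a decision tree
#'
#' Brute-force oracle for [rollback()]: lists every path per strategy with
#' its product-of-branch probability and terminal payoffs. Aggregating
#' `sum(probability * payoff)` per strategy reproduces the rollback
#' expectations.
#'
#' @inheritParams rollback
#' @return A tibble with columns `strategy`, `leaf`, `probability`, `cost`,
#'   `effect` (one row per path).
#' @export
enumerate_paths <- function(tree, params, settings) {
  report <- validate_tree(tree, params)
  if (!is_valid(report)) {
    stop("model failed validation:\n",
         paste0("  - ", unclass(report), collapse = "\n"), call. = FALSE)
  }
  values <- param_values(params)
  mult <- effect_multiplier(settings)
  rows <- list()
  descend <- function(node, strategy, prob) {
    if (node$node_kind == "terminal") {
      rows[[length(rows) + 1L]] <<- tibble::tibble(
        strategy = strategy, leaf = node$label, probability = prob,
        cost = eval_model_expr(node$cost, values),
        effect = eval_model_expr(node$effect, values) * mult)
      return(invisible())
    }
    probs <- resolve_branch_probs(node, values)
    for (i in seq_along(node$branches)) {
      descend(node$branches[[i]]$node, strategy, prob * probs[i])
    }
  }
  for (s in names(tree$strategies)) descend(tree$strategies[[s]], s, 1)
  do.call(rbind, rows)
}

#' Bundle a tree, parameters and settings into a model
#'
#' @param tree A [decision_tree()].
#' @param params A [parameter_set()].
#' @param settings An [analysis_settings()].
#' @return A `cua_model` object.
#' @export
cua_model <- function(tree, params, settings) {
  stopifnot(inherits(tree, "decision_tree"),
            inherits(params, "parameter_set"),
            inherits(settings, "analysis_settings"))
  structure(list(tree = tree, params = params, settings = settings),
            class = "cua_model")
}

#' @export
print.cua_model <- function(x, ...) {
  cat("<cua_model> '", x$tree$label, "': ",
      length(x$tree$strategies), " strategies, ",
      length(x$params), " parameters; WTP US$", format(x$settings$wtp),
      "/QALY\n", sep = "")
  invisible(x)
}

#' Evaluate a model at its base-case parameter values
#'
#' @param model A [cua_model()].
#' @param overrides Optional named numeric vector of parameter overrides.
#' @return `strategy_outcomes` tibble, as [rollback()].
#' @export
evaluate_model <- function(model, overrides = NULL) {
  stopifnot(inherits(model, "cua_model"))
  params <- model$params
  if (!is.null(overrides)) {
    for (nm in names(overrides)) params <- set_base(params, nm, overrides[[nm]])
  }
  rollback(model$tree, params, model$settings)
}
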