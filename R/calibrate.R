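# Calibration of terminal payoffs to arm-level targets, plus random-tree
# and perturbation generators used as fixtures by the oracle and
# property-based tests.

#' Calibrate free payoff parameters to arm-level targets
#'
#' Expected cost and effect are linear in the terminal payoff parameters,
#' so calibration is an exact linear solve: the free parameters are set so
#' that [rollback()] reproduces the per-strategy target cost and effect.
#' The system is built numerically — evaluate once with all free
#' parameters at zero (offset) and once per free parameter at one (unit
#' responses) — and solved by QR; a residual above `1e-9` (relative) or a
#' solution outside the parameters' kind bounds is an error.
#'
#' @param tree A [decision_tree()] template.
#' @param params A [parameter_set()] holding the fixed values; free
#'   parameters must exist in it (their current bases are ignored).
#' @param targets Tibble/data.frame with columns `strategy`, `cost`,
#'   `effect`, one row per strategy of `tree`.
#' @param free_costs,free_effects Names of the free cost and effect
#'   parameters (defaults are the bundled ACL model's per-arm residuals).
#' @param settings [analysis_settings()]; in `utility_at_horizon` mode
#'   target effects must lie in \[0, 1\].
#' @return A `calibration` list: `params` (the calibrated set), `solution`
#'   (tibble of parameter, value, feasible), `residual` (max absolute
#'   equation residual).
#' @export
#' @examples
#' cal <- calibrate(build_acl_tree(acl_parameters(calibrated = FALSE)),
#'                  acl_parameters(calibrated = FALSE), acl_targets())
#' cal$solution
calibrate <- function(tree, params, targets,
                      free_costs = c("c_arm_aclr", "c_arm_conserv"),
                      free_effects = c("u_stable_aclr", "u_stable_conserv"),
                      settings = acl_settings()) {
  stopifnot(inherits(tree, "decision_tree"), inherits(params, "parameter_set"),
            is.data.frame(targets),
            all(c("strategy", "cost", "effect") %in% names(targets)))
  free <- c(free_costs, free_effects)
  unknown <- setdiff(free, names(params))
  if (length(unknown) > 0L) {
    stop("unknown free parameter(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  strategies <- strategy_labels(tree)
  if (!setequal(targets$strategy, strategies)) {
    stop("targets must cover exactly the strategies: ",
         paste(strategies, collapse = ", "), call. = FALSE)
  }
  if (!all(is.finite(targets$cost)) || !all(is.finite(targets$effect))) {
    stop("targets must be finite", call. = FALSE)
  }
  if (settings$effectiveness_mode == "utility_at_horizon" &&
      any(targets$effect < 0 | targets$effect > 1)) {
    stop("target effects must lie in [0, 1] in utility_at_horizon mode",
         call. = FALSE)
  }
  targets <- targets[match(strategies, targets$strategy), ]

  zero_free <- function(ps, values) {
    for (i in seq_along(free)) ps <- set_base(ps, free[i], values[i])
    ps
  }
  eval_vec <- function(ps) {
    out <- rollback(tree, ps, settings)
    out <- out[match(strategies, out$strategy), ]
    c(out$cost, out$effect)  # length 2S: costs then effects
  }
  offset <- eval_vec(zero_free(params, rep(0, length(free))))
  A <- vapply(seq_along(free), function(j) {
    unit <- rep(0, length(free)); unit[j] <- 1
    eval_vec(zero_free(params, unit)) - offset
  }, numeric(2L * length(strategies)))
  b <- c(targets$cost, targets$effect) - offset

  qr_A <- qr(A)
  if (qr_A$rank < length(free)) {
    stop("calibration system is rank-deficient: free parameters ",
         paste(free, collapse = ", "), " are not independently identifiable",
         call. = FALSE)
  }
  x <- qr.coef(qr_A, b)
  residual <- max(abs(A %*% x - b))
  if (residual > 1e-9 * max(1, max(abs(b)))) {
    stop("calibration targets are inconsistent with the tree template ",
         "(residual ", format(residual), ")", call. = FALSE)
  }
  feasible <- logical(length(free))
  for (j in seq_along(free)) {
    bounds <- kind_bounds(params[[free[j]]]$kind)
    feasible[j] <- x[j] >= bounds[1] && x[j] <= bounds[2]
    if (!feasible[j]) {
      stop("calibration infeasible: parameter '", free[j], "' would need ",
           "value ", format(x[j]), " outside its kind bounds [",
           bounds[1], ", ", bounds[2], "]", call. = FALSE)
    }
  }
  structure(
    list(params = zero_free(params, x),
         solution = tibble::tibble(parameter = free, value = as.numeric(x),
                                   feasible = feasible),
         residual = residual),
    class = "calibration"
  )
}

#' @export
print.calibration <- function(x, ...) {
  cat("<calibration> residual", format(x$residual), "\n")
  print(x$solution, ...)
  invisible(x)
}

#' Generate a random valid decision tree and parameter set
#'
#' Fixture generator for oracle and property tests: a decision root over
#' two strategies, each a random nest of chance nodes (uniform branch
#' probabilities normalised to one; the final branch is sometimes the
#' `complement` keyword) ending in terminals with costs in \[0, 1e4\] and
#' utilities in \[0, 1\]. Some payoffs are routed through named cost
#' parameters so parameter lookup is exercised. Deterministic in `seed`.
#'
#' @param seed Integer seed.
#' @param max_depth Maximum chance-node depth below the root (>= 1).
#' @param max_branching Maximum branches per chance node (>= 2).
#' @return List with elements `tree` and `params`.
#' @export
random_tree <- function(seed, max_depth = 3, max_branching = 3) {
  stopifnot(max_depth >= 1, max_branching >= 2)
  local_seed(seed)
  param_pool <- list()
  next_id <- 0L
  new_cost_param <- function(value) {
    next_id <<- next_id + 1L
    nm <- sprintf("c_rand_%03d", next_id)
    param_pool[[nm]] <<- parameter(nm, "cost", value)
    nm
  }
  num <- function(x) format(x, digits = 17)
  gen_node <- function(depth) {
    if (depth >= max_depth || stats::runif(1) < 0.35) {
      next_id <<- next_id + 1L
      cost_val <- stats::runif(1, 0, 1e4)
      cost <- if (stats::runif(1) < 0.3) new_cost_param(cost_val) else num(cost_val)
      return(terminal_node(sprintf("leaf_%03d", next_id),
                           cost = cost,
                           effect = num(stats::runif(1))))
    }
    k <- sample(2:max_branching, 1)
    probs <- stats::runif(k)
    probs <- probs / sum(probs)
    use_comp <- stats::runif(1) < 0.5
    branches <- vector("list", k)
    for (i in seq_len(k)) {
      p_expr <- if (use_comp && i == k) "complement" else num(probs[i])
      branches[[i]] <- branch(p_expr, gen_node(depth + 1))
    }
    next_id <<- next_id + 1L
    chance_node(sprintf("chance_%03d", next_id), branches)
  }
  strategies <- list(
    structure_strategy(gen_node(0), "strategy A"),
    structure_strategy(gen_node(0), "strategy B")
  )
  params <- if (length(param_pool) > 0L) parameter_set(param_pool)
            else parameter_set(list(parameter("unused", "count", 1)))
  list(tree = decision_tree("random model", strategies), params = params)
}

#' Perturb parameter base values multiplicatively
#'
#' Each selected base value is multiplied by `1 + u` with `u` uniform on
#' `[-rel_noise, rel_noise]`, then clipped to the parameter's kind bounds
#' (probabilities and utilities to \[0, 1\], costs to non-negative);
#' declared ranges widen to keep bracketing the new base. Used to verify
#' that [calibrate()] recovers targets from any starting point.
#'
#' @param params A [parameter_set()].
#' @param rel_noise Relative noise half-width (>= 0).
#' @param seed Integer seed.
#' @param names Parameters to perturb; default all.
#' @return The perturbed parameter set.
#' @export
perturb <- function(params, rel_noise, seed, names = NULL) {
  stopifnot(inherits(params, "parameter_set"), rel_noise >= 0)
  if (is.null(names)) names <- base::names(params)
  local_seed(seed)
  u <- stats::runif(length(names), -rel_noise, rel_noise)
  for (i in seq_along(names)) {
    p <- params[[names[i]]]
    bounds <- kind_bounds(p$kind)
    value <- min(max(p$base * (1 + u[i]), bounds[1]), bounds[2])
    params <- set_base(params, names[i], value)
  }
  params
}

# Scoped RNG: set the seed for the calling function's duration and restore
# the caller's random state on exit.
local_seed <- function(seed, env = parent.frame()) {
  withr::local_seed(as.integer(seed), .local_envir = env)
}
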