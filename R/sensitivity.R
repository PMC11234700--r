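# Deterministic sensitivity analysis: one-way and two-way grids, tornado
# diagrams, and threshold solving by bisection. All code paths evaluate the
# model through the same core (evaluate_model), so outputs at base values
# are identical across them.

SA_OUTPUTS <- c("nmb_diff", "icer", "cost", "effect")

# Reference = lowest-cost strategy at base case; comparator = the other
# (two-strategy models) or an explicit label.
sa_roles <- function(model, comparator = NULL) {
  base <- evaluate_model(model)
  ref <- base$strategy[which.min(base$cost)]
  if (is.null(comparator)) {
    others <- setdiff(base$strategy, ref)
    if (length(others) != 1L) {
      stop("specify `comparator` for models with more than two strategies",
           call. = FALSE)
    }
    comparator <- others
  }
  list(reference = ref, comparator = comparator)
}

# Scalar model output as a function of parameter overrides.
# nmb_diff: NMB(comparator) - NMB(reference) at the model's WTP (positive
#   means the comparator is cost-effective); icer: delta cost / delta
#   effect; cost / effect: the comparator's expected values.
sa_output_fn <- function(model, output = SA_OUTPUTS, comparator = NULL) {
  output <- match.arg(output)
  roles <- sa_roles(model, comparator)
  wtp <- model$settings$wtp
  function(overrides) {
    out <- evaluate_model(model, overrides)
    ref <- out[out$strategy == roles$reference, ]
    cmp <- out[out$strategy == roles$comparator, ]
    switch(output,
      nmb_diff = (wtp * cmp$effect - cmp$cost) - (wtp * ref$effect - ref$cost),
      icer = (cmp$cost - ref$cost) / (cmp$effect - ref$effect),
      cost = cmp$cost,
      effect = cmp$effect
    )
  }
}

check_grid_bounds <- function(param, grid) {
  bounds <- kind_bounds(param$kind)
  if (any(grid < bounds[1]) || any(grid > bounds[2])) {
    stop("grid for parameter '", param$name, "' of kind '", param$kind,
         "' violates bounds [", bounds[1], ", ", bounds[2], "]",
         call. = FALSE)
  }
}

#' One-way sensitivity analysis
#'
#' Re-evaluates a scalar model output over a grid of values for one
#' parameter, all other parameters at base.
#'
#' @param model A [cua_model()].
#' @param name Parameter to vary.
#' @param grid Numeric grid of values (must respect the parameter's kind
#'   bounds).
#' @param output One of `"nmb_diff"` (net-monetary-benefit difference,
#'   comparator minus reference, at the model's WTP — the default),
#'   `"icer"`, `"cost"`, `"effect"`.
#' @param comparator Comparator strategy label (needed only for models with
#'   more than two strategies).
#' @return Tibble with columns `value`, `output`.
#' @export
#' @examples
#' m <- acl_model()
#' one_way(m, "u_stable_aclr", seq(0.82, 0.94, by = 0.02), output = "icer")
one_way <- function(model, name, grid, output = "nmb_diff", comparator = NULL) {
  stopifnot(inherits(model, "cua_model"), is.numeric(grid), length(grid) >= 1L)
  if (!name %in% names(model$params)) {
    stop("unknown parameter ", name, call. = FALSE)
  }
  check_grid_bounds(model$params[[name]], grid)
  f <- sa_output_fn(model, output, comparator)
  vals <- vapply(grid, function(v) f(stats::setNames(v, name)), numeric(1))
  tibble::tibble(value = grid, output = vals)
}

#' Two-way sensitivity analysis
#'
#' @inheritParams one_way
#' @param name_a,name_b Parameters to vary jointly.
#' @param grid_a,grid_b Grids for each parameter (Cartesian product).
#' @return Matrix of outputs with `grid_a` along rows and `grid_b` along
#'   columns (dimnames carry the grid values).
#' @export
two_way <- function(model, name_a, name_b, grid_a, grid_b,
                    output = "nmb_diff", comparator = NULL) {
  stopifnot(inherits(model, "cua_model"))
  for (nm in c(name_a, name_b)) {
    if (!nm %in% names(model$params)) stop("unknown parameter ", nm, call. = FALSE)
  }
  check_grid_bounds(model$params[[name_a]], grid_a)
  check_grid_bounds(model$params[[name_b]], grid_b)
  f <- sa_output_fn(model, output, comparator)
  out <- matrix(NA_real_, length(grid_a), length(grid_b),
                dimnames = list(format(grid_a), format(grid_b)))
  for (i in seq_along(grid_a)) {
    for (j in seq_along(grid_b)) {
      out[i, j] <- f(stats::setNames(c(grid_a[i], grid_b[j]),
                                     c(name_a, name_b)))
    }
  }
  out
}

#' Tornado analysis
#'
#' Evaluates the output at each parameter's low and high bound (all else at
#' base) and ranks parameters by the absolute output spread. Default ranges
#' are each parameter's declared low/high; a parameter declared without a
#' range (low = high = base) falls back to +/-20% of base clipped to its
#' kind bounds. Ties in spread are broken alphabetically by parameter name.
#'
#' @inheritParams one_way
#' @param ranges Optional named list of `c(low, high)` ranges; each must
#'   bracket the parameter's base value.
#' @param parameters Parameters to include; default, every parameter
#'   referenced by the tree's expressions.
#' @return Tibble (`tornado_result`) with columns `parameter`, `low`,
#'   `high`, `output_low`, `output_high`, `spread`, sorted by decreasing
#'   spread.
#' @export
tornado <- function(model, ranges = NULL, output = "nmb_diff",
                    parameters = NULL, comparator = NULL) {
  stopifnot(inherits(model, "cua_model"))
  if (is.null(parameters)) {
    parameters <- intersect(names(model$params), tree_param_names(model$tree))
  }
  get_range <- function(nm) {
    p <- model$params[[nm]]
    if (!is.null(ranges) && nm %in% names(ranges)) {
      r <- ranges[[nm]]
      if (!(r[1] <= p$base && p$base <= r[2])) {
        stop("range for parameter '", nm, "' does not bracket its base value ",
             p$base, call. = FALSE)
      }
      return(r)
    }
    if (p$low == p$high && p$low == p$base) {
      bounds <- kind_bounds(p$kind)
      return(c(max(0.8 * p$base, bounds[1]), min(1.2 * p$base, bounds[2])))
    }
    c(p$low, p$high)
  }
  rows <- lapply(parameters, function(nm) {
    r <- get_range(nm)
    ends <- one_way(model, nm, r, output = output, comparator = comparator)
    tibble::tibble(parameter = nm, low = r[1], high = r[2],
                   output_low = ends$output[1], output_high = ends$output[2],
                   spread = abs(ends$output[2] - ends$output[1]))
  })
  out <- do.call(rbind, rows)
  out <- out[order(-out$spread, out$parameter), ]
  class(out) <- c("tornado_result", class(out))
  out
}

# All parameter names referenced anywhere in the tree's expressions.
tree_param_names <- function(tree) {
  nms <- character(0)
  walk <- function(node) {
    if (node$node_kind == "terminal") {
      if (!is.null(node$cost)) nms <<- c(nms, expr_param_names(node$cost))
      if (!is.null(node$effect)) nms <<- c(nms, expr_param_names(node$effect))
    } else if (node$node_kind == "chance") {
      for (b in node$branches) {
        if (!identical(b$prob, "complement")) {
          nms <<- c(nms, expr_param_names(b$prob))
        }
        walk(b$node)
      }
    }
  }
  for (s in tree$strategies) walk(s)
  unique(nms)
}

# Side of a threshold on which the comparator is cost-effective, given the
# output's monotone direction: favourable when icer/cost are below target,
# nmb_diff/effect above it.
FAVOURABLE_SIGN <- c(nmb_diff = 1, icer = -1, cost = -1, effect = 1)

#' Threshold analysis by bisection
#'
#' Finds the value of one parameter at which a scalar model output equals a
#' target (for example the parameter value at which the ICER equals the
#' willingness-to-pay). The output evaluated at the bracket ends must
#' straddle the target; bisection then runs to a relative tolerance of
#' `1e-8` on `|output - target|` or 200 iterations. If the bracket shows no
#' sign change the result is returned with `converged = FALSE` and the
#' diagnostic output values at both ends.
#'
#' @inheritParams one_way
#' @param target Target output value.
#' @param bracket Length-2 numeric `c(lo, hi)` bracket for the parameter.
#' @param tol Relative convergence tolerance on the output (default 1e-8).
#' @param max_iter Iteration cap (default 200).
#' @return A `threshold_result` list: `parameter`, `threshold`, `direction`
#'   (`"above"`/`"below"`: the side of the threshold where the comparator is
#'   cost-effective), `converged`, `iterations`, `output_at_threshold`, and
#'   on failure `output_lo`/`output_hi`.
#' @export
#' @examples
#' m <- acl_model()
#' solve_threshold(m, "u_stable_aclr", target = 12876,
#'                 bracket = c(0.82, 0.95), output = "icer")
solve_threshold <- function(model, name, target, bracket, output = "icer",
                            comparator = NULL, tol = 1e-8, max_iter = 200) {
  stopifnot(inherits(model, "cua_model"), length(bracket) == 2L,
            bracket[1] < bracket[2])
  if (!name %in% names(model$params)) {
    stop("unknown parameter ", name, call. = FALSE)
  }
  output <- match.arg(output, SA_OUTPUTS)
  check_grid_bounds(model$params[[name]], bracket)
  f <- sa_output_fn(model, output, comparator)
  g <- function(x) f(stats::setNames(x, name)) - target
  lo <- bracket[1]; hi <- bracket[2]
  g_lo <- g(lo); g_hi <- g(hi)
  if (!is.finite(g_lo) || !is.finite(g_hi) || sign(g_lo) == sign(g_hi)) {
    return(structure(
      list(parameter = name, threshold = NA_real_, direction = NA_character_,
           converged = FALSE, iterations = 0L,
           output_lo = g_lo + target, output_hi = g_hi + target),
      class = "threshold_result"))
  }
  scale <- max(1, abs(target))
  iter <- 0L
  mid <- (lo + hi) / 2
  g_mid <- g(mid)
  while (abs(g_mid) > tol * scale && iter < max_iter) {
    if (sign(g_mid) == sign(g_lo)) {
      lo <- mid; g_lo <- g_mid
    } else {
      hi <- mid; g_hi <- g_mid
    }
    mid <- (lo + hi) / 2
    g_mid <- g(mid)
    iter <- iter + 1L
  }
  # slope of the output across the bracket decides which side favours the
  # comparator
  increasing <- g_hi > g_lo
  fav_high <- if (FAVOURABLE_SIGN[[output]] > 0) increasing else !increasing
  structure(
    list(parameter = name, threshold = mid,
         direction = if (fav_high) "above" else "below",
         converged = abs(g_mid) <= tol * scale, iterations = iter,
         output_at_threshold = g_mid + target),
    class = "threshold_result")
}

#' @export
print.threshold_result <- function(x, ...) {
  if (x$converged) {
    cat("<threshold_result> ", x$parameter, " = ", format(x$threshold),
        " (comparator cost-effective ", x$direction, " this value; ",
        x$iterations, " iterations)\n", sep = "")
  } else {
    cat("<threshold_result> no crossing in bracket for ", x$parameter,
        " (outputs ", format(x$output_lo), " / ", format(x$output_hi),
        ")\n", sep = "")
  }
  invisible(x)
}
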