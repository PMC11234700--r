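# Model parameters: named inputs (probabilities, utilities, costs, rates,
# counts) with a base value, a deterministic-sensitivity range and an
# optional sampling distribution for probabilistic sensitivity analysis.

PARAM_KINDS <- c("probability", "utility", "cost", "rate", "count")
DIST_FAMILIES <- c("beta", "gamma", "uniform", "fixed")

#' Distribution specification for probabilistic sensitivity analysis
#'
#' Describes how a parameter is sampled in PSA. `beta` and `gamma`
#' distributions are parameterised by mean and standard error and converted
#' to natural parameters by the method of moments; `uniform` is centred at
#' the mean with half-width `sqrt(3) * se`; `fixed` is degenerate at the
#' mean.
#'
#' @param family One of `"beta"`, `"gamma"`, `"uniform"`, `"fixed"`.
#' @param mean Distribution mean. For `beta` it must lie in (0, 1); for
#'   `gamma` it must be positive.
#' @param se Standard error (standard deviation of the sampling
#'   distribution); non-negative. Ignored for `fixed`.
#' @return A `dist_spec` list with elements `family`, `mean`, `se`.
#' @export
#' @examples
#' dist_spec("beta", mean = 0.41, se = 0.02)
dist_spec <- function(family, mean = NULL, se = NULL) {
  family <- match.arg(family, DIST_FAMILIES)
  if (family != "fixed") {
    stopifnot(is.numeric(mean), length(mean) == 1L, is.finite(mean))
    if (is.null(se)) se <- 0
    stopifnot(is.numeric(se), length(se) == 1L, is.finite(se), se >= 0)
    if (family == "beta" && (mean <= 0 || mean >= 1)) {
      stop("beta distribution requires mean in (0, 1), got ", mean, call. = FALSE)
    }
    if (family == "gamma" && mean <= 0) {
      stop("gamma distribution requires mean > 0, got ", mean, call. = FALSE)
    }
  }
  structure(list(family = family, mean = mean, se = se), class = "dist_spec")
}

#' Define a model parameter
#'
#' @param name Parameter identifier (used in payoff and probability
#'   expressions).
#' @param kind One of `"probability"`, `"utility"`, `"cost"`, `"rate"`,
#'   `"count"`. Probabilities and utilities are constrained to \[0, 1\];
#'   costs (US$), rates and counts must be non-negative.
#' @param base Base-case value.
#' @param low,high Deterministic sensitivity range; must bracket `base`.
#' @param dist Optional [dist_spec()] for PSA sampling.
#' @return A `cea_parameter` object.
#' @export
#' @examples
#' parameter("p_delayed_aclr", "probability", 0.41, low = 0.30, high = 0.55)
parameter <- function(name, kind, base, low = base, high = base, dist = NULL) {
  stopifnot(is.character(name), length(name) == 1L, nzchar(name))
  kind <- match.arg(kind, PARAM_KINDS)
  stopifnot(is.numeric(base), is.numeric(low), is.numeric(high),
            length(base) == 1L, length(low) == 1L, length(high) == 1L,
            is.finite(base), is.finite(low), is.finite(high))
  if (!(low <= base && base <= high)) {
    stop("parameter '", name, "': range [", low, ", ", high,
         "] does not bracket base ", base, call. = FALSE)
  }
  bounds <- kind_bounds(kind)
  if (low < bounds[1] || high > bounds[2]) {
    stop("parameter '", name, "' of kind '", kind, "' must lie in [",
         bounds[1], ", ", bounds[2], "]", call. = FALSE)
  }
  if (!is.null(dist) && !inherits(dist, "dist_spec")) {
    dist <- do.call(dist_spec, dist)
  }
  structure(
    list(name = name, kind = kind, base = base, low = low, high = high,
         dist = dist),
    class = "cea_parameter"
  )
}

kind_bounds <- function(kind) {
  switch(kind,
    probability = c(0, 1),
    utility = c(0, 1),
    cost = c(0, Inf),
    rate = c(0, Inf),
    count = c(0, Inf)
  )
}

#' Collect parameters into a parameter set
#'
#' @param ... `cea_parameter` objects, or a single list of them.
#' @return A `parameter_set`, a named list of parameters.
#' @export
parameter_set <- function(...) {
  ps <- list(...)
  if (length(ps) == 1L && is.list(ps[[1]]) && !inherits(ps[[1]], "cea_parameter")) {
    ps <- ps[[1]]
  }
  ok <- vapply(ps, inherits, logical(1), "cea_parameter")
  if (!all(ok)) stop("all elements must be cea_parameter objects", call. = FALSE)
  nm <- vapply(ps, `[[`, character(1), "name")
  if (anyDuplicated(nm)) {
    stop("duplicated parameter names: ",
         paste(unique(nm[duplicated(nm)]), collapse = ", "), call. = FALSE)
  }
  names(ps) <- nm
  structure(ps, class = "parameter_set")
}

#' @export
print.parameter_set <- function(x, ...) {
  cat("<parameter_set> with", length(x), "parameters\n")
  print(as.data.frame(x), ...)
  invisible(x)
}

#' @export
as.data.frame.parameter_set <- function(x, ...) {
  data.frame(
    name = vapply(x, `[[`, character(1), "name"),
    kind = vapply(x, `[[`, character(1), "kind"),
    base = vapply(x, `[[`, numeric(1), "base"),
    low = vapply(x, `[[`, numeric(1), "low"),
    high = vapply(x, `[[`, numeric(1), "high"),
    dist = vapply(x, function(p) if (is.null(p$dist)) NA_character_ else p$dist$family,
                  character(1)),
    row.names = NULL
  )
}

#' Base-case values of a parameter set
#'
#' @param params A [parameter_set()].
#' @return Named numeric vector of base values.
#' @export
param_values <- function(params) {
  stopifnot(inherits(params, "parameter_set"))
  vapply(params, `[[`, numeric(1), "base")
}

#' Override a parameter's base value
#'
#' The new value must respect the parameter's kind bounds (probabilities and
#' utilities in \[0, 1\], costs non-negative); the declared low/high range is
#' widened if needed so the object stays internally consistent.
#'
#' @param params A [parameter_set()].
#' @param name Parameter name.
#' @param value New base value.
#' @return The modified parameter set.
#' @export
set_base <- function(params, name, value) {
  stopifnot(inherits(params, "parameter_set"))
  if (!name %in% names(params)) {
    stop("unknown parameter ", name, call. = FALSE)
  }
  p <- params[[name]]
  bounds <- kind_bounds(p$kind)
  if (value < bounds[1] || value > bounds[2]) {
    stop("value ", value, " outside bounds of kind '", p$kind, "' for parameter '",
         name, "'", call. = FALSE)
  }
  p$base <- value
  p$low <- min(p$low, value)
  p$high <- max(p$high, value)
  params[[name]] <- p
  params
}

#' Fill in default PSA distributions
#'
#' Parameters without an explicit [dist_spec()] get the package's default
#' convention: beta (method of moments) for probabilities and utilities with
#' se = 5% of the mean, gamma for costs and rates with se = 10% of the mean,
#' fixed for counts and for any value at the boundary of its support. Beta
#' standard errors are clipped to half the feasibility limit
#' `sqrt(m (1 - m))`.
#'
#' @param params A [parameter_set()].
#' @return The parameter set with every parameter carrying a distribution.
#' @export
default_dists <- function(params) {
  stopifnot(inherits(params, "parameter_set"))
  for (nm in names(params)) {
    p <- params[[nm]]
    if (!is.null(p$dist)) next
    m <- p$base
    p$dist <- switch(p$kind,
      probability = ,
      utility = {
        if (m <= 0 || m >= 1) dist_spec("fixed", mean = m)
        else dist_spec("beta", mean = m,
                       se = min(0.05 * m, 0.5 * sqrt(m * (1 - m))))
      },
      cost = ,
      rate = {
        if (m <= 0) dist_spec("fixed", mean = m)
        else dist_spec("gamma", mean = m, se = 0.10 * m)
      },
      count = dist_spec("fixed", mean = m)
    )
    params[[nm]] <- p
  }
  params
}
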