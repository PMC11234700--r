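# Probabilistic sensitivity analysis: method-of-moments samplers, seeded
# Monte Carlo evaluation of the tree, cost-effectiveness acceptability
# curves and the cost-effectiveness plane with its confidence ellipse.

#' Build a parameter sampler for PSA
#'
#' Converts each parameter's [dist_spec()] into a sampling function by the
#' method of moments: beta `alpha = m (m (1 - m) / s^2 - 1)`,
#' `beta = (1 - m) (m (1 - m) / s^2 - 1)` for probabilities and utilities;
#' gamma `shape = (m / s)^2`, `scale = s^2 / m` for costs; uniform centred
#' at the mean with half-width `sqrt(3) s`; fixed parameters are degenerate
#' at their mean. A beta spec with `s^2 >= m (1 - m)` is infeasible and an
#' error. Parameters are sampled in sorted-name order so reproducibility
#' does not depend on declaration order.
#'
#' @param params A [parameter_set()] in which every parameter carries a
#'   distribution (see [default_dists()]).
#' @return A `psa_sampler`: list of per-parameter sampling functions
#'   (sorted by name), each taking a draw count `n`.
#' @export
build_sampler <- function(params) {
  stopifnot(inherits(params, "parameter_set"))
  nms <- sort(names(params))
  fns <- lapply(nms, function(nm) {
    p <- params[[nm]]
    d <- p$dist
    if (is.null(d)) {
      stop("parameter '", nm, "' has no distribution; run default_dists() ",
           "or declare one", call. = FALSE)
    }
    m <- if (d$family == "fixed") d$mean %||% p$base else d$mean
    s <- d$se
    switch(d$family,
      fixed = local({ m0 <- m %||% p$base; function(n) rep(m0, n) }),
      beta = {
        if (s == 0) return(function(n) rep(m, n))
        if (s^2 >= m * (1 - m)) {
          stop("beta distribution infeasible for parameter '", nm,
               "': se^2 = ", format(s^2), " >= mean(1-mean) = ",
               format(m * (1 - m)), call. = FALSE)
        }
        common <- m * (1 - m) / s^2 - 1
        a <- m * common; b <- (1 - m) * common
        function(n) stats::rbeta(n, a, b)
      },
      gamma = {
        if (s == 0) return(function(n) rep(m, n))
        shape <- (m / s)^2; scale <- s^2 / m
        function(n) stats::rgamma(n, shape = shape, scale = scale)
      },
      uniform = {
        h <- sqrt(3) * s
        function(n) stats::runif(n, m - h, m + h)
      }
    )
  })
  names(fns) <- nms
  structure(fns, class = "psa_sampler")
}

#' Run a probabilistic sensitivity analysis
#'
#' Samples one parameter vector per draw from a single seeded stream
#' (parameters in sorted-name order), evaluates the tree for each draw and
#' records per-strategy cost and effect. Draws whose sampled vector yields
#' an invalid tree (a resolved branch probability outside \[0, 1\]) are
#' rejected and resampled; the rejection count is kept as an attribute.
#' Identical seed, model and draw count reproduce the result bit for bit.
#'
#' @param model A [cua_model()].
#' @param sampler A `psa_sampler`; default builds one from the model's
#'   parameters (filling default distributions).
#' @param draws Number of Monte Carlo draws (default: the model settings').
#' @param seed Integer seed (default: the model settings').
#' @return A `psa_samples` tibble with columns `draw`, `strategy`, `cost`,
#'   `effect` (`draws * n_strategies` rows); attributes `seed`, `draws`,
#'   `rejections`.
#' @export
#' @examples
#' m <- acl_model()
#' s <- run_psa(m, draws = 100, seed = 1)
run_psa <- function(model, sampler = NULL, draws = model$settings$psa_draws,
                    seed = model$settings$seed) {
  stopifnot(inherits(model, "cua_model"), draws >= 1)
  if (is.null(sampler)) sampler <- build_sampler(default_dists(model$params))
  report <- validate_tree(model$tree, model$params)
  if (!is_valid(report)) {
    stop("model failed validation:\n",
         paste0("  - ", unclass(report), collapse = "\n"), call. = FALSE)
  }
  prep <- prepare_tree(model$tree)
  strategies <- names(prep$strategies)
  mult <- effect_multiplier(model$settings)
  base_values <- param_values(model$params)

  local_seed(seed)
  draw_matrix <- function(n) {
    vapply(sampler, function(fn) fn(n), numeric(n))
  }
  X <- matrix(draw_matrix(as.integer(draws)),
              nrow = draws, dimnames = list(NULL, names(sampler)))
  cost <- matrix(NA_real_, draws, length(strategies),
                 dimnames = list(NULL, strategies))
  effect <- cost
  rejections <- 0L
  eval_draw <- function(values) {
    env <- list2env(as.list(values))
    out <- matrix(NA_real_, 2L, length(strategies))
    for (j in seq_along(strategies)) {
      ce <- eval_strategy(prep$strategies[[j]], env, mult)
      if (is.null(ce)) return(NULL)
      out[, j] <- ce
    }
    out
  }
  for (i in seq_len(draws)) {
    values <- base_values
    values[colnames(X)] <- X[i, ]
    res <- eval_draw(values)
    while (is.null(res)) {
      rejections <- rejections + 1L
      if (rejections > 100L * draws) {
        stop("PSA rejection rate too high; check distribution spreads",
             call. = FALSE)
      }
      redraw <- draw_matrix(1L)
      values[names(sampler)] <- redraw
      res <- eval_draw(values)
    }
    cost[i, ] <- res[1, ]
    effect[i, ] <- res[2, ]
  }
  if (rejections > 0L) {
    message("run_psa: ", rejections, " draw(s) rejected and resampled")
  }
  out <- tibble::tibble(
    draw = rep(seq_len(draws), times = length(strategies)),
    strategy = rep(strategies, each = draws),
    cost = as.vector(cost),
    effect = as.vector(effect)
  )
  attr(out, "seed") <- as.integer(seed)
  attr(out, "draws") <- as.integer(draws)
  attr(out, "rejections") <- rejections
  class(out) <- c("psa_samples", class(out))
  out
}

psa_matrix <- function(samples, what) {
  strategies <- unique(samples$strategy)
  draws <- attr(samples, "draws") %||% max(samples$draw)
  vapply(strategies, function(s) {
    x <- samples[samples$strategy == s, ]
    x[[what]][order(x$draw)]
  }, numeric(draws))
}

#' Cost-effectiveness acceptability curves
#'
#' For each willingness-to-pay value in the grid, the probability (fraction
#' of PSA draws) that each strategy attains the highest net monetary
#' benefit. Tied draws are split equally among the tied strategies, so the
#' probabilities sum to one at every grid point by construction.
#'
#' @param samples A `psa_samples` tibble from [run_psa()].
#' @param wtp_grid Non-empty vector of non-negative WTP values.
#' @return A `ceac_curve` tibble with columns `wtp`, `strategy`,
#'   `probability`.
#' @export
ceac <- function(samples, wtp_grid) {
  stopifnot(inherits(samples, "psa_samples"),
            length(wtp_grid) >= 1L, all(wtp_grid >= 0))
  cost <- psa_matrix(samples, "cost")
  effect <- psa_matrix(samples, "effect")
  strategies <- colnames(cost)
  rows <- lapply(wtp_grid, function(l) {
    nmb <- l * effect - cost
    best <- nmb == apply(nmb, 1L, max)
    share <- best / rowSums(best)       # tie draws split equally
    tibble::tibble(wtp = l, strategy = strategies,
                   probability = colMeans(share))
  })
  out <- do.call(rbind, rows)
  class(out) <- c("ceac_curve", class(out))
  out
}

#' Cost-effectiveness plane and confidence ellipse
#'
#' Per-draw incremental (effect, cost) pairs of a comparator against a
#' reference strategy, with a confidence ellipse from the bivariate normal
#' fit: centre at the mean vector, semi-axes
#' `sqrt(qchisq(level, 2) * eigenvalues)` of the sample covariance,
#' orientation along the leading eigenvector.
#'
#' @param samples A `psa_samples` tibble.
#' @param reference,comparator Strategy labels.
#' @param level Ellipse coverage level in (0, 1), default 0.95.
#' @return List with `cloud` (tibble `delta_effect`, `delta_cost`) and
#'   `ellipse` (list: `center`, `semi_axes`, `orientation` in radians,
#'   `level`, `cov`, `degenerate`). With fewer than 3 draws the ellipse is
#'   `NULL`; a zero-variance cloud yields a degenerate point ellipse with a
#'   warning.
#' @export
ce_plane <- function(samples, reference, comparator, level = 0.95) {
  stopifnot(inherits(samples, "psa_samples"), level > 0, level < 1)
  strategies <- unique(samples$strategy)
  if (!all(c(reference, comparator) %in% strategies)) {
    stop("both strategies must be present in the samples", call. = FALSE)
  }
  cost <- psa_matrix(samples, "cost")
  effect <- psa_matrix(samples, "effect")
  cloud <- tibble::tibble(
    delta_effect = effect[, comparator] - effect[, reference],
    delta_cost = cost[, comparator] - cost[, reference]
  )
  n <- nrow(cloud)
  if (n < 3L) {
    return(list(cloud = cloud, ellipse = NULL))
  }
  mu <- c(mean(cloud$delta_effect), mean(cloud$delta_cost))
  S <- stats::cov(cbind(cloud$delta_effect, cloud$delta_cost))
  eig <- eigen(S, symmetric = TRUE)
  degenerate <- any(eig$values <= .Machine$double.eps * max(1, max(abs(eig$values))))
  if (degenerate) {
    warning("zero-variance cloud: ellipse degenerates to a point")
  }
  semi <- sqrt(pmax(eig$values, 0) * stats::qchisq(level, df = 2))
  ellipse <- list(
    center = stats::setNames(mu, c("delta_effect", "delta_cost")),
    semi_axes = semi,
    orientation = atan2(eig$vectors[2, 1], eig$vectors[1, 1]),
    level = level, cov = S, degenerate = degenerate
  )
  list(cloud = cloud, ellipse = ellipse)
}

#' Points of a confidence ellipse outline
#'
#' @param ellipse The `ellipse` element of a [ce_plane()] result.
#' @param n Number of outline points.
#' @return Tibble with columns `delta_effect`, `delta_cost`.
#' @export
ellipse_points <- function(ellipse, n = 200L) {
  theta <- seq(0, 2 * pi, length.out = n)
  unit <- rbind(ellipse$semi_axes[1] * cos(theta),
                ellipse$semi_axes[2] * sin(theta))
  phi <- ellipse$orientation
  R <- matrix(c(cos(phi), sin(phi), -sin(phi), cos(phi)), 2, 2)
  pts <- R %*% unit
  tibble::tibble(delta_effect = pts[1, ] + ellipse$center[1],
                 delta_cost = pts[2, ] + ellipse$center[2])
}

#' Does an ellipse contain given points?
#'
#' Membership is computed from the ellipse's own geometry (centre,
#' semi-axes, orientation), not from the covariance matrix it was fitted
#' from.
#'
#' @param ellipse The `ellipse` element of a [ce_plane()] result.
#' @param points Two-column matrix or data frame of (delta_effect,
#'   delta_cost) points.
#' @return Logical vector.
#' @export
ellipse_contains <- function(ellipse, points) {
  pts <- as.matrix(points)
  stopifnot(ncol(pts) == 2L)
  phi <- ellipse$orientation
  R <- matrix(c(cos(phi), -sin(phi), sin(phi), cos(phi)), 2, 2)
  centred <- sweep(pts, 2L, ellipse$center)
  z <- centred %*% t(R)
  a <- pmax(ellipse$semi_axes, .Machine$double.eps)
  (z[, 1] / a[1])^2 + (z[, 2] / a[2])^2 <= 1
}
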