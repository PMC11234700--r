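test_that("method-of-moments samplers recover their mean and se", {
  params <- parameter_set(
    parameter("p", "probability", 0.41,
              dist = dist_spec("beta", mean = 0.41, se = 0.05)),
    parameter("c", "cost", 2853,
              dist = dist_spec("gamma", mean = 2853, se = 570)),
    parameter("f", "count", 7, dist = dist_spec("fixed", mean = 7)))
  sampler <- build_sampler(params)
  withr::local_seed(123)
  n <- 1e5
  p_draws <- sampler$p(n)
  expect_lt(abs(mean(p_draws) - 0.41), 3 * 0.05 / sqrt(n))
  expect_equal(stats::sd(p_draws), 0.05, tolerance = 0.02)
  c_draws <- sampler$c(n)
  expect_equal(mean(c_draws), 2853, tolerance = 0.01)
  expect_equal(stats::var(c_draws), 570^2, tolerance = 0.03)
  expect_identical(unique(sampler$f(10)), 7)
})

test_that("zero se collapses beta and gamma to their mean", {
  params <- parameter_set(
    parameter("p", "probability", 0.3, dist = dist_spec("beta", 0.3, 0)),
    parameter("c", "cost", 100, dist = dist_spec("gamma", 100, 0)))
  sampler <- build_sampler(params)
  expect_identical(unique(sampler$p(5)), 0.3)
  expect_identical(unique(sampler$c(5)), 100)
})

test_that("infeasible beta moments name the offending parameter", {
  params <- parameter_set(
    parameter("p_wild", "probability", 0.5,
              dist = dist_spec("beta", mean = 0.5, se = 0.6)))
  expect_error(build_sampler(params), "p_wild")
})

test_that("all-fixed distributions reproduce the base case on every draw", {
  params <- tiny_params()
  for (nm in names(params)) {
    params[[nm]]$dist <- dist_spec("fixed", mean = params[[nm]]$base)
  }
  m <- cua_model(tiny_tree(), params, tiny_settings())
  s <- run_psa(m, draws = 20, seed = 5)
  expect_identical(unique(s$cost), 41)
  expect_identical(unique(s$effect), 0.682)
})

test_that("the same seed reproduces a PSA bit for bit", {
  m <- acl_model()
  s1 <- run_psa(m, draws = 200, seed = 77)
  s2 <- run_psa(m, draws = 200, seed = 77)
  expect_identical(s1$cost, s2$cost)
  expect_identical(s1$effect, s2$effect)
  s3 <- run_psa(m, draws = 200, seed = 78)
  expect_false(identical(s1$cost, s3$cost))
})

test_that("the PSA cloud mean stays near the base case (law of large numbers)", {
  m <- acl_model()
  s <- run_psa(m, draws = 2000, seed = 11)
  cost <- ceatree:::psa_matrix(s, "cost")
  effect <- ceatree:::psa_matrix(s, "effect")
  # mean-centred distributions: cloud means within a few MC standard errors
  expect_equal(mean(cost[, "Early ACLR"]), 4266, tolerance = 0.02)
  expect_equal(mean(cost[, "Conservative treatment"]), 3290, tolerance = 0.02)
  expect_equal(mean(effect[, "Early ACLR"]), 0.86, tolerance = 0.01)
  expect_equal(mean(effect[, "Conservative treatment"]), 0.81, tolerance = 0.01)
})

test_that("ceac probabilities sum to one and behave at the WTP extremes", {
  m <- acl_model()
  s <- run_psa(m, draws = 1000, seed = 3)
  grid <- c(0, 5000, 12876, 20000, 1e6)
  curve <- ceac(s, grid)
  sums <- tapply(curve$probability, curve$wtp, sum)
  expect_equal(as.numeric(sums), rep(1, length(grid)))
  early <- curve[curve$strategy == "Early ACLR", ]
  # lambda = 0 reduces NMB to -cost: mass goes to the cheaper strategy
  expect_lt(early$probability[early$wtp == 0], 0.1)
  # very large lambda: the higher-effect strategy dominates
  expect_gt(early$probability[early$wtp == 1e6], 0.5)
})

test_that("ceac splits tied draws equally", {
  params <- parameter_set(parameter("u", "utility", 0.5,
                                    dist = dist_spec("fixed", 0.5)))
  tr <- decision_tree("ties", list(
    chance_node("A", list(branch("1", terminal_node("a", "100", "u")))),
    chance_node("B", list(branch("1", terminal_node("b", "100", "u"))))
  ))
  m <- cua_model(tr, params, analysis_settings(wtp = 1000))
  s <- run_psa(m, draws = 10, seed = 1)
  curve <- ceac(s, c(0, 1000))
  expect_identical(unique(curve$probability), 0.5)
})

test_that("the comparator's ceac is nondecreasing when it always gains effect", {
  m <- acl_model()
  params <- m$params
  # collapse utility uncertainty so every draw has delta effect > 0
  params[["u_stable_aclr"]]$dist <- dist_spec("fixed", 0.86)
  params[["u_stable_conserv"]]$dist <- dist_spec("fixed", 0.81)
  m$params <- params
  s <- run_psa(m, draws = 500, seed = 9)
  curve <- ceac(s, seq(0, 60000, by = 2500))
  early <- curve$probability[curve$strategy == "Early ACLR"]
  expect_true(all(diff(early) >= 0))
})

test_that("ce_plane fits the generating covariance's geometry", {
  withr::local_seed(31)
  n <- 5000
  # cov [[4, 0], [0, 1]]: axis ratio 2:1, oriented along x
  de <- rnorm(n, sd = 2); dc <- rnorm(n, sd = 1)
  samples <- tibble::tibble(
    draw = rep(seq_len(n), 2),
    strategy = rep(c("ref", "cmp"), each = n),
    cost = c(rep(0, n), dc),
    effect = c(rep(0, n), de))
  attr(samples, "draws") <- n
  class(samples) <- c("psa_samples", class(samples))
  plane <- ce_plane(samples, "ref", "cmp", level = 0.95)
  ell <- plane$ellipse
  expect_equal(ell$semi_axes[1] / ell$semi_axes[2], 2, tolerance = 0.1)
  expect_lt(abs(sin(ell$orientation)), 0.1)
  expect_equal(unname(ell$center), c(0, 0), tolerance = 0.1)
  # isotropic unit-variance cloud: both semi-axes near sqrt(5.991)
  de2 <- rnorm(n); dc2 <- rnorm(n)
  samples$cost <- c(rep(0, n), dc2); samples$effect <- c(rep(0, n), de2)
  ell2 <- ce_plane(samples, "ref", "cmp", level = 0.95)$ellipse
  expect_equal(unname(ell2$semi_axes), rep(sqrt(qchisq(0.95, 2)), 2),
               tolerance = 0.05)
})

test_that("degenerate clouds yield a point ellipse or none at all", {
  samples <- tibble::tibble(
    draw = rep(1:5, 2), strategy = rep(c("ref", "cmp"), each = 5),
    cost = rep(c(0, 10), each = 5), effect = rep(c(0.5, 0.6), each = 5))
  attr(samples, "draws") <- 5L
  class(samples) <- c("psa_samples", class(samples))
  expect_warning(plane <- ce_plane(samples, "ref", "cmp"), "degenerates")
  expect_true(plane$ellipse$degenerate)
  few <- samples[samples$draw <= 2, ]
  attr(few, "draws") <- 2L
  class(few) <- c("psa_samples", class(few))
  expect_null(ce_plane(few, "ref", "cmp")$ellipse)
})
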