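test_that("a one-point grid at base reproduces the base-case output", {
  m <- acl_model()
  base <- one_way(m, "u_stable_aclr", 0.86, output = "icer")
  expect_equal(base$output, 976 / 0.05)
  base_nmb <- one_way(m, "u_stable_aclr", 0.86, output = "nmb_diff")
  expect_equal(base_nmb$output, 6807.36 - 7139.56)
})

test_that("ICER decreases monotonically as post-ACLR utility rises", {
  m <- acl_model()
  res <- one_way(m, "u_stable_aclr", seq(0.82, 0.95, by = 0.01),
                 output = "icer")
  expect_true(all(diff(res$output) < 0))
  # utility 0.89 brings the ICER below the WHO-CHOICE threshold
  at_089 <- one_way(m, "u_stable_aclr", 0.89, output = "icer")$output
  expect_lt(at_089, 12876)
})

test_that("a parameter appearing in no expression leaves the output constant", {
  m <- acl_model()
  res <- one_way(m, "u_baseline", c(0.55, 0.61, 0.67), output = "nmb_diff")
  expect_identical(length(unique(res$output)), 1L)
})

test_that("one_way rejects unknown parameters and kind-violating grids", {
  m <- acl_model()
  expect_error(one_way(m, "nope", 0.5), "unknown parameter")
  expect_error(one_way(m, "u_stable_aclr", c(0.5, 1.2)), "violates bounds")
})

test_that("a two_way slice at base equals the one_way result", {
  m <- acl_model()
  g_a <- seq(0.30, 0.55, by = 0.05)
  mat <- two_way(m, "p_delayed_aclr", "u_stable_aclr", g_a, c(0.84, 0.86, 0.88))
  expect_identical(dim(mat), c(length(g_a), 3L))
  slice <- one_way(m, "p_delayed_aclr", g_a)
  expect_equal(unname(mat[, 2]), slice$output)
  # single cell at base values is the base case
  cell <- two_way(m, "p_delayed_aclr", "u_stable_aclr", 0.41, 0.86)
  expect_equal(unname(cell[1, 1]), 6807.36 - 7139.56)
  # nmb_diff rises with the crossover probability (conservative arm gets
  # costlier) and with post-ACLR utility, so the matrix is monotone in both
  expect_true(all(apply(mat, 2, function(col) all(diff(col) > 0))))
  expect_true(all(apply(mat, 1, function(row) all(diff(row) > 0))))
})

test_that("tornado endpoints equal the one_way evaluations and sort by spread", {
  m <- acl_model()
  res <- tornado(m)
  expect_true(all(diff(res$spread) <= 0))
  for (i in c(1L, nrow(res))) {
    ends <- one_way(m, res$parameter[i], c(res$low[i], res$high[i]))
    expect_identical(res$output_low[i], ends$output[1])
    expect_identical(res$output_high[i], ends$output[2])
  }
  # zero-width range: zero spread, ranked last (alphabetical among ties)
  res2 <- tornado(m, ranges = list(u_stable_aclr = c(0.86, 0.86)))
  expect_identical(res2$spread[res2$parameter == "u_stable_aclr"], 0)
  expect_gte(which(res2$parameter == "u_stable_aclr"), nrow(res2) - 1L)
})

test_that("cost and crossover parameters dominate the tornado over utilities", {
  res <- tornado(acl_model(), output = "nmb_diff")
  rank_of <- function(p) which(res$parameter == p)
  drivers <- c("c_arm_aclr", "c_arm_conserv", "p_delayed_aclr")
  utilities <- c("u_stable_aclr", "u_stable_conserv")
  expect_true(max(vapply(drivers, rank_of, integer(1))) <
              min(vapply(utilities, rank_of, integer(1))))
})

test_that("tornado rejects ranges that do not bracket the base", {
  expect_error(tornado(acl_model(), ranges = list(u_stable_aclr = c(0.9, 0.95))),
               "does not bracket")
})

test_that("bisection solves a synthetic linear threshold to closed form", {
  # one chance-free strategy pair: delta cost = a + b * theta, fixed delta
  # effect, so theta* = (target * de - a) / b
  ps <- parameter_set(
    parameter("theta", "cost", 500, 0, 5000),
    parameter("a", "cost", 200), parameter("b", "count", 2))
  tr <- decision_tree("linear", list(
    chance_node("ref", list(branch("1", terminal_node("r", "1000", "0.5")))),
    chance_node("cmp", list(branch("1", terminal_node("c", "1000 + a + b * theta", "0.6"))))
  ))
  m <- cua_model(tr, ps, analysis_settings(wtp = 10000))
  target <- 9000
  analytic <- (target * 0.1 - 200) / 2
  res <- solve_threshold(m, "theta", target = target, bracket = c(0, 3000),
                         output = "icer")
  expect_true(res$converged)
  expect_equal(res$threshold, analytic, tolerance = 1e-6)
  expect_identical(res$direction, "below")  # cheaper comparator is favourable
})

test_that("a bracket without a crossing reports non-convergence with diagnostics", {
  m <- acl_model()
  res <- solve_threshold(m, "u_stable_aclr", target = 12876,
                         bracket = c(0.90, 0.95), output = "icer")
  expect_false(res$converged)
  expect_true(is.na(res$threshold))
  expect_true(is.finite(res$output_lo) && is.finite(res$output_hi))
})

test_that("bisection agrees with a dense grid scan on a monotone output", {
  m <- acl_model()
  res <- solve_threshold(m, "u_stable_aclr", target = 12876,
                         bracket = c(0.82, 0.95), output = "icer")
  grid <- seq(0.82, 0.95, length.out = 10001)
  ow <- one_way(m, "u_stable_aclr", grid, output = "icer")
  cross <- grid[which.min(abs(ow$output - 12876))]
  expect_lt(abs(res$threshold - cross), diff(grid[1:2]))
  expect_identical(res$direction, "above")
})
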