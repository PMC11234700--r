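test_that("rollback computes the hand-checked expectation", {
  out <- rollback(tiny_tree(), tiny_params(), tiny_settings())
  # 0.41 * (100, 0.8) + 0.59 * (0, 0.6)
  expect_equal(out$cost, 41)
  expect_equal(out$effect, 0.682)
})

test_that("rollback refuses a model that fails validation", {
  ps <- parameter_set(parameter("x", "count", 1))
  tr <- decision_tree("bad", list(
    chance_node("arm", list(
      branch("0.7", terminal_node("a", "1", "0.5")),
      branch("0.7", terminal_node("b", "2", "0.5"))))))
  expect_error(rollback(tr, ps, tiny_settings()), "failed validation")
  expect_error(enumerate_paths(tr, ps, tiny_settings()), "failed validation")
})

test_that("all probability mass on one branch returns that branch's payoffs", {
  ps <- set_base(tiny_params(), "p_hit", 1)
  out <- rollback(tiny_tree(), ps, tiny_settings())
  expect_equal(out$cost, 100)
  expect_equal(out$effect, 0.8)
})

test_that("discount_factor matches its closed form", {
  expect_identical(discount_factor(0, 0.03), 1)
  expect_equal(discount_factor(1, 0.03), 1 / 1.03)
  # closed form vs log-space evaluation at a fractional horizon
  expect_equal(discount_factor(1.5, 0.03), exp(-1.5 * log(1.03)))
  expect_error(discount_factor(-1, 0.03))
})

test_that("time-integrated effects equal utility x horizon-years when undiscounted", {
  s0 <- tiny_settings(discount_rate = 0, horizon_months = 18,
                      effectiveness_mode = "time_integrated")
  out <- rollback(tiny_tree(), tiny_params(), s0)
  expect_identical(out$effect, 0.682 * 1.5)
  # with discounting the accrual must shrink, but stay below the undiscounted value
  s3 <- tiny_settings(discount_rate = 0.03, horizon_months = 18,
                      effectiveness_mode = "time_integrated")
  out3 <- rollback(tiny_tree(), tiny_params(), s3)
  expect_lt(out3$effect, out$effect)
  expect_gt(out3$effect, out$effect * discount_factor(1.5, 0.03))
})

test_that("path enumeration aggregates to the rollback expectation", {
  paths <- enumerate_paths(tiny_tree(), tiny_params(), tiny_settings())
  expect_identical(nrow(paths), 2L)
  expect_equal(sum(paths$probability), 1)
  agg <- aggregate_paths(paths)
  out <- rollback(tiny_tree(), tiny_params(), tiny_settings())
  expect_equal(agg$cost, out$cost)
  expect_equal(agg$effect, out$effect)
})

test_that("scaling terminal costs scales expected costs linearly", {
  for (seed in c(11, 12, 13)) {
    rt <- random_tree(seed, max_depth = 4, max_branching = 4)
    out1 <- rollback(rt$tree, rt$params, tiny_settings())
    k <- 3.7
    scale_node <- function(node) {
      if (node$node_kind == "terminal") {
        node$cost <- sprintf("(%s) * %s", node$cost, format(k, digits = 17))
      } else {
        node$branches <- lapply(node$branches, function(b) {
          b$node <- scale_node(b$node); b
        })
      }
      node
    }
    tr2 <- rt$tree
    tr2$strategies <- lapply(tr2$strategies, scale_node)
    out2 <- rollback(tr2, rt$params, tiny_settings())
    expect_equal(out2$cost, k * out1$cost, tolerance = 1e-12)
    expect_equal(out2$effect, out1$effect)
  }
})

test_that("expected outcomes are invariant to branch order within a chance node", {
  local_reversed <- function(node) {
    if (node$node_kind == "chance") {
      # make the complement explicit before reversing so semantics survive
      vals <- param_values(tiny_params())
      probs <- ceatree:::resolve_branch_probs(node, vals)
      for (i in seq_along(node$branches)) {
        if (identical(node$branches[[i]]$prob, "complement")) {
          node$branches[[i]]$prob <- format(probs[i], digits = 17)
        }
      }
      node$branches <- rev(lapply(node$branches, function(b) {
        b$node <- local_reversed(b$node)
        b
      }))
    }
    node
  }
  tr <- tiny_tree()
  tr$strategies <- lapply(tr$strategies, local_reversed)
  out <- rollback(tr, tiny_params(), tiny_settings())
  ref <- rollback(tiny_tree(), tiny_params(), tiny_settings())
  expect_equal(out$cost, ref$cost)
  expect_equal(out$effect, ref$effect)
})

test_that("strategy outcomes lie within the convex hull of terminal payoffs", {
  for (seed in 21:25) {
    rt <- random_tree(seed, max_depth = 4, max_branching = 3)
    paths <- enumerate_paths(rt$tree, rt$params, tiny_settings())
    out <- rollback(rt$tree, rt$params, tiny_settings())
    for (s in out$strategy) {
      leaf <- paths[paths$strategy == s, ]
      row <- out[out$strategy == s, ]
      expect_gte(row$cost, min(leaf$cost) - 1e-9)
      expect_lte(row$cost, max(leaf$cost) + 1e-9)
      expect_gte(row$effect, min(leaf$effect) - 1e-12)
      expect_lte(row$effect, max(leaf$effect) + 1e-12)
    }
  }
})
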