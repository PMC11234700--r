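# Shared fixtures: a minimal one-chance-node model whose expectation is
# hand-checkable, plus a path-table aggregator used against rollback().

tiny_params <- function() {
  parameter_set(
    parameter("p_hit", "probability", 0.41, 0.2, 0.6),
    parameter("c_hit", "cost", 100, 50, 150),
    parameter("u_hit", "utility", 0.8, 0.7, 0.9),
    parameter("u_miss", "utility", 0.6, 0.5, 0.7)
  )
}

tiny_tree <- function() {
  arm <- chance_node("only strategy", list(
    branch("p_hit", terminal_node("hit", cost = "c_hit", effect = "u_hit")),
    branch("complement", terminal_node("miss", cost = "0", effect = "u_miss"))
  ))
  decision_tree("tiny", list(arm))
}

tiny_settings <- function(...) analysis_settings(wtp = 1000, ...)

aggregate_paths <- function(paths) {
  out <- lapply(split(paths, paths$strategy), function(d) {
    tibble::tibble(strategy = d$strategy[1],
                   cost = sum(d$probability * d$cost),
                   effect = sum(d$probability * d$effect))
  })
  res <- do.call(rbind, out)
  res[order(res$strategy), ]
}
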