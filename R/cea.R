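# Incremental cost-effectiveness statistics: ICER with dominance flags,
# net monetary benefit, the incremental table and the WTP decision rule.

#' Incremental cost-effectiveness ratio between two strategies
#'
#' `ICER = (cost_comparator - cost_reference) / (effect_comparator -
#' effect_reference)`. When the comparator is cheaper and at least as
#' effective it *dominates* the reference (no ratio is meaningful); when it
#' is more expensive and less effective it is *dominated*; equal effects
#' yield the `equal-effect` flag.
#'
#' @param reference,comparator Rows of a `strategy_outcomes` tibble (or any
#'   list with numeric `cost` and `effect`).
#' @return A list with `icer` (US$/QALY, `NA` unless `status == "icer"`),
#'   `status` (one of `"icer"`, `"dominant"`, `"dominated"`,
#'   `"equal-effect"`), `delta_cost`, `delta_effect`.
#' @export
#' @examples
#' icer(list(cost = 3290, effect = 0.81), list(cost = 4266, effect = 0.86))
icer <- function(reference, comparator) {
  dc <- comparator$cost - reference$cost
  de <- comparator$effect - reference$effect
  if (!is.finite(dc) || !is.finite(de)) {
    stop("non-finite strategy outcomes", call. = FALSE)
  }
  status <-
    if (de == 0) "equal-effect"
    else if (dc <= 0 && de > 0) "dominant"
    else if (dc >= 0 && de < 0) "dominated"
    else "icer"
  list(icer = if (status == "icer") dc / de else NA_real_,
       status = status, delta_cost = dc, delta_effect = de)
}

#' Net monetary benefit
#'
#' `NMB = wtp * effect - cost`: the monetised value of a strategy at
#' willingness-to-pay `wtp` (US$/QALY). Maximising NMB is equivalent to the
#' ICER-versus-WTP rule for two strategies with a positive effect gain.
#'
#' @param outcome A row of `strategy_outcomes` (list with `cost`, `effect`).
#' @param wtp Willingness-to-pay, US$/QALY, non-negative.
#' @return NMB in US$.
#' @export
#' @examples
#' nmb(list(cost = 3290, effect = 0.81), wtp = 12876)
nmb <- function(outcome, wtp) {
  stopifnot(is.numeric(wtp), wtp >= 0)
  wtp * outcome$effect - outcome$cost
}

#' Incremental cost-effectiveness table
#'
#' Strategies are sorted by cost; the cheapest is the reference with empty
#' incremental fields. Each subsequent strategy is compared with the last
#' non-dominated strategy below it (a pairwise sorted-by-cost sweep — with
#' more than two strategies this is an experimental efficiency-frontier
#' sweep, the two-strategy case matches the usual incremental analysis).
#'
#' @param outcomes A `strategy_outcomes` tibble from [rollback()].
#' @param wtp Willingness-to-pay, US$/QALY.
#' @return A tibble (`cea_table`) with columns `strategy`, `cost`, `effect`,
#'   `incr_cost`, `incr_effect`, `icer`, `status`, `nmb`; attribute `wtp`.
#' @export
cea_table <- function(outcomes, wtp) {
  stopifnot(is.data.frame(outcomes), all(c("strategy", "cost", "effect") %in%
                                         names(outcomes)))
  ord <- order(outcomes$cost, outcomes$effect)
  out <- outcomes[ord, c("strategy", "cost", "effect")]
  n <- nrow(out)
  out$incr_cost <- NA_real_
  out$incr_effect <- NA_real_
  out$icer <- NA_real_
  out$status <- c("reference", rep(NA_character_, n - 1L))
  out$nmb <- wtp * out$effect - out$cost
  comp_base <- 1L
  if (n > 1L) {
    for (i in 2:n) {
      cmp <- icer(out[comp_base, ], out[i, ])
      out$incr_cost[i] <- cmp$delta_cost
      out$incr_effect[i] <- cmp$delta_effect
      out$icer[i] <- cmp$icer
      out$status[i] <- cmp$status
      if (cmp$status != "dominated") comp_base <- i
    }
  }
  out <- tibble::as_tibble(out)
  attr(out, "wtp") <- wtp
  class(out) <- c("cea_table", class(out))
  out
}

#' Preferred strategy at a willingness-to-pay threshold
#'
#' Returns the strategy with maximal net monetary benefit. For two
#' strategies with a positive effect difference this coincides with the
#' rule "adopt the comparator iff its ICER is below the WTP". Exact NMB
#' ties return the cheaper strategy with `tie = TRUE`.
#'
#' @param table A [cea_table()].
#' @param wtp Willingness-to-pay; defaults to the table's own WTP (the
#'   table's `nmb` column is recomputed if a different value is given).
#' @return List with `strategy` (label) and `tie` (logical).
#' @export
decide <- function(table, wtp = attr(table, "wtp")) {
  stopifnot(inherits(table, "cea_table"), is.numeric(wtp), wtp >= 0)
  nmbs <- wtp * table$effect - table$cost
  best <- max(nmbs)
  at_best <- which(nmbs == best)
  if (length(at_best) > 1L) {
    cheapest <- at_best[which.min(table$cost[at_best])]
    list(strategy = table$strategy[cheapest], tie = TRUE)
  } else {
    list(strategy = table$strategy[at_best], tie = FALSE)
  }
}

#' @export
print.cea_table <- function(x, ...) {
  cat("<cea_table> at WTP US$", format(attr(x, "wtp")), "/QALY\n", sep = "")
  y <- x
  y$cost <- round(y$cost)
  y$incr_cost <- round(y$incr_cost)
  y$nmb <- round(y$nmb)
  y$effect <- round(y$effect, 2)
  y$incr_effect <- round(y$incr_effect, 2)
  y$icer <- round(y$icer)
  class(y) <- setdiff(class(y), "cea_table")
  print(y, ...)
  invisible(x)
}
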