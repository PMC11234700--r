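# Decision-tree structure: one decision root whose children are the
# treatment strategies, chance nodes with probability expressions, and
# terminal nodes carrying cost and effect (utility) payoff expressions.

PROB_SUM_TOL <- 1e-9

#' Terminal (leaf) node of a decision tree
#'
#' @param label Node label.
#' @param cost,effect Payoff expressions (strings over parameter names,
#'   literals, `+ - * /` and parentheses). Cost in US$, effect as a utility
#'   weight. Either may be `NULL` while a model is under construction;
#'   [validate_tree()] reports missing payoffs.
#' @return A `tree_node` of kind terminal.
#' @export
#' @examples
#' terminal_node("stable knee", cost = "c_arm_conserv", effect = "u_stable_conserv")
terminal_node <- function(label, cost = NULL, effect = NULL) {
  stopifnot(is.character(label), length(label) == 1L, nzchar(label))
  structure(
    list(label = label, node_kind = "terminal", cost = cost, effect = effect),
    class = c("tn_terminal", "tree_node")
  )
}

#' Chance-node branch
#'
#' @param prob Probability expression, or the keyword `"complement"`
#'   (at most one per chance node), resolved as one minus the sum of the
#'   sibling branch probabilities.
#' @param node Child [tree_node].
#' @return A branch (probability, node) pair.
#' @export
branch <- function(prob, node) {
  stopifnot(is.character(prob), length(prob) == 1L, nzchar(prob))
  stopifnot(inherits(node, "tree_node"))
  list(prob = prob, node = node)
}

#' Chance node of a decision tree
#'
#' @param label Node label.
#' @param branches List of [branch()]es. Resolved branch probabilities must
#'   lie in \[0, 1\] and sum to one (tolerance `1e-9`); violations are
#'   reported by [validate_tree()], not at construction.
#' @return A `tree_node` of kind chance.
#' @export
chance_node <- function(label, branches) {
  stopifnot(is.character(label), length(label) == 1L, nzchar(label))
  stopifnot(is.list(branches), length(branches) >= 1L)
  structure(
    list(label = label, node_kind = "chance", branches = branches),
    class = c("tn_chance", "tree_node")
  )
}

#' Decision root of a tree
#'
#' The single decision node sits at the root; its children are the
#' strategies under comparison (decision branches carry no probability).
#'
#' @param label Root label.
#' @param strategies List of `tree_node`s, one per strategy; strategy labels
#'   are the child node labels and must be unique.
#' @return A `decision_tree` object.
#' @export
decision_tree <- function(label, strategies) {
  stopifnot(is.character(label), length(label) == 1L)
  stopifnot(is.list(strategies), length(strategies) >= 1L)
  ok <- vapply(strategies, inherits, logical(1), "tree_node")
  if (!all(ok)) stop("strategies must be tree_node objects", call. = FALSE)
  labs <- vapply(strategies, `[[`, character(1), "label")
  if (anyDuplicated(labs)) stop("strategy labels must be unique", call. = FALSE)
  names(strategies) <- labs
  structure(
    list(label = label, node_kind = "decision", strategies = strategies),
    class = c("decision_tree", "tree_node")
  )
}

#' Strategy labels of a decision tree
#' @param tree A [decision_tree()].
#' @return Character vector of strategy labels.
#' @export
strategy_labels <- function(tree) {
  stopifnot(inherits(tree, "decision_tree"))
  names(tree$strategies)
}

#' @export
print.decision_tree <- function(x, ...) {
  cat("<decision_tree> '", x$label, "'\n", sep = "")
  for (s in names(x$strategies)) {
    cat("strategy:", s, "\n")
    print_node(x$strategies[[s]], indent = 2L)
  }
  invisible(x)
}

print_node <- function(node, indent = 0L, prob = NULL) {
  pad <- strrep(" ", indent)
  if (node$node_kind == "terminal") {
    cat(pad,
        if (!is.null(prob)) paste0("[", prob, "] ") else "",
        node$label, "  (cost: ", node$cost %||% "<missing>",
        ", effect: ", node$effect %||% "<missing>", ")\n", sep = "")
  } else {
    cat(pad, if (!is.null(prob)) paste0("[", prob, "] ") else "",
        node$label, "\n", sep = "")
    for (b in node$branches) print_node(b$node, indent + 2L, b$prob)
  }
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Resolve the branch probabilities of a chance node against parameter
# values. Returns the numeric probabilities (complement filled in) without
# range checks; callers validate.
resolve_branch_probs <- function(node, values) {
  probs <- rep(NA_real_, length(node$branches))
  comp <- which(vapply(node$branches, function(b) identical(b$prob, "complement"),
                       logical(1)))
  for (i in seq_along(node$branches)) {
    if (i %in% comp) next
    probs[i] <- eval_model_expr(node$branches[[i]]$prob, values)
  }
  if (length(comp) == 1L) probs[comp] <- 1 - sum(probs[-comp])
  probs
}

#' Validate a decision tree against a parameter set
#'
#' Collects every structural violation rather than stopping at the first:
#' unknown parameter names, branch probabilities outside \[0, 1\] or not
#' summing to one (tolerance `1e-9`), more than one complement branch per
#' chance node, missing terminal payoffs, and nested decision nodes. An
#' empty report means the model is evaluable by [rollback()].
#'
#' @param tree A [decision_tree()].
#' @param params A [parameter_set()].
#' @return A `validation_report`: character vector of violation messages
#'   (zero length when valid); query with [is_valid()].
#' @export
#' @examples
#' ps <- parameter_set(parameter("p", "probability", 0.41))
#' tr <- decision_tree("demo", list(
#'   chance_node("arm", list(
#'     branch("p", terminal_node("a", "100", "0.8")),
#'     branch("complement", terminal_node("b", "0", "0.6"))))))
#' is_valid(validate_tree(tr, ps))
validate_tree <- function(tree, params) {
  stopifnot(inherits(tree, "decision_tree"), inherits(params, "parameter_set"))
  values <- param_values(params)
  problems <- character(0)
  note <- function(...) problems <<- c(problems, paste0(...))

  check_expr_names <- function(text, where) {
    nms <- tryCatch(expr_param_names(text), error = function(e) {
      note(where, ": ", conditionMessage(e))
      character(0)
    })
    unknown <- setdiff(nms, names(values))
    for (u in unknown) note(where, ": unknown parameter ", u)
    length(unknown) == 0L
  }

  walk <- function(node) {
    if (node$node_kind == "decision") {
      note("nested decision node '", node$label,
           "': only the root may be a decision node")
      return(invisible())
    }
    if (node$node_kind == "terminal") {
      if (is.null(node$cost)) {
        note("terminal node '", node$label, "': missing cost payoff")
      } else {
        check_expr_names(node$cost, paste0("terminal node '", node$label, "' cost"))
      }
      if (is.null(node$effect)) {
        note("terminal node '", node$label, "': missing effect payoff")
      } else {
        check_expr_names(node$effect, paste0("terminal node '", node$label, "' effect"))
      }
      return(invisible())
    }
    # chance node
    comp <- vapply(node$branches, function(b) identical(b$prob, "complement"),
                   logical(1))
    if (sum(comp) > 1L) {
      note("chance node '", node$label, "': more than one complement branch")
    }
    probs_ok <- TRUE
    for (b in node$branches[!comp]) {
      ok <- check_expr_names(b$prob,
                             paste0("chance node '", node$label, "' branch"))
      probs_ok <- probs_ok && ok
    }
    if (probs_ok && sum(comp) <= 1L) {
      probs <- resolve_branch_probs(node, values)
      bad <- which(probs < -PROB_SUM_TOL | probs > 1 + PROB_SUM_TOL)
      for (i in bad) {
        note("chance node '", node$label, "': branch probability ",
             format(probs[i]), " outside [0, 1]")
      }
      s <- sum(probs)
      if (abs(s - 1) > PROB_SUM_TOL) {
        note("chance node '", node$label, "': branch probabilities sum to ",
             format(s))
      }
    }
    for (b in node$branches) walk(b$node)
    invisible()
  }

  for (s in tree$strategies) walk(s)
  structure(problems, class = "validation_report")
}

#' Is a validation report empty?
#' @param report A `validation_report` from [validate_tree()].
#' @return `TRUE` when no violations were found.
#' @export
is_valid <- function(report) {
  stopifnot(inherits(report, "validation_report"))
  length(report) == 0L
}

#' @export
print.validation_report <- function(x, ...) {
  if (length(x) == 0L) {
    cat("<validation_report> model is valid\n")
  } else {
    cat("<validation_report>", length(x), "problem(s):\n")
    cat(paste0("  - ", unclass(x)), sep = "\n")
  }
  invisible(x)
}
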