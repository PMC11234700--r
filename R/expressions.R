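# Payoff and branch-probability expressions: a deliberately small arithmetic
# language over parameter names and numeric literals (+ - * / and
# parentheses), so model configs stay auditable. Branch probabilities may
# additionally be the keyword "complement", resolved per chance node as
# 1 - sum(siblings).

ALLOWED_OPS <- c("+", "-", "*", "/", "(")

parse_model_expr <- function(text) {
  if (!is.character(text) || length(text) != 1L || !nzchar(trimws(text))) {
    stop("expression must be a single non-empty string", call. = FALSE)
  }
  e <- tryCatch(str2lang(text), error = function(err) {
    stop("cannot parse expression '", text, "': ", conditionMessage(err),
         call. = FALSE)
  })
  check_model_expr(e, text)
  e
}

check_model_expr <- function(e, text) {
  if (is.numeric(e)) return(invisible(TRUE))
  if (is.symbol(e)) return(invisible(TRUE))
  if (is.call(e)) {
    op <- as.character(e[[1]])
    if (!op %in% ALLOWED_OPS) {
      stop("operator '", op, "' not allowed in expression '", text,
           "' (only + - * / and parentheses)", call. = FALSE)
    }
    for (i in seq_along(e)[-1]) check_model_expr(e[[i]], text)
    return(invisible(TRUE))
  }
  stop("invalid token in expression '", text, "'", call. = FALSE)
}

# Parameter names referenced by an expression string.
expr_param_names <- function(text) {
  e <- parse_model_expr(text)
  unique(all.vars(e))
}

eval_model_expr <- function(e, values) {
  if (is.character(e)) e <- parse_model_expr(e)
  eval(e, envir = as.list(values))
}
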