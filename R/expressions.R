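# Restricted arithmetic expression grammar used for rate laws and observables.
# Only names, numeric literals, + - * / ^ and parentheses are admitted, so a
# model file can never smuggle in arbitrary code.

.tf_allowed_ops <- c("+", "-", "*", "/", "^", "(")

tf_validate_expr <- function(e, allowed_names, where = "expression") {
  if (is.numeric(e) || is.integer(e) || is.complex(e)) {
    return(invisible(TRUE))
  }
  if (is.name(e)) {
    nm <- as.character(e)
    if (!nm %in% allowed_names) {
      stop(sprintf("unknown symbol '%s' in %s", nm, where), call. = FALSE)
    }
    return(invisible(TRUE))
  }
  if (is.call(e)) {
    op <- e[[1L]]
    if (!is.name(op) || !as.character(op) %in% .tf_allowed_ops) {
      stop(sprintf("operator or function '%s' is not allowed in %s (only + - * / ^ and parentheses)",
                   deparse(op), where), call. = FALSE)
    }
    for (i in seq_along(e)[-1L]) {
      tf_validate_expr(e[[i]], allowed_names, where)
    }
    return(invisible(TRUE))
  }
  stop(sprintf("unsupported construct in %s", where), call. = FALSE)
}

tf_parse_expr <- function(text, allowed_names, where = "expression") {
  stopifnot(is.character(text), length(text) == 1L)
  e <- tryCatch(
    str2lang(text),
    error = function(err) stop(sprintf("cannot parse %s: '%s'", where, text), call. = FALSE)
  )
  tf_validate_expr(e, allowed_names, where)
  e
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Deterministic child seeds: a small string hash folded with the master seed,
# kept strictly below 2^31 so it is always a valid integer seed.
tf_derive_seed <- function(master, key, phase = "") {
  s <- paste0(as.character(key), ":", as.character(phase))
  h <- 0
  for (ch in utf8ToInt(s)) h <- (h * 31 + ch) %% 2147483647
  ((master %% 65521) * 65521 + h) %% 2147483646 + 1
}

#' Evaluation and sampling counter
#'
#' A small environment with fields `evaluations` and `samplings`, passed to
#' scoring and sampling operations for budget accounting.  Every
#' score-backed viability check increments `evaluations` (including
#' re-validations of known points); every adaptive re-sampling increments
#' `samplings`.
#'
#' @return a counter environment.
#' @export
tf_new_counter <- function() {
  env <- new.env(parent = emptyenv())
  env$evaluations <- 0L
  env$samplings <- 0L
  env
}
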