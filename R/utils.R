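# Internal helpers: classed conditions and small numeric utilities.

#' Signal a classed package error
#'
#' All user-facing failures in the package raise conditions inheriting from
#' `"b2p_error"` plus a specific subclass, so callers can trap individual
#' failure modes (e.g. `"b2p_refused_comparison"`) with `tryCatch()`.
#'
#' @param class character; specific condition subclass.
#' @param message character; human-readable message.
#' @param ... named fields attached to the condition object.
#' @keywords internal
#' @noRd
b2p_stop <- function(class, message, ...) {
  cond <- structure(
    class = c(class, "b2p_error", "error", "condition"),
    list(message = message, call = sys.call(-1), ...)
  )
  stop(cond)
}

b2p_warn <- function(class, message, ...) {
  cond <- structure(
    class = c(class, "b2p_warning", "warning", "condition"),
    list(message = message, call = sys.call(-1), ...)
  )
  warning(cond)
}

# scalar checks ---------------------------------------------------------

is_number <- function(x) is.numeric(x) && length(x) == 1L && is.finite(x)

stopifnot_number <- function(x, name, positive = FALSE, nonneg = FALSE) {
  if (!is_number(x)) {
    b2p_stop("b2p_invalid_argument", sprintf("`%s` must be a finite numeric scalar", name))
  }
  if (positive && x <= 0) {
    b2p_stop("b2p_invalid_argument", sprintf("`%s` must be > 0 (got %g)", name, x))
  }
  if (nonneg && x < 0) {
    b2p_stop("b2p_invalid_argument", sprintf("`%s` must be >= 0 (got %g)", name, x))
  }
  invisible(x)
}

#' Run an expression with a temporary RNG seed, restoring global state
#' @noRd
with_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      },
      add = TRUE
    )
  }
  set.seed(seed)
  expr
}

# formatting used by CSV writers (documented %.6g round trip)
fmt_num <- function(x) formatC(x, format = "g", digits = 6)
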