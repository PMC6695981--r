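# Classed error conditions used across the package. Every domain error is a
# condition of class c("bcg_<What>", "bcg_error", "error"); tests and callers
# dispatch on the first class.

bcg_abort <- function(class, message, ...) {
  stop(structure(
    class = c(paste0("bcg_", class), "bcg_error", "error", "condition"),
    list(message = message, call = sys.call(-1), ...)
  ))
}

# shared validators ---------------------------------------------------------

assert_scalar_num <- function(x, name, lower = -Inf, upper = Inf) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x) || x < lower || x > upper)
    bcg_abort("InvalidSpec", sprintf("`%s` must be a finite number in [%g, %g]", name, lower, upper))
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
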