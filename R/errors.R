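# Typed condition system. Every validation failure in the package signals a
# condition whose first class names the error kind (e.g. "DuplicateMoleculeError"),
# so callers and the CLI can dispatch on it; all of them also inherit from
# "edgeqnet_error".

eq_abort <- function(class, message, ..., call = NULL) {
  cond <- structure(
    class = c(class, "edgeqnet_error", "error", "condition"),
    list(message = message, call = call, data = list(...))
  )
  stop(cond)
}

#' @export
print.edgeqnet_error <- function(x, ...) {
  cat("<", class(x)[1], "> ", conditionMessage(x), "\n", sep = "")
  invisible(x)
}

# internal helpers -----------------------------------------------------------

check_number <- function(x, name, lower = -Inf, upper = Inf) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x) || x < lower || x > upper) {
    eq_abort("ConfigError", sprintf(
      "`%s` must be a single finite number in [%s, %s]", name, lower, upper))
  }
  x
}

check_count <- function(x, name, lower = 1L) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x) || x < lower ||
      x != as.integer(x)) {
    eq_abort("ConfigError", sprintf("`%s` must be an integer >= %d", name, lower))
  }
  as.integer(x)
}
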