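`%||%` <- function(a, b) if (is.null(a)) b else a

stopf <- function(...) stop(sprintf(...), call. = FALSE)

# scalar checks used by the config constructors; all errors are descriptive
check_scalar <- function(x, name, min = -Inf, max = Inf, strict_min = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x))
    stopf("`%s` must be a single finite number", name)
  if (strict_min && x <= min) stopf("`%s` must be > %g", name, min)
  if (!strict_min && x < min) stopf("`%s` must be >= %g", name, min)
  if (x > max) stopf("`%s` must be <= %g", name, max)
  invisible(x)
}

check_prob <- function(x, name) check_scalar(x, name, min = 0, max = 1)

check_seed <- function(seed) {
  if (missing(seed) || is.null(seed) || !is.numeric(seed) || length(seed) != 1L)
    stopf("`seed` is required and must be a single integer")
  as.integer(seed)
}
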