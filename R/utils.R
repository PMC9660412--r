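#' @importFrom rlang abort warn %||%
#' @importFrom stats rnorm runif fft sd cor
NULL

# internal: consistent validation failure naming the offending field
fail_field <- function(field, msg) {
  abort(sprintf("invalid `%s`: %s", field, msg), class = "eegseize_validation_error")
}

check_scalar_num <- function(x, field, lower = -Inf, upper = Inf, strict = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x)) {
    fail_field(field, "must be a single finite number")
  }
  ok <- if (strict) x > lower && x < upper else x >= lower && x <= upper
  if (!ok) {
    fail_field(field, sprintf("must be in %s%s, %s%s", if (strict) "(" else "[",
                              lower, upper, if (strict) ")" else "]"))
  }
  invisible(x)
}

check_flag <- function(x, field) {
  if (!is.logical(x) || length(x) != 1L || is.na(x)) fail_field(field, "must be TRUE or FALSE")
  invisible(x)
}

# internal: run `expr` under a private RNG state seeded with `seed`
with_rng <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  check_scalar_num(seed, "seed")
  withr::with_seed(as.integer(seed), expr)
}

seizure_class_levels <- function(n_classes) {
  if (n_classes == 2L) c("nonseizure", "seizure") else c("nonseizure", "onset", "seizure")
}
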