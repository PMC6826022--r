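#' @importFrom methods new validObject is slot
#' @importFrom stats coef lm optimize pchisq rnorm rexp sd aov TukeyHSD t.test
#' @importFrom utils read.csv write.csv
NULL

# Classed error constructor so callers can condition on failure modes.
fhStop <- function(class, msg, call. = FALSE) {
  stop(errorCondition(msg, class = c(class, "fishheartError", "error")))
}

fhCheck <- function(ok, class, msg) {
  if (!isTRUE(ok)) fhStop(class, msg)
  invisible(TRUE)
}

# All generators draw through this wrapper: the global RNG stream is left
# untouched and identical (params, seed) give bit-identical output.
fhWithSeed <- function(seed, expr) {
  fhCheck(is.numeric(seed) && length(seed) == 1L && is.finite(seed),
          "invalidParameterError", "'seed' must be a single finite number")
  withr::with_seed(as.integer(seed), expr)
}

isScalarNum <- function(x) is.numeric(x) && length(x) == 1L && is.finite(x)

checkScalar <- function(x, name, lower = -Inf, upper = Inf,
                        strict_lower = FALSE, strict_upper = FALSE) {
  fhCheck(isScalarNum(x), "invalidParameterError",
          sprintf("'%s' must be a single finite number", name))
  low_ok <- if (strict_lower) x > lower else x >= lower
  hi_ok <- if (strict_upper) x < upper else x <= upper
  fhCheck(low_ok && hi_ok, "invalidParameterError",
          sprintf("'%s' = %g is outside its allowed range", name, x))
  invisible(TRUE)
}
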