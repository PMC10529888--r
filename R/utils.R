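# Round half away from zero at `digits` decimals. R's round() uses IEC 60559
# half-to-even (0.625 -> 0.62), which does not reproduce how clinical papers
# print proportions; published 2-dp tables round 0.625 -> 0.63.
round_half_up <- function(x, digits = 2) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

check_number <- function(x, name, min = -Inf, max = Inf, allow_vector = FALSE) {
  if (!allow_vector && length(x) != 1) {
    abort(sprintf("`%s` must be a single number, not length %d.", name, length(x)))
  }
  if (!is.numeric(x) || anyNA(x) || any(!is.finite(x))) {
    abort(sprintf("`%s` must be finite and numeric.", name))
  }
  if (any(x < min)) abort(sprintf("`%s` must be >= %s.", name, format(min)))
  if (any(x > max)) abort(sprintf("`%s` must be <= %s.", name, format(max)))
  invisible(x)
}

# Run `expr` under a fixed RNG seed when one is given, leaving the caller's
# RNG state untouched; otherwise use the ambient RNG stream.
with_optional_seed <- function(seed, expr) {
  if (is.null(seed)) expr else withr::with_seed(as.integer(seed), expr)
}
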