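# internal helpers

# run code with a fixed RNG seed without disturbing the caller's RNG state
with_seed <- function(seed, code) {
  withr::with_seed(seed, code)
}

# strict scalar checks used across the public surface
check_number <- function(x, name, lower = -Inf, upper = Inf,
                         strict_lower = FALSE, strict_upper = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x)) {
    abort(sprintf("`%s` must be a single non-missing number.", name))
  }
  lo_ok <- if (strict_lower) x > lower else x >= lower
  hi_ok <- if (strict_upper) x < upper else x <= upper
  if (!lo_ok || !hi_ok) {
    abort(sprintf(
      "`%s` must be in %s%s, %s%s; got %g.", name,
      if (strict_lower) "(" else "[", format(lower),
      format(upper), if (strict_upper) ")" else "]", x
    ))
  }
  invisible(x)
}

check_seed <- function(seed) {
  if (!is.numeric(seed) || length(seed) != 1L || is.na(seed) ||
      seed != as.integer(seed)) {
    abort("`seed` must be a single integer.")
  }
  as.integer(seed)
}

# canonical unordered taxon pair: a < b lexically
order_pair <- function(a, b) {
  swap <- a > b
  tibble(
    taxon_a = ifelse(swap, b, a),
    taxon_b = ifelse(swap, a, b)
  )
}
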