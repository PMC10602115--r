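# internal helpers

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_config <- function(field, msg) {
  stop(sprintf("invalid configuration field '%s': %s", field, msg), call. = FALSE)
}

check_count <- function(x, field, min = 1L) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < min || x != round(x))
    stop_config(field, sprintf("must be a single integer >= %d", min))
  as.integer(x)
}

check_fraction <- function(x, field, lo = 0, hi = 1, lo_open = FALSE, hi_open = FALSE) {
  ok <- is.numeric(x) && length(x) == 1L && !is.na(x) &&
    (if (lo_open) x > lo else x >= lo) && (if (hi_open) x < hi else x <= hi)
  if (!ok) stop_config(field, sprintf("must lie in %s%g, %g%s",
                                      if (lo_open) "(" else "[", lo, hi,
                                      if (hi_open) ")" else "]"))
  as.numeric(x)
}

# run expr under an isolated RNG state seeded with `seed`
with_rng <- function(seed, expr) {
  seed <- check_count(seed, "seed", min = 0L)
  withr::with_seed(seed, expr)
}
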