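# Internal helpers shared across modules.

# Run `code` under a fixed RNG seed without disturbing the caller's RNG state.
# seed = NULL means "use the RNG as-is" (still reproducible if the caller seeds).
with_seed_or_not <- function(seed, code) {
  if (is.null(seed)) {
    force(code)
  } else {
    stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
    withr::with_seed(as.integer(seed), code)
  }
}

check_number <- function(x, name, lower = -Inf, upper = Inf,
                         closed_lower = TRUE, closed_upper = TRUE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x)) {
    abort(sprintf("`%s` must be a single finite number.", name))
  }
  lo_ok <- if (closed_lower) x >= lower else x > lower
  hi_ok <- if (closed_upper) x <= upper else x < upper
  if (!lo_ok || !hi_ok) {
    abort(sprintf(
      "`%s` must be in %s%g, %g%s (got %g).",
      name, if (closed_lower) "[" else "(", lower, upper,
      if (closed_upper) "]" else ")", x
    ))
  }
  invisible(x)
}

check_count <- function(x, name, lower = 1L) {
  check_number(x, name, lower = lower)
  if (x != as.integer(x)) abort(sprintf("`%s` must be an integer.", name))
  as.integer(x)
}

check_series <- function(x, name = "x", min_len = 2L) {
  if (!is.numeric(x)) abort(sprintf("`%s` must be numeric.", name))
  if (length(x) < min_len) {
    abort(sprintf("`%s` must have at least %d values.", name, min_len))
  }
  if (anyNA(x) || any(!is.finite(x))) {
    abort(sprintf("`%s` contains non-finite values.", name))
  }
  invisible(x)
}

# Deterministic per-cell substream seeds derived from one master seed, so any
# subject/session/ROI subset reproduces identically within a fixed design.
spawn_seeds <- function(master_seed, n) {
  with_seed_or_not(master_seed, sample.int(.Machine$integer.max - 1L, n, replace = TRUE))
}
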