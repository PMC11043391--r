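#' @keywords internal
"_PACKAGE"

# Internal validation helpers. All user-facing errors funnel through stop()
# with call. = FALSE so messages read as pipeline diagnostics, not tracebacks.

sk_assert <- function(cond, msg) {
  if (!isTRUE(cond)) stop(msg, call. = FALSE)
  invisible(TRUE)
}

sk_check_prob <- function(x, name, open_low = TRUE, open_high = TRUE) {
  sk_assert(is.numeric(x) && length(x) == 1L && is.finite(x),
            sprintf("'%s' must be a single finite number", name))
  lo <- if (open_low) x > 0 else x >= 0
  hi <- if (open_high) x < 1 else x <= 1
  sk_assert(lo && hi, sprintf("'%s' must lie in %s0,1%s (got %g)",
                              name, if (open_low) "(" else "[",
                              if (open_high) ")" else "]", x))
  x
}

sk_check_count <- function(x, name, min = 1L) {
  sk_assert(is.numeric(x) && length(x) == 1L && is.finite(x) &&
              x == as.integer(x) && x >= min,
            sprintf("'%s' must be an integer >= %d (got %s)", name, min,
                    paste(x, collapse = ",")))
  as.integer(x)
}

sk_check_pos <- function(x, name) {
  sk_assert(is.numeric(x) && length(x) == 1L && is.finite(x) && x > 0,
            sprintf("'%s' must be a single positive number (got %s)", name,
                    paste(x, collapse = ",")))
  as.numeric(x)
}

# Local RNG scope: every stochastic operation takes an explicit seed and
# restores the caller's random state on exit (no global state leakage).
with_seed <- function(seed, code) {
  sk_assert(is.numeric(seed) && length(seed) == 1L && is.finite(seed),
            "'seed' must be a single integer")
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(as.integer(seed))
  force(code)
}
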