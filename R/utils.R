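# Run code under an explicit seed without disturbing the caller's RNG state.
# All stochastic functions in the package take a `seed` argument and route
# through this, so there is no reliance on (or mutation of) global RNG state.
local_seed <- function(seed, code) {
  stopifnot(is.numeric(seed), length(seed) == 1, is.finite(seed))
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else {
    NULL
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  force(code)
}

# Derive a stream of child seeds from one parent seed, keeping each below
# 2^31 so they remain valid R integers.
derive_seeds <- function(seed, n) {
  local_seed(seed, sample.int(.Machine$integer.max - 1L, n))
}

assert_scalar_number <- function(x, name, min = -Inf, strict = FALSE) {
  if (!is.numeric(x) || length(x) != 1 || !is.finite(x)) {
    abort(sprintf("`%s` must be a single finite number.", name))
  }
  if (strict && x <= min) {
    abort(sprintf("`%s` must be > %s (got %s).", name, format(min), format(x)))
  }
  if (!strict && x < min) {
    abort(sprintf("`%s` must be >= %s (got %s).", name, format(min), format(x)))
  }
  invisible(x)
}

assert_columns <- function(df, cols, what) {
  missing <- setdiff(cols, names(df))
  if (length(missing) > 0) {
    abort(sprintf(
      "%s is missing required column(s): %s.",
      what, paste0("`", missing, "`", collapse = ", ")
    ))
  }
  invisible(df)
}
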