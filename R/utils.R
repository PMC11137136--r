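# internal helpers shared across modules

# Evaluate `code` under a temporary RNG state seeded with `seed`, restoring
# the caller's RNG afterwards. All randomness in the package flows through
# this so that a user's global RNG stream is never disturbed.
with_seed <- function(seed, code) {
  if (!is.numeric(seed) || length(seed) != 1L || !is.finite(seed)) {
    rlang::abort("`seed` must be a single finite number.")
  }
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
  }, add = TRUE)
  set.seed(as.integer(seed))
  force(code)
}

# Derive a per-unit substream seed from a base seed and a unit index.
# Keeps results for unit i independent of how many units precede it.
substream_seed <- function(seed, index) {
  s <- (as.numeric(seed) %% 1000003) * 2011 + 7 * as.numeric(index) + 13
  as.integer(s %% 2147483647)
}

stopifnot_scalar_number <- function(x, name, positive = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x)) {
    rlang::abort(sprintf("`%s` must be a single finite number.", name))
  }
  if (positive && x <= 0) {
    rlang::abort(sprintf("`%s` must be positive.", name))
  }
  invisible(x)
}
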