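# Internal helpers shared across modules.

# log(sum(exp(x))) without overflow; x may contain -Inf.
logsumexp <- function(x) {
  m <- max(x)
  if (!is.finite(m)) return(m)
  m + log(sum(exp(x - m)))
}

# Derive a stream-specific seed from a global one, keeping it a valid
# 32-bit integer. `stream` is a short label naming the consumer.
derive_seed <- function(seed, stream) {
  stopifnot(is.numeric(seed), length(seed) == 1)
  h <- sum(utf8ToInt(stream) * seq_along(utf8ToInt(stream)))
  as.integer((as.numeric(seed) * 48271 + h) %% 2147483647L)
}

# Run `expr` under a temporary RNG state seeded with `seed`.
with_seed <- function(seed, expr) {
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
  set.seed(seed)
  force(expr)
}

check_counts <- function(n_inclusion, n_exclusion) {
  if (any(n_inclusion < 0) || any(n_exclusion < 0)) {
    abort("read counts must be non-negative")
  }
  if (any(n_inclusion != floor(n_inclusion)) || any(n_exclusion != floor(n_exclusion))) {
    abort("read counts must be integers")
  }
  invisible(TRUE)
}

`%||%` <- rlang::`%||%`
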