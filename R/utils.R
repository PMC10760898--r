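# Internal helpers.

# Evaluate `expr` under a fixed RNG seed without disturbing the caller's
# random stream.
with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
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
  expr
}

# Derive a stream-specific 31-bit sub-seed from a master seed.
derive_seed <- function(seed, stream) {
  (as.integer(seed) * 48271 + as.integer(stream) * 16807) %% 2147483647L
}
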