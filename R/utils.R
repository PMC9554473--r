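# Small internal helpers.

# Temporarily seed the RNG without clobbering the caller's stream.
local_seed <- function(seed) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else {
    NULL
  }
  set.seed(as.integer(seed))
  old
}

restore_seed <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  } else {
    assign(".Random.seed", old, envir = globalenv())
  }
  invisible(NULL)
}

clamp <- function(x, lo, hi) pmin(pmax(x, lo), hi)

# derive a per-item 31-bit seed from a master seed
derive_seed <- function(master, i) {
  m <- as.double(master) %% 2147483647
  as.integer((m * 48271 + i * 104729) %% 2147483647)
}
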