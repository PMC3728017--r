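# Internal helpers: seed discipline and small utilities.

# Run code under a fixed RNG seed without disturbing the caller's RNG state.
with_seed <- function(seed, code) {
  seed <- as.integer(seed)  # force now: the caller's expression may use RNG
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv()))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(as.integer(seed))
  force(code)
}

# Deterministic child seed from a master seed, kept inside 32-bit range.
derive_seed <- function(master, i) {
  as.integer((as.double(master) + 104729 * as.double(i)) %% 2147483646 + 1)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
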