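# Deterministic seed derivation.  All randomness in the package flows from
# user-supplied integer seeds through these helpers, so that every run is
# reproducible from its master seed.  Arithmetic is done in doubles below
# 2^53 and reduced mod a Mersenne prime, keeping results in 1..2^31-2.

mix_seed <- function(...) {
  x <- 11
  for (v in as.numeric(c(...))) {
    x <- (x * 69069 + v + 1013904223) %% 2147483647
    x <- (x * 69069 + 1) %% 2147483647
  }
  as.integer(x + 1)
}

# n child seeds from one master seed
seed_stream <- function(master, n, salt = 0) {
  vapply(seq_len(n), function(i) mix_seed(master, salt, i), integer(1))
}

# Evaluate expr with R's RNG seeded, restoring the caller's RNG state.
with_seed <- function(seed, expr) {
  has <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has) old <- get(".Random.seed", envir = globalenv())
  set.seed(seed)
  on.exit({
    if (has) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  expr
}
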