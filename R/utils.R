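# Evaluate `expr` under a temporary RNG state seeded with `seed`, restoring
# the caller's RNG state afterwards. All package randomness flows through
# this, so sub-streams derived from (seed, counter) are reproducible and
# independent of evaluation order.
.with_seed <- function(seed, expr) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_seed) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed %% .Machine$integer.max))
  expr
}

# Deterministic sub-seed for stream `k` of a top-level seed; stays within
# 32-bit integer range.
.derive_seed <- function(seed, k) {
  as.integer((as.double(seed) * 1000 + k) %% 2147483647)
}
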