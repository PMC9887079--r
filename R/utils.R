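# Seed plumbing shared by the stochastic modules.

# Evaluate `code` under a temporary RNG state seeded with `seed`, restoring
# the caller's state afterwards so library code never clobbers user RNG.
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

# Deterministic per-lesion substream seed from (global seed, lesion index),
# kept below 2^31 so it is a valid R integer seed. Using substreams makes a
# cohort's first k lesions invariant under changes to the cohort size.
substream_seed <- function(seed, index) {
  s <- (as.numeric(seed) %% 2147483647) * 48271 + as.numeric(index) * 12345 + 7919
  as.integer(s %% 2147483647)
}
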