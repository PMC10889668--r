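# Internal helpers shared across modules.

# Evaluate `code` under set.seed(seed) without disturbing the caller's RNG
# stream.
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

# Squared Euclidean distances from every row of `m` to the vector `v`.
row_dist2 <- function(m, v) {
  rowSums(sweep(m, 2, v, "-")^2)
}
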