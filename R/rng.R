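# Seed management: one master seed spawns named substreams so that the
# population draw, the per-replication sample draws and the stochastic
# model fits use non-overlapping, reproducible RNG streams.

# Deterministic 31-bit hash of (master seed, stream name, index).
# All intermediate products stay below 2^53 so the arithmetic is exact
# in doubles; the result is a valid set.seed() argument.
substream_seed <- function(master, name, index = 0L) {
  stopifnot(is.numeric(master), length(master) == 1L, is.finite(master))
  m <- 2147483647 # 2^31 - 1
  h <- 0
  for (code in utf8ToInt(as.character(name))) {
    h <- (h * 31 + code) %% m
  }
  h <- (h + (abs(master) %% m) * 69069) %% m
  h <- (h + (index %% m) * 40503) %% m
  # avoid the degenerate seed 0
  as.integer(h %% (m - 1L) + 1L)
}

# Evaluate `expr` under `seed` with the caller's RNG state untouched.
with_seed <- function(seed, expr) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_old) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_old) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  expr
}
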