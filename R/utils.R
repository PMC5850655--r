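# Internal helpers shared across modules.

# 31-bit polynomial hash folding a user seed, a stream key and a replicate
# index into an independent sub-seed. Deterministic across platforms (all
# arithmetic stays below 2^53 so doubles are exact); makes every replicate's
# random stream a pure function of (seed, key, index), independent of the
# order in which replicates or clades are evaluated.
mix_seed <- function(seed, key, index = 0L) {
  m <- 2147483647 # 2^31 - 1
  h <- as.numeric(seed) %% m
  for (code in utf8ToInt(as.character(key))) {
    h <- (h * 31 + code) %% m
  }
  h <- (h * 31 + as.numeric(index) + 1) %% m
  as.integer(h)
}

# Run `expr` under a temporary RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, expr) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_seed) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  expr
}

`%||%` <- function(a, b) if (is.null(a)) b else a
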