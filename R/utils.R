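# Small internal utilities.

# Evaluate `code` under a fixed RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, code) {
  env <- globalenv()
  had <- exists(".Random.seed", envir = env, inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = env, inherits = FALSE)
  on.exit({
    if (had) {
      assign(".Random.seed", old, envir = env)
    } else if (exists(".Random.seed", envir = env, inherits = FALSE)) {
      rm(".Random.seed", envir = env)
    }
  })
  set.seed(as.integer(seed))
  code
}

# Derive a deterministic substream seed (< 2^31) from a master seed and a
# stream name, so adding a stream never perturbs the others.
stream_seed <- function(seed, stream) {
  h <- sum(utf8ToInt(stream) * seq_along(utf8ToInt(stream)))
  as.integer((as.numeric(seed) * 48271 + h * 16807) %% 2147483647)
}

# sequence-comparison key: exact or with I/L collapsed
il_key <- function(collapse) {
  if (isTRUE(collapse)) {
    function(x) gsub("I", "L", x, fixed = TRUE)
  } else {
    identity
  }
}

# sample() without its length-1 surprise
sample_vec <- function(x, size, replace = FALSE, prob = NULL) {
  x[sample.int(length(x), size, replace = replace, prob = prob)]
}
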