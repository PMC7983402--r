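# Internal helpers shared across modules.

# Deterministic sub-seed derivation. Every random component (bootstrap
# replicate, repetition, imputation draw) runs on its own counter-derived
# substream so results do not depend on execution order.
# Constants keep seed * 69069 < 2^53, so the arithmetic is exact in doubles.
mix_seed <- function(seed, k = 0L) {
  s <- (as.numeric(seed) %% 2147483647) * 69069 + as.numeric(k) * 10007 + 1
  as.integer(s %% 2147483629)
}

# Evaluate `code` under a local RNG state; the caller's stream is untouched.
with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
    get(".Random.seed", globalenv())
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

# Numerically stable log(1 + exp(x)).
log1pexp <- function(x) {
  out <- numeric(length(x))
  pos <- x > 0
  out[pos] <- x[pos] + log1p(exp(-x[pos]))
  out[!pos] <- log1p(exp(x[!pos]))
  out
}

logit <- function(p) stats::qlogis(p)
expit <- function(x) stats::plogis(x)
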