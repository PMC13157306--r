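# Internal helpers: seed substreams and small validators.

# Deterministically derive a child seed from a master seed and a stream tag.
# Keeps results reproducible from one master seed while giving imputation
# chains, per-outcome CV splits and bootstrap draws independent streams.
# All values stay below 2^31 - 1.
seed_stream <- function(seed, tag) {
  stopifnot(is.numeric(seed), length(seed) == 1, is.finite(seed))
  tag <- sum(as.integer(charToRaw(as.character(tag))) *
               (seq_along(charToRaw(as.character(tag))) %% 97 + 1))
  as.integer((abs(seed) * 48271 + tag * 16807) %% 2147483647)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Evaluate `expr` under `set.seed(seed)` while preserving the caller's RNG
# state, so seeded internals (fold splits, imputation chains) never disturb
# an enclosing stochastic procedure such as a bootstrap loop.
with_seed <- function(seed, expr) {
  has_old <- exists(".Random.seed", globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", globalenv(), inherits = FALSE)
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

assert_scalar_num <- function(x, name, lo = -Inf, hi = Inf) {
  if (!is.numeric(x) || length(x) != 1 || !is.finite(x) || x < lo || x > hi)
    stop(sprintf("`%s` must be a single number in [%s, %s]", name, lo, hi),
         call. = FALSE)
  x
}
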