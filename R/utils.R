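## Internal helpers.

## Evaluate expr with a private RNG state so generators are pure functions of
## their spec + seed and never disturb the caller's random stream.
withSeed <- function(seed, expr) {
  has <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  eval.parent(substitute(expr))
}

## Derive a stream of sub-seeds from one master seed (kept < 2^31).
deriveSeeds <- function(seed, n) {
  withSeed(seed, sample.int(.Machine$integer.max - 1L, n))
}

stopifnot2 <- function(cond, msg) if (!isTRUE(cond)) stop(msg, call. = FALSE)

asCount <- function(x, name) {
  if (length(x) != 1L || !is.finite(x) || x < 0 || x != round(x))
    stop(name, " must be a single non-negative integer", call. = FALSE)
  as.integer(x)
}
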