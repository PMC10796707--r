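# Internal helpers shared across modules.

# Evaluate `expr` under a fixed RNG seed, restoring the caller's RNG state.
withSeed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv()))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  expr
}

# Derive a stream of distinct 32-bit sub-seeds from one base seed.
subSeeds <- function(seed, n) {
  withSeed(seed, sample.int(.Machine$integer.max, n))
}

# Min-max rescale a numeric vector to [0, 1]; constant input maps to zeros.
minmaxVector <- function(v) {
  r <- range(v)
  if (r[2] - r[1] <= 0) return(rep(0, length(v)))
  (v - r[1]) / (r[2] - r[1])
}

`%||%` <- function(a, b) if (is.null(a)) b else a
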