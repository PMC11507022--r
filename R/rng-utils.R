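# Seeded evaluation that restores the caller's RNG state, so that all
# generators are pure functions of their seed and parameters.
.with_seed <- function(seed, code) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed) %% .Machine$integer.max)
  force(code)
}

# Stable small integer derived from a string (for per-entry sub-seeds).
.string_seed <- function(x, offset = 0L) {
  v <- utf8ToInt(x)
  (sum(v * seq_along(v)) + offset) %% 2147483L
}
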