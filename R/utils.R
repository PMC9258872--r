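# Internal helpers.

# Evaluate expr under a local RNG seed, restoring the caller's RNG state.
withSeed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

# Deterministic derived seed (kept in 32-bit integer range).
deriveSeed <- function(seed, ...) {
  parts <- c(seed, unlist(list(...)))
  x <- 0
  for (p in parts) x <- (x * 1103515245 + as.numeric(p) + 12345) %% 2147483647
  as.integer(x)
}
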