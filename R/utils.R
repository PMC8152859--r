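# Seed plumbing: every stochastic operation derives a private stream from the
# caller's seed so stages are reproducible independently of evaluation order.

# deterministic 32-bit mix of a master seed and stream identifiers
derive_seed <- function(seed, ...) {
  ids <- c(as.integer(seed), as.integer(c(...)))
  h <- 0
  for (k in ids) {
    h <- (h * 31 + (k %% 2147483647) + 7) %% 2147483647
    h <- (h * 65599 + 17) %% 2147483647
  }
  as.integer(h)
}

# evaluate expr under a local RNG state; global .Random.seed untouched
with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  expr
}

`%||%` <- function(a, b) if (is.null(a)) b else a
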