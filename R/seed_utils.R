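# Seeded-randomness plumbing: every stochastic routine derives its own
# sub-stream from integer seeds so that outputs are byte-identical under a
# fixed top-level seed, independent of call order.

# evaluate expr under a temporary RNG state seeded with `seed`
with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

# mix integer components into a single seed in [1, 2^31 - 2]
derive_seed <- function(...) {
  parts <- as.numeric(unlist(list(...)))
  h <- 104729
  for (p in parts) h <- (h * 7919 + (p %% 2147483647) * 31 + 17) %% 2147483629
  as.integer(h + 1)
}
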