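# Deterministic sub-stream seeds. Every stochastic stage of the pipeline
# draws under a seed derived from (master seed, iteration, a string key),
# so adding or removing a species never perturbs the draws of the others.
# Plain 31-bit arithmetic; all intermediates stay far below 2^53.
.hash_string <- function(s) {
  h <- 0
  for (c in utf8ToInt(s)) h <- (h * 131 + c) %% 2147483647
  h
}

substream_seed <- function(master, iter, key) {
  h <- .hash_string(key)
  as.integer(((h * 2654435 + iter * 40503 + (master %% 2147483647) * 69069 + 7)
              %% 2147483646) + 1)
}

# Evaluate expr under a temporary RNG state; the caller's stream is restored
# afterwards. seed = NULL leaves the current stream untouched.
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed(seed)
  expr
}
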