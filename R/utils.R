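# Deterministic 32-bit seed derived from a master seed and a key path.
# All synthetic-data randomness flows through this, so any trial/channel can
# be regenerated in isolation and no global random state is shared.
deriveSeed <- function(master, ...) {
  key <- paste(c(format(master, scientific = FALSE), ...), collapse = "/")
  h <- 0
  for (ch in utf8ToInt(key)) h <- (h * 31 + ch) %% 2147483629
  as.integer(h)
}

# Evaluate expr with a local RNG seed, restoring the caller's RNG state.
withSeed <- function(seed, expr) {
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

# Condition helpers: errors carry a class so callers can test for them.
geStop <- function(msg, class, call. = FALSE) {
  stop(errorCondition(msg, class = c(class, "GaitEnvError")))
}
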