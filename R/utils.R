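`%||%` <- function(a, b) if (is.null(a)) b else a

# Evaluate expr under a temporary RNG state so library calls never clobber
# the caller's random stream.
with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(expr)
}

# Deterministic half-up rounding (printed percentages round 0.05 -> 0.1),
# unlike base round()'s half-to-even.
round_half_up <- function(x, digits = 1) {
  m <- 10^digits
  floor(x * m + 0.5) / m
}

# Derive a child seed from a base seed and a stream label, kept < 2^31.
child_seed <- function(seed, stream) {
  as.integer(((as.numeric(seed) %% 1000003) * 2011 + as.numeric(stream) * 7919) %%
               2147483629)
}

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)
warnf <- function(fmt, ...) warning(sprintf(fmt, ...), call. = FALSE)
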