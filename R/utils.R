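# Internal helpers: seeded evaluation and small numeric utilities.

# Evaluate expr with a temporarily-seeded RNG, restoring the caller's RNG
# state afterwards so library calls never disturb user-level reproducibility.
withSeed <- function(seed, expr) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      get(".Random.seed", envir = globalenv()) else NULL
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
          rm(".Random.seed", envir = globalenv())
      } else assign(".Random.seed", old, envir = globalenv())
    })
    set.seed(seed)
  }
  force(expr)
}

# Derive a reproducible child seed from a base seed and a stream label,
# keeping the result inside the 32-bit signed-integer range.
childSeed <- function(seed, ...) {
  key <- paste(c(seed, ...), collapse = "/")
  h <- 0
  for (ch in utf8ToInt(key)) h <- (h * 31 + ch) %% 2147483647
  as.integer(h)
}

normalize <- function(v) v / sqrt(sum(v^2))

# Rows of x normalised to unit length.
normalizeRows <- function(x) x / sqrt(rowSums(x^2))

stopIfNot <- function(cond, msg) if (!cond) stop(msg, call. = FALSE)
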