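# Shared internal helpers: deterministic seed derivation and input checks.

# Derive a 31-bit child seed from a base seed and a path of stage names /
# indices.  Stage insertion upstream never perturbs an unrelated stage's
# stream because each stream is addressed by its own path, not by draw order.
derive_seed <- function(seed, ...) {
  parts <- unlist(lapply(list(...), as.character), use.names = FALSE)
  h <- as.double(seed %% 2147483647L)
  for (p in parts) {
    for (cp in utf8ToInt(p)) {
      h <- (h * 31 + cp) %% 2147483629
    }
  }
  as.integer(h %% 2147483647)
}

# Evaluate an expression under a local RNG state so library internals never
# disturb the caller's stream.
with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else {
    NULL
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  expr
}

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

warnf <- function(fmt, ...) warning(sprintf(fmt, ...), call. = FALSE)

is_count <- function(x) {
  length(x) == 1L && is.numeric(x) && !is.na(x) && x > 0 && x == floor(x)
}
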