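# internal helpers shared across modules

# run code under a fixed RNG seed, restoring the caller's RNG state afterwards
with_seed <- function(seed, code) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      get(".Random.seed", envir = globalenv()) else NULL
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
          rm(".Random.seed", envir = globalenv())
      } else assign(".Random.seed", old, envir = globalenv())
    })
    set.seed(as.integer(seed))
  }
  force(code)
}

# derive a child seed from a master seed; stays within 32-bit integer range
derive_seed <- function(seed, offset) {
  as.integer((as.numeric(seed) * 1103L + as.numeric(offset) * 12289L) %% 2147483647)
}

check_count <- function(x, name, min = 1L) {
  if (length(x) != 1L || !is.numeric(x) || is.na(x) || x < min || x != floor(x))
    stop(sprintf("'%s' must be a single integer >= %d", name, min), call. = FALSE)
  as.integer(x)
}

check_number <- function(x, name, min = -Inf, strict = FALSE) {
  if (length(x) != 1L || !is.numeric(x) || is.na(x) ||
      (strict && x <= min) || (!strict && x < min))
    stop(sprintf("'%s' must be a single number %s %g", name,
                 if (strict) ">" else ">=", min), call. = FALSE)
  as.numeric(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
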