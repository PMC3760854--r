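# internal helpers

# Evaluate expr under a temporary RNG state seeded with `seed`, restoring the
# caller's .Random.seed afterwards. All stochastic entry points route through
# this so a single integer seed makes a whole run reproducible.
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
    set.seed(as.integer(seed))
  }
  force(expr)
}

# Derive a child seed from a run seed and a stream index, kept below 2^31.
childSeed <- function(seed, stream) {
  (as.numeric(seed) * 48271 + as.numeric(stream) * 16807) %% 2147483647
}

AA_ALPHABET20 <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]

assertProb <- function(x, what) {
  if (length(x) == 0) stop(what, " must be non-empty", call. = FALSE)
  if (any(!is.finite(x)) || any(x < 0) || any(x > 1))
    stop(what, " values must lie in [0, 1]", call. = FALSE)
  invisible(x)
}
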