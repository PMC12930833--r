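# Seed handling: every stochastic entry point takes one seed and derives
# independent sub-streams from it, so a pipeline run is reproducible from a
# single integer.

with_seed <- function(seed, code) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      get(".Random.seed", envir = globalenv())
    }
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
          rm(".Random.seed", envir = globalenv())
        }
      } else {
        assign(".Random.seed", old, envir = globalenv())
      }
    }, add = TRUE)
    set.seed(as.integer(seed))
  }
  force(code)
}

# k sub-seeds derived deterministically from one master seed; kept < 2^31.
derive_seeds <- function(seed, k) {
  with_seed(seed, sample.int(.Machine$integer.max - 1L, k))
}

assert_scalar_number <- function(x, name, lower = -Inf, upper = Inf) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < lower || x > upper) {
    abort(sprintf("`%s` must be a single number in [%s, %s].", name, lower, upper))
  }
  invisible(x)
}

# Coerce a two-class response to logical "is positive class".
as_positive <- function(y, positive) {
  if (is.logical(y)) return(y)
  y <- as.character(y)
  if (!positive %in% y) {
    abort(sprintf("positive class '%s' not present in response.", positive))
  }
  y == positive
}
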