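# Internal helpers shared across modules.

# Evaluate `expr` under a fixed RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, expr) {
  if (!is.null(seed)) {
    stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      get(".Random.seed", envir = globalenv())
    } else {
      NULL
    }
    on.exit({
      if (is.null(old)) {
        rm(".Random.seed", envir = globalenv())
      } else {
        assign(".Random.seed", old, envir = globalenv())
      }
    })
    set.seed(as.integer(seed))
  }
  expr
}

stop_if_not_scalar <- function(x, name, finite = TRUE) {
  if (!is.numeric(x) || length(x) != 1L || (finite && !is.finite(x))) {
    stop(sprintf("'%s' must be a single finite number", name), call. = FALSE)
  }
  invisible(x)
}

# Derive a stream-specific child seed from a master seed (kept < 2^31).
child_seed <- function(seed, k) {
  if (is.null(seed)) return(NULL)
  (as.numeric(seed) * 7919 + as.numeric(k) * 104729) %% 2147483587
}

`%||%` <- function(a, b) if (is.null(a)) b else a
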