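# internal helpers shared across modules

# Evaluate `expr` with a private, seeded RNG stream; the caller's RNG state
# is untouched. All stochastic code in the package routes through this.
with_seed <- function(seed, expr) {
  if (!is.numeric(seed) || length(seed) != 1L || is.na(seed)) {
    stop("`seed` must be a single non-missing number", call. = FALSE)
  }
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
  set.seed(as.integer(seed))
  expr
}

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

`%||%` <- function(a, b) if (is.null(a)) b else a

assert_prob <- function(p, what = "p-values") {
  if (any(!is.finite(p)) || any(p < 0) || any(p > 1)) {
    stopf("%s must all lie in [0, 1]", what)
  }
  invisible(p)
}
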