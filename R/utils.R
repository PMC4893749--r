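#' @keywords internal
"_PACKAGE"

#' Evaluate code under a fixed RNG seed, restoring the caller's RNG state
#'
#' All stochastic operations in the package route their randomness through
#' this helper so that a user-level seed fully determines the output without
#' clobbering the session RNG.
#'
#' @param seed integer scalar seed.
#' @param code expression to evaluate.
#' @return the value of `code`.
#' @keywords internal
with_seed <- function(seed, code) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
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
  force(code)
}

# derive a stream-specific child seed from a user seed; kept < 2^31
child_seed <- function(seed, stream) {
  as.integer((as.numeric(seed) %% 2147483647 * 1000003 + as.numeric(stream)) %% 2147483647)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_if_not_scalar_number <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x)) {
    stop(sprintf("`%s` must be a finite numeric scalar", name), call. = FALSE)
  }
  invisible(x)
}
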