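#' Evaluate an expression under a temporary RNG seed
#'
#' Saves and restores `.Random.seed` so seeded generators never disturb the
#' caller's RNG stream. All stochastic functions in the package route their
#' randomness through this helper.
#'
#' @param seed integer seed.
#' @param expr expression to evaluate.
#' @return the value of `expr`.
#' @keywords internal
with_seed <- function(seed, expr) {
  if (!is.numeric(seed) || length(seed) != 1L || !is.finite(seed)) {
    stop("`seed` must be a single finite number", call. = FALSE)
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

#' Derive a child seed from a master seed
#'
#' Deterministic splitting so each pipeline stage gets its own stream.
#' Kept below 2^31 - 1.
#'
#' @param seed master seed.
#' @param k stage index (>= 1).
#' @keywords internal
child_seed <- function(seed, k) {
  as.integer((as.numeric(seed) * 2654435761 + 97 * k) %% 2147483629)
}

stop_invalid <- function(...) {
  stop(sprintf(...), call. = FALSE)
}
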