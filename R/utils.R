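# internal helpers shared across modules

`%||%` <- function(a, b) if (is.null(a)) b else a

clamp <- function(x, lo, hi) pmin(pmax(x, lo), hi)

#' Evaluate an expression under a local RNG seed
#'
#' Saves and restores `.Random.seed` so generators are pure functions of
#' `(parameters, seed)` without disturbing the caller's RNG stream.
#' @noRd
with_seed <- function(seed, expr) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
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

abort_octa <- function(msg, class) {
  stop(structure(class = c(class, "octaperf_error", "error", "condition"),
                 list(message = msg, call = sys.call(-1))))
}
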