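#' Evaluate code under a temporary RNG seed
#'
#' Runs \code{code} with the global random-number generator seeded to
#' \code{seed}, then restores the previous RNG state, so that seeded
#' generators are pure functions of their arguments and leave the caller's
#' random stream untouched.
#'
#' @param seed integer seed; \code{NULL} leaves the RNG alone.
#' @param code expression to evaluate.
#' @return the value of \code{code}.
#' @keywords internal
withSeed <- function(seed, code) {
  if (!is.null(seed)) {
    had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
    old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
    on.exit({
      if (had) {
        assign(".Random.seed", old, envir = globalenv())
      } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    })
    set.seed(as.integer(seed))
  }
  force(code)
}

# midpoint of a range, integer floor((start+end)/2) in 1-based closed coords
.midpoint <- function(gr) {
  floor((GenomicRanges::start(gr) + GenomicRanges::end(gr)) / 2)
}

.assertScalarNumber <- function(x, name, lower = -Inf, upper = Inf,
                                openLower = FALSE, openUpper = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x))
    stop("'", name, "' must be a single finite number", call. = FALSE)
  lo <- if (openLower) x > lower else x >= lower
  hi <- if (openUpper) x < upper else x <= upper
  if (!lo || !hi)
    stop("'", name, "' = ", x, " is outside the allowed range", call. = FALSE)
  invisible(x)
}
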