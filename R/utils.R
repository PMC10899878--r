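#' Evaluate an expression under a temporary RNG seed
#'
#' Runs \code{code} with the global random-number generator seeded to
#' \code{seed}, then restores the caller's RNG state, so seeded package
#' operations never perturb the user's random stream. A \code{NULL} seed
#' evaluates the code with the current stream untouched.
#'
#' @param seed integer seed or \code{NULL}.
#' @param code expression to evaluate.
#' @return the value of \code{code}.
#' @keywords internal
withSeed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  if (!is.numeric(seed) || length(seed) != 1L || !is.finite(seed))
    stop("'seed' must be a single finite number or NULL")
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(as.integer(seed))
  force(code)
}

#' Derive a stage-specific seed from a global seed
#'
#' Deterministically mixes a global integer seed with a stage name so that
#' every pipeline stage gets its own reproducible random stream. The result
#' always fits in a 32-bit signed integer.
#'
#' @param seed global integer seed.
#' @param stage character tag naming the consumer (e.g. \code{"folds"}).
#' @return a positive integer seed.
#' @export
#' @examples
#' deriveSeed(1, "folds")
#' deriveSeed(1, "vae") != deriveSeed(1, "folds")
deriveSeed <- function(seed, stage) {
  stopifnot(is.character(stage), length(stage) == 1L)
  # 31-based polynomial rolling hash over the stage name, mixed with the seed;
  # all arithmetic stays below 2^53 so doubles are exact, result below 2^31.
  m <- 2147483629
  h <- 0
  for (ch in utf8ToInt(stage)) h <- (h * 31 + ch) %% m
  as.integer((h + (as.numeric(seed) %% m) * 48271) %% m) + 1L
}

# row-wise shuffle of a matrix, preserving colnames
shuffleRows <- function(x, seed = NULL) {
  withSeed(seed, x[sample.int(nrow(x)), , drop = FALSE])
}

# stop() with call.=FALSE everywhere, keeps messages clean
fail <- function(...) stop(..., call. = FALSE)
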