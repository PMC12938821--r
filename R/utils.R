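# Internal helpers shared across modules.

#' Evaluate an expression under a temporary RNG seed
#'
#' Sets the RNG seed, evaluates \code{expr}, and restores the caller's RNG
#' state afterwards, so seeded package functions do not disturb the user's
#' random stream. A \code{NULL} or \code{NA} seed evaluates \code{expr}
#' against the current stream.
#'
#' @param seed integer seed or \code{NA}/\code{NULL}.
#' @param expr expression to evaluate.
#' @return the value of \code{expr}.
#' @keywords internal
withSeed <- function(seed, expr) {
  if (!is.null(seed) && !is.na(seed)) {
    had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
    old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
    set.seed(as.integer(seed))
    on.exit({
      if (had) {
        assign(".Random.seed", old, envir = globalenv())
      } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    })
  }
  expr
}

#' Derive a stage seed from a global seed
#'
#' Deterministic splitting rule used by campaigns so that each stage can be
#' re-run in isolation: the stage name is hashed together with the global
#' seed into a 31-bit integer.
#'
#' @param seed global integer seed.
#' @param stage character stage name.
#' @return integer seed in \code{[1, 2^31 - 2]}.
#' @export
spawnSeed <- function(seed, stage) {
  stopifnot(is.character(stage), length(stage) == 1L)
  h <- sum(utf8ToInt(stage) * seq_along(utf8ToInt(stage)))
  v <- (abs(as.numeric(seed)) * 48271 + h * 69621) %% (2^31 - 1)
  as.integer(v + 1)
}

# round half away from zero to `digits` decimals (printed-style rounding,
# unlike base round()'s round-half-even)
roundHalfUp <- function(x, digits = 2L) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# recycle a scalar to length n with basic checks
recycleTo <- function(x, n, what) {
  if (length(x) == 1L) x <- rep(x, n)
  if (length(x) != n) {
    stop(sprintf("'%s' must have length 1 or %d, got %d", what, n, length(x)))
  }
  x
}
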