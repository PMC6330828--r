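# Independent RNG streams emulated by swapping .Random.seed, so that e.g.
# redrawing the test noise cannot perturb the turnover draws of the same run.

#' Create an independent random-number stream
#'
#' Returns a stream object holding its own generator state, initialised from
#' `seed`. Use [with_stream()] to evaluate code under the stream; the global
#' generator state is left untouched.
#'
#' @param seed Integer seed for the stream.
#' @return An environment of class `"rng_stream"`.
#' @seealso [with_stream()], [child_seed()]
#' @export
rng_stream <- function(seed) {
  stream <- new.env(parent = emptyenv())
  old <- get0(".Random.seed", envir = .GlobalEnv, inherits = FALSE)
  set.seed(as.integer(seed))
  stream$state <- get(".Random.seed", envir = .GlobalEnv, inherits = FALSE)
  if (is.null(old)) {
    rm(".Random.seed", envir = .GlobalEnv)
  } else {
    assign(".Random.seed", old, envir = .GlobalEnv)
  }
  class(stream) <- "rng_stream"
  stream
}

#' Evaluate an expression under a random-number stream
#'
#' Swaps the stream's state into the global generator, evaluates `expr`, and
#' saves the advanced state back into the stream. The caller's generator state
#' is restored on exit.
#'
#' @param stream An object from [rng_stream()].
#' @param expr Expression to evaluate.
#' @return The value of `expr`.
#' @export
with_stream <- function(stream, expr) {
  stopifnot(inherits(stream, "rng_stream"))
  old <- get0(".Random.seed", envir = .GlobalEnv, inherits = FALSE)
  assign(".Random.seed", stream$state, envir = .GlobalEnv)
  on.exit({
    stream$state <- get(".Random.seed", envir = .GlobalEnv, inherits = FALSE)
    if (is.null(old)) {
      rm(".Random.seed", envir = .GlobalEnv)
    } else {
      assign(".Random.seed", old, envir = .GlobalEnv)
    }
  })
  expr
}

#' Derive a child seed from a master seed
#'
#' Deterministic integer mixing; children for distinct (`purpose`, `index`)
#' pairs are distinct with overwhelming probability. Result is in
#' `[1, 2^31 - 2]` so it is always a valid seed.
#'
#' @param seed Master integer seed.
#' @param purpose Small integer tag for the consumer of the stream.
#' @param index Optional further index (e.g. replicate number).
#' @return An integer seed.
#' @export
child_seed <- function(seed, purpose, index = 0L) {
  m <- 2147483647  # 2^31 - 1, Mersenne prime
  x <- (as.double(seed) %% m)
  x <- (x * 48271 + as.double(purpose) * 8191 + as.double(index) * 131071 + 1) %% m
  x <- (x * 69621) %% m
  as.integer(x %% (m - 1) + 1)
}
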