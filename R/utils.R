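# Internal helpers: seed management and input checking.

#' Evaluate an expression under a temporary RNG seed
#'
#' Saves the caller's RNG state, seeds the generator, evaluates `expr`
#' and restores the previous state on exit, so package functions never
#' clobber the user's random stream.
#'
#' @param seed Integer seed.
#' @param expr Expression to evaluate.
#' @return The value of `expr`.
#' @keywords internal
with_seed <- function(seed, expr) {
  if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    stats::runif(1) # initialise RNG state so it can be saved
  }
  old <- get(".Random.seed", envir = globalenv())
  on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  set.seed(seed)
  expr
}

#' Derive a substream seed from a master seed
#'
#' Deterministic arithmetic derivation of named substream seeds so that
#' one master seed controls every stochastic step of a pipeline run.
#' Results stay below 2^31 - 1.
#'
#' @param master Integer master seed.
#' @param offset Integer substream index (>= 0).
#' @return An integer seed.
#' @export
derive_seed <- function(master, offset = 0L) {
  stopifnot(is.numeric(master), length(master) == 1L, is.finite(master),
            is.numeric(offset), length(offset) == 1L, offset >= 0)
  as.integer((abs(master) * 7919 + offset * 104729) %% 2147483647)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# stop() with sprintf formatting, never truncating the call
abort <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)
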