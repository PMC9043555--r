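#' Evaluate an expression under a temporary RNG seed
#'
#' Saves and restores `.Random.seed` so that seeded package internals never
#' leak state into (or depend on) the caller's RNG stream.
#'
#' @param seed integer seed.
#' @param expr expression to evaluate.
#' @return the value of `expr`.
#' @keywords internal
with_seed <- function(seed, expr) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}

#' Derive reproducible per-stage seeds from a master seed
#'
#' Every source of randomness in the package flows from one master seed
#' through named derived seeds, so a manifest recording the master seed
#' suffices to reproduce a run.
#'
#' @param master integer master seed.
#' @param n number of seeds to draw.
#' @param salt integer stream identifier separating stages.
#' @return integer vector of `n` seeds in `[1, 2^31 - 2]`.
#' @export
derive_seeds <- function(master, n, salt = 0L) {
  stopifnot(is.numeric(master), length(master) == 1, is.finite(master))
  stream <- (as.numeric(master) + 1013904223 * (as.numeric(salt) %% 1024)) %%
    (.Machine$integer.max - 1)
  with_seed(as.integer(stream), sample.int(.Machine$integer.max - 1L, n))
}

clip01 <- function(x) {
  d <- dim(x)
  x <- pmin(1, pmax(0, x))
  dim(x) <- d
  x
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_arg <- function(...) stop(..., call. = FALSE)
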