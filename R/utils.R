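# Seeding helpers: every stochastic operation in the package draws from a
# locally seeded RNG so results are pure functions of (inputs, seed) and the
# caller's RNG state is left untouched.

#' Evaluate an expression under a local RNG seed
#'
#' @param seed integer seed.
#' @param expr expression to evaluate.
#' @return the value of \code{expr}; the global RNG state is restored.
#' @export
withSeed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}

#' Derive a per-module seed from a global seed
#'
#' One global seed fans out into named streams (a small deterministic string
#' hash added modulo 2^31 - 1) so module-level determinism survives pipeline
#' reordering.
#'
#' @param seed global integer seed.
#' @param module stream name, e.g. "simulate" or "twsvm".
#' @return integer seed below 2^31.
#' @export
moduleSeed <- function(seed, module) {
  h <- 0
  for (ch in utf8ToInt(module)) h <- (h * 31 + ch) %% 2147483647
  as.integer((abs(as.numeric(seed)) + h) %% 2147483647)
}
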