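#' Evaluate an expression under a temporary RNG seed
#'
#' Runs `code` with the global random-number generator seeded to `seed`,
#' then restores the previous RNG state so callers see no side effect.
#'
#' @param seed Integer seed.
#' @param code Expression to evaluate.
#' @return The value of `code`.
#' @keywords internal
with_seed <- function(seed, code) {
  env <- globalenv()
  had <- exists(".Random.seed", envir = env, inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = env, inherits = FALSE)
  on.exit({
    if (had) assign(".Random.seed", old, envir = env)
    else if (exists(".Random.seed", envir = env, inherits = FALSE))
      rm(".Random.seed", envir = env)
  })
  set.seed(seed)
  code
}

#' Derive named sub-seeds from one master seed
#'
#' All randomness in the package flows from a single master seed fanned out
#' into named substreams (design, labels, patterns, noise, ...) so that any
#' one stage can be reproduced in isolation.
#'
#' @param seed Master integer seed.
#' @param names Character vector naming the substreams.
#' @return Named integer vector of sub-seeds, each < 2^31.
#' @keywords internal
derive_seeds <- function(seed, names) {
  s <- with_seed(seed, sample.int(.Machine$integer.max - 1L, length(names)))
  stats::setNames(s, names)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_submvpa <- function(...) stop(..., call. = FALSE)
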