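#' Evaluate code under a temporary RNG seed
#'
#' Runs `expr` with the global RNG seeded to `seed`, then restores the
#' caller's RNG state, so package functions never leak randomness into (or
#' out of) the session.  All stochastic operations in mrsinet draw their
#' randomness through this gate.
#'
#' @param seed integer seed (below 2^31).
#' @param expr expression to evaluate.
#' @return The value of `expr`.
#' @keywords internal
with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}

#' Derive independent child seeds from a parent seed
#'
#' Splittable-generator discipline: every nested stochastic task (a voxel, a
#' grid, a subject, a search trial) gets its own seed derived once from the
#' parent, so regenerating any component is reproducible in isolation.
#'
#' @param seed parent integer seed.
#' @param n number of child seeds.
#' @return integer vector of `n` seeds in `[1, 2^31 - 2]`.
#' @keywords internal
child_seeds <- function(seed, n) {
  with_seed(seed, sample.int(.Machine$integer.max - 1L, n, replace = FALSE))
}

stopf <- function(fmt, ..., class = "mrsinet_error") {
  stop(errorCondition(sprintf(fmt, ...), class = c(class, "error", "condition")))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
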