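#' Evaluate code under a temporary RNG seed
#'
#' Runs `code` with the global RNG seeded at `seed`, then restores the
#' caller's RNG state so library code does not disturb user-level
#' reproducibility. A `NULL` seed evaluates `code` under the current state.
#'
#' @param seed Integer seed or `NULL`.
#' @param code Expression to evaluate.
#' @return The value of `code`.
#' @keywords internal
with_seed <- function(seed, code) {
  if (is.null(seed)) {
    return(force(code))
  }
  if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    stats::runif(1L)
  }
  old <- get(".Random.seed", envir = globalenv(), inherits = FALSE)
  on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  set.seed(seed)
  code
}

#' Derive a reproducible sub-seed
#'
#' Deterministic stream-splitting: maps a master seed and a unit index to a
#' sub-seed via a Lehmer-style multiplicative hash modulo the Mersenne prime
#' 2^31 - 1, so per-subject simulations are reproducible and independent of
#' the order in which subjects are generated.
#'
#' @param master Integer master seed.
#' @param index Non-negative integer identifying the unit (subject, trial).
#' @return An integer seed in `[1, 2^31 - 2]`.
#' @keywords internal
derive_seed <- function(master, index) {
  m <- 2147483647
  h <- (as.numeric(master) %% m) * 48271 %% m
  h <- (h + (as.numeric(index) %% m) * 16807) %% m
  as.integer(h %% (m - 1) + 1)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
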