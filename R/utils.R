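#' Evaluate code with a temporary RNG seed
#'
#' Runs `code` with the RNG seeded at `seed`, then restores the caller's RNG
#' state, so generators are pure functions of their inputs and do not disturb
#' the session stream.
#'
#' @param seed integer seed.
#' @param code expression to evaluate.
#' @return the value of `code`.
#' @keywords internal
with_seed <- function(seed, code) {
  if (!is.numeric(seed) || length(seed) != 1L || is.na(seed)) {
    stop("`seed` must be a single non-missing number", call. = FALSE)
  }
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  }, add = TRUE)
  set.seed(as.integer(seed))
  force(code)
}

# derive a child seed from a base seed and a stage offset, kept in 32-bit range
child_seed <- function(seed, offset) {
  (as.integer(seed) %% 1000000L) * 1000L + as.integer(offset)
}

#' @keywords internal
is_near_constant <- function(v, tol = 1e-8) {
  v <- v[is.finite(v)]
  if (length(v) < 2L) return(TRUE)
  diff(range(v)) <= tol * (1 + max(abs(v)))
}

# stop with a consistent prefix for configuration problems
cfg_stop <- function(...) stop("configuration error: ", ..., call. = FALSE)
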