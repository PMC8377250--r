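# Internal helpers: seeding, argument checks, small shared utilities.

#' Evaluate code under a temporary RNG seed
#'
#' Sets the seed, evaluates `code`, and restores the caller's RNG state so
#' that library functions with optional `seed` arguments do not disturb the
#' global random stream. A `NULL` seed evaluates `code` under the current
#' stream.
#' @noRd
with_seed <- function(seed, code) {
  if (is.null(seed)) {
    return(force(code))
  }
  had_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had_seed) {
    old <- get(".Random.seed", envir = globalenv(), inherits = FALSE)
  }
  set.seed(seed)
  on.exit({
    if (had_seed) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  }, add = TRUE)
  force(code)
}

#' Derive a component seed from a master seed
#'
#' Each simulation component (agent, participant, blinks, renderer, ...) runs
#' on its own stream so that changing one component does not shift the draws
#' of another. Result stays inside the 32-bit integer range `set.seed()`
#' accepts.
#'
#' @param seed Master seed (integer-like scalar) or `NULL`.
#' @param k Component index (small non-negative integer).
#' @return An integer seed, or `NULL` if `seed` is `NULL`.
#' @export
derive_seed <- function(seed, k) {
  if (is.null(seed)) return(NULL)
  stopifnot(is.numeric(seed), length(seed) == 1L, is.numeric(k))
  as.integer((abs(as.double(seed)) * 7919 + 104729 * as.double(k)) %% 2147483647)
}

stop_input <- function(...) {
  stop(sprintf(...), call. = FALSE)
}

check_scalar_number <- function(x, name, lower = -Inf, upper = Inf) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x)) {
    stop_input("'%s' must be a single finite number", name)
  }
  if (x < lower || x > upper) {
    stop_input("'%s' must be in [%s, %s], got %s", name,
               format(lower), format(upper), format(x))
  }
  invisible(x)
}

check_probability <- function(x, name) check_scalar_number(x, name, 0, 1)

# round to integer milliseconds, never below 1 ms
round_ms <- function(x) pmax(1, round(x))
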