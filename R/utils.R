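# Internal helpers shared across modules.

# Evaluate `expr` under a fixed RNG seed without disturbing the caller's
# RNG stream. All stochastic operations in the package go through this so
# that a session is a pure function of its config.
with_local_seed <- function(seed, expr) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      get(".Random.seed", envir = globalenv())
    } else {
      NULL
    }
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
  }
  force(expr)
}

# Derive a stream-specific 31-bit seed from a master seed, so independent
# components (sub-trains, regions, noise) never share a stream.
derive_seed <- function(seed, stream) {
  (as.double(seed) * 48271 + as.double(stream) * 16807) %% 2147483647
}

#' Wrap angles to the interval (-pi, pi]
#'
#' The package-wide phase convention: a unique representative for every
#' angle, with +pi mapping to itself (and -pi to +pi).
#'
#' @param x numeric vector of angles in radians.
#' @return numeric vector of the same length, in (-pi, pi].
#' @examples
#' wrap_phase(c(0, pi, -pi, 3 * pi / 2))
#' @export
wrap_phase <- function(x) {
  out <- x - 2 * pi * ceiling((x - pi) / (2 * pi))
  # ceiling() maps exact multiples so that -pi -> pi and pi -> pi
  out
}

stopifnot_scalar_number <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x)) {
    abort(sprintf("`%s` must be a single finite number.", name))
  }
}
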