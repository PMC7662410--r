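# Internal helpers shared across modules.

#' Derive a deterministic child seed from a master seed
#'
#' Used so that one master seed drives independent substreams (one per
#' generated signal / resampling stage) without the streams overlapping.
#' Result always fits in a 32-bit signed integer.
#'
#' @param seed master seed (integer).
#' @param offset substream index (non-negative integer).
#' @return an integer seed.
#' @keywords internal
derive_seed <- function(seed, offset = 0L) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  # Knuth-style multiplicative hash, folded into [0, 2^31 - 1)
  x <- (abs(as.double(seed)) %% 2^31) + 1
  h <- (x * 2654435761 + as.double(offset) * 97531) %% (2^31 - 1)
  as.integer(floor(h))
}

# Evaluate `code` under a fixed RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, code) {
  if (!is.null(seed)) {
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
    })
    set.seed(as.integer(seed))
  }
  force(code)
}

stop_anspm <- function(..., class) {
  stop(structure(
    class = c(class, "anspm_error", "error", "condition"),
    list(message = paste0(...), call = sys.call(-1))
  ))
}

assert_scalar_number <- function(x, name, lower = -Inf, upper = Inf,
                                 strict_lower = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x)) {
    stop_anspm(name, " must be a single finite number", class = "anspm_invalid_argument")
  }
  if (strict_lower && x <= lower) {
    stop_anspm(name, " must be > ", lower, class = "anspm_invalid_argument")
  }
  if (!strict_lower && x < lower) {
    stop_anspm(name, " must be >= ", lower, class = "anspm_invalid_argument")
  }
  if (x > upper) {
    stop_anspm(name, " must be <= ", upper, class = "anspm_invalid_argument")
  }
  invisible(x)
}
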