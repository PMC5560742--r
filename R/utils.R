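# Internal helpers shared across modules.

#' Evaluate code under a temporary RNG state
#'
#' Seeds the R RNG, runs `code`, and restores the previous RNG state so that
#' seeded simulation helpers never disturb the caller's random stream.
#'
#' @param seed Integer seed (< 2^31).
#' @param code Expression to evaluate.
#' @return The value of `code`.
#' @keywords internal
with_seed <- function(seed, code) {
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
  code
}

# Derive a stream-specific child seed from a master seed, kept inside the
# 32-bit signed integer range.
derive_seed <- function(seed, stream) {
  (as.numeric(seed) * 1009 + stream * 7919) %% 2147483647
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

# The four decoding states, in the fixed order used by every transition matrix.
STATE_LEVELS <- c("F", "B", "C", "N")
CATEGORY_LEVELS <- c("F", "B", "C")
PERSPECTIVE_LEVELS <- c("left60", "front", "right60")
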