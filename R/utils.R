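# Internal helpers shared across modules.

# Evaluate `code` under a fixed RNG seed without disturbing the caller's
# RNG state. `seed = NULL` leaves the RNG alone.
with_seed <- function(seed, code) {
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
    })
    set.seed(as.integer(seed))
  }
  force(code)
}

stopf <- function(...) stop(sprintf(...), call. = FALSE)

warnf <- function(...) warning(sprintf(...), call. = FALSE)

is_number <- function(x) is.numeric(x) && length(x) == 1L && is.finite(x)

#' Derive a per-stage child seed from a global seed
#'
#' Deterministic fan-out rule (`(seed mod 2e7) * 100 + stage`) so each
#' pipeline stage can be rerun in isolation with reproducible randomness.
#' Results stay well below the 32-bit integer limit for the small global
#' seeds used throughout.
#'
#' @param seed global integer seed (`NULL` passes through).
#' @param stage integer stage index.
#' @return integer child seed.
#' @export
stage_seed <- function(seed, stage) {
  if (is.null(seed)) return(NULL)
  (as.integer(seed) %% 20000000L) * 100L + as.integer(stage)
}
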