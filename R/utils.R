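# Internal helpers: seeded evaluation and seed derivation.

#' Evaluate code under a fixed RNG seed, restoring the caller's RNG state
#'
#' @param seed integer seed.
#' @param code expression to evaluate.
#' @return the value of `code`.
#' @keywords internal
#' @noRd
with_seed <- function(seed, code) {
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
  set.seed(seed)
  code
}

#' Derive a reproducible sub-seed from a master seed
#'
#' A Lehmer-style step keeps derived seeds inside the 32-bit integer range
#' so any single stage of a seeded experiment can be replayed in isolation.
#'
#' @param seed master integer seed.
#' @param index non-negative integer stream index (a stage or bootstrap id).
#' @return an integer in `[1, 2^31 - 2]`.
#' @export
derive_seed <- function(seed, index = 0L) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed),
            is.numeric(index), length(index) == 1L, index >= 0)
  m <- 2147483647 # 2^31 - 1, prime
  s <- (abs(as.numeric(seed)) %% m)
  for (i in seq_len(index + 1L)) {
    s <- (48271 * s + 11) %% m
  }
  as.integer(max(1, s))
}

stop_txa <- function(...) stop(..., call. = FALSE)

is_count <- function(x) {
  is.numeric(x) && length(x) == 1L && is.finite(x) && x == round(x)
}
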