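## Internal helpers shared across modules.

#' Evaluate an expression under a fixed RNG seed
#'
#' All randomized operations in the package take explicit `seed` arguments;
#' none touch the caller's global RNG state. This helper saves and restores
#' `.Random.seed` around a seeded evaluation.
#'
#' @param seed integer seed.
#' @param code expression to evaluate.
#' @return the value of `code`.
#' @keywords internal
#' @noRd
with_seed <- function(seed, code) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (has_old) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  }, add = TRUE)
  set.seed(as.integer(seed))
  force(code)
}

## Derive a stream-specific child seed from a user seed. Kept below 2^31.
derive_seed <- function(seed, stream) {
  (as.double(seed) * 1000003 + stream) %% 2147483647
}

dp_log <- function(fmt, ..., level = "INFO") {
  message(sprintf("[%s] %s", level, sprintf(fmt, ...)))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

## Deterministic score ordering: descending score, ties by ascending gene id.
order_scores <- function(gene, score) {
  order(-score, gene, method = "radix")
}
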