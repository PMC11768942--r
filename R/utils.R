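# Internal helpers: seeded evaluation and seed derivation.

#' Evaluate an expression under a temporary RNG seed
#'
#' Saves and restores `.Random.seed` so that seeded generators do not disturb
#' the caller's random stream. A `NULL` seed evaluates the expression with the
#' current stream untouched.
#'
#' @param seed integer seed or `NULL`.
#' @param code expression to evaluate.
#' @return the value of `code`.
#' @keywords internal
#' @noRd
with_seed <- function(seed, code) {
  if (is.null(seed)) {
    return(force(code))
  }
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

#' Derive a per-trial seed from a master seed and integer stream labels
#'
#' Deterministic multiplicative mixing so that every (condition, trial,
#' stream) tuple draws from an independent, individually reproducible
#' substream. Result always lies in [1, 2^31 - 2].
#'
#' @param master integer master seed.
#' @param ... integer labels (condition index, trial index, stream id, ...).
#' @return a single integer seed.
#' @export
derive_seed <- function(master, ...) {
  ids <- as.double(c(master, ...))
  if (any(!is.finite(ids))) stop("seed labels must be finite numbers")
  m <- 2147483647 # 2^31 - 1, prime
  h <- 104729
  for (v in ids) {
    # all intermediates stay below 2^53, exact in doubles
    h <- (h * 48271 + (abs(v) %% m) + 1) %% m
    h <- (h * 16807) %% m
  }
  as.integer(h %% (m - 1) + 1)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_if_not_number <- function(x, name, positive = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x)) {
    stop(sprintf("`%s` must be a single finite number", name), call. = FALSE)
  }
  if (positive && x <= 0) {
    stop(sprintf("`%s` must be positive", name), call. = FALSE)
  }
  invisible(x)
}
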