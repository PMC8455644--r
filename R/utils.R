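#' @keywords internal
`%||%` <- function(a, b) if (is.null(a)) b else a

## stop() with a consistent error class so callers/tests can distinguish
## user errors from genuine failures
abort_invalid <- function(...) {
  stop(errorCondition(paste0(...), class = c("forestcndd_invalid", "error")))
}

abort_degenerate <- function(...) {
  stop(errorCondition(paste0(...), class = c("forestcndd_degenerate", "error")))
}

check_number <- function(x, name, lower = -Inf, upper = Inf,
                         strict_lower = FALSE, strict_upper = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x))
    abort_invalid(name, " must be a single finite number")
  if (strict_lower && x <= lower)
    abort_invalid(name, " must be > ", lower)
  if (!strict_lower && x < lower)
    abort_invalid(name, " must be >= ", lower)
  if (strict_upper && x >= upper)
    abort_invalid(name, " must be < ", upper)
  if (!strict_upper && x > upper)
    abort_invalid(name, " must be <= ", upper)
  invisible(x)
}

#' Derive a reproducible sub-seed from a master seed
#'
#' Counter-based mixing so that per-(stage, plot, species, replicate)
#' streams are identical whether stages run serially or independently.
#' Always returns an integer in `[1, 2^31 - 2]`.
#'
#' @param seed master seed (single integer).
#' @param ... further integer counters identifying the stream.
#' @return a single integer usable with [set.seed()].
#' @export
derive_seed <- function(seed, ...) {
  m <- 2147483647  # 2^31 - 1, Lehmer modulus
  h <- (abs(as.numeric(seed)) %% m)
  for (k in c(...)) {
    h <- (h * 48271 + abs(as.numeric(k)) + 1) %% m
  }
  as.integer(h %% (m - 2) + 1)
}

## run expr with a local RNG state when seed is non-NULL
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(
      rm(".Random.seed", envir = globalenv())), add = TRUE)
  }
  set.seed(seed)
  expr
}
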