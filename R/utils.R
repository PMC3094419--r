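#' @keywords internal
"_PACKAGE"

`%||%` <- function(a, b) if (is.null(a)) b else a

clamp <- function(x, lo = -Inf, hi = Inf) pmin(pmax(x, lo), hi)

#' Derive a stage seed from a master seed
#'
#' Deterministic integer hash used so that every pipeline stage gets its own
#' reproducible RNG stream from one master seed. Results stay below 2^31.
#'
#' @param seed master seed (integer).
#' @param offset stage offset (integer).
#' @return an integer seed.
#' @export
derive_seed <- function(seed, offset = 0L) {
  as.integer((as.numeric(seed) * 1009 + as.numeric(offset) * 7919) %% 2147483587 + 1)
}

with_seed <- function(seed, expr) {
  if (!is.null(seed)) set.seed(seed)
  expr
}

stop_config <- function(...) stop(sprintf(...), call. = FALSE)

is_count <- function(x) length(x) == 1L && is.finite(x) && x == round(x) && x >= 0
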