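# Internal helpers shared across modules.

#' Evaluate an expression under a temporary RNG state
#'
#' Seeds the generator, runs `expr`, and restores the caller's RNG state so
#' seeded simulation calls never perturb the global stream.
#'
#' @param seed integer seed, or NULL to use the current stream.
#' @param expr expression to evaluate.
#' @return the value of `expr`.
#' @keywords internal
#' @noRd
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
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
  expr
}

# Deterministic sub-seed derivation: mixes a base seed with stream labels so
# per-round / per-target draws are independent yet reproducible. Stays within
# the 32-bit signed integer range R requires of set.seed().
derive_seed <- function(seed, ...) {
  labels <- paste(c(seed, ...), collapse = "/")
  bytes <- utf8ToInt(labels)
  h <- 0
  for (b in bytes) h <- (h * 31 + b) %% 2147483647
  as.integer(h)
}

# Consistent error classes so callers can distinguish bad configuration from
# bad data.
abort_config <- function(msg) {
  stop(errorCondition(msg, class = c("proximap_config_error", "error")))
}

abort_lookup <- function(msg) {
  stop(errorCondition(msg, class = c("proximap_lookup_error", "error")))
}

abort_data <- function(msg) {
  stop(errorCondition(msg, class = c("proximap_data_error", "error")))
}

check_scalar <- function(x, name, min = -Inf, max = Inf, allow_zero = TRUE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x)) {
    abort_config(sprintf("'%s' must be a single finite number", name))
  }
  if (x < min || x > max || (!allow_zero && x == 0)) {
    abort_config(sprintf("'%s' = %g outside allowed range [%g, %g]",
                         name, x, min, max))
  }
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
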