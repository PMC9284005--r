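# internal helpers shared across modules

#' Evaluate an expression under a private RNG state
#'
#' Saves and restores `.Random.seed` so that package internals never disturb
#' the caller's random stream, then seeds with `seed`.
#' @noRd
with_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())), add = TRUE)
  }
  set.seed(as.integer(seed))
  expr
}

#' @noRd
stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

#' @noRd
assert_scalar_number <- function(x, name, min = -Inf) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x))
    stopf("'%s' must be a finite numeric scalar", name)
  if (x < min) stopf("'%s' must be >= %s (got %s)", name, min, x)
  invisible(x)
}

# derive a stream of child seeds (< 2^31) from one master seed
#' @noRd
derive_seeds <- function(seed, n) {
  with_seed(seed, sample.int(.Machine$integer.max - 1L, n))
}

#' @noRd
match_movement_label <- function(label) {
  match.arg(label, MOVEMENT_CLASSES)
}
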