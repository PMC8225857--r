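## Internal helpers: seeding, input checking, small numerics.

#' Evaluate an expression under a temporary RNG state
#'
#' Saves the caller's RNG state, seeds with `seed`, evaluates `expr`, and
#' restores the previous state, so that seeded package routines never disturb
#' the user's random number stream.
#'
#' @param seed integer scalar or `NULL` (evaluate without reseeding).
#' @param expr expression to evaluate.
#' @return the value of `expr`.
#' @keywords internal
#' @noRd
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    set.seed(NULL)  # initialise
  }
  old <- get(".Random.seed", envir = globalenv())
  on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  set.seed(as.integer(seed))
  expr
}

#' Derive a child seed from a master seed and a stream label
#'
#' Stable string-hash mixing so each output stream (file role, bootstrap
#' replicate, ...) gets an independent, reproducible seed below 2^31.
#'
#' @keywords internal
#' @noRd
child_seed <- function(seed, role) {
  h <- as.double(seed %% 2147483647L)
  for (cp in utf8ToInt(as.character(role))) {
    h <- (h * 31 + cp) %% 2147483647
  }
  as.integer(h)
}

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)
warnf <- function(fmt, ...) warning(sprintf(fmt, ...), call. = FALSE)

assert_scalar_int <- function(x, name, lower = -Inf) {
  if (length(x) != 1L || !is.numeric(x) || is.na(x) || x != floor(x))
    stopf("`%s` must be a single integer", name)
  if (x < lower) stopf("`%s` must be >= %s", name, format(lower))
  invisible(as.integer(x))
}

## log C(a, b) that is -Inf outside the support, vectorised, real-valued a, b
lchoose_safe <- function(a, b) {
  out <- suppressWarnings(lchoose(a, b))
  out[b > a | b < 0] <- -Inf
  out
}

## Benjamini-Hochberg step-up adjustment, written out explicitly (the
## package's own implementation; validated against stats::p.adjust in tests).
bh_adjust <- function(p) {
  m <- length(p)
  if (m == 0L) return(numeric(0))
  o <- order(p, decreasing = TRUE)
  ro <- order(o)
  adj <- pmin(1, cummin(m / (m:1) * p[o]))[ro]
  adj
}
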