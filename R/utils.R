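# Internal helpers shared across modules.

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Evaluate an expression under a temporary RNG seed
#'
#' Saves and restores `.Random.seed` so generators are pure functions of
#' their arguments and never disturb the caller's RNG stream.
#'
#' @param seed integer seed.
#' @param expr expression to evaluate.
#' @return the value of `expr`.
#' @keywords internal
#' @noRd
with_seed <- function(seed, expr) {
  if (!is.numeric(seed) || length(seed) != 1L || !is.finite(seed))
    stop("`seed` must be a single finite number", call. = FALSE)
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  }, add = TRUE)
  set.seed(as.integer(seed))
  expr
}

stopifnot_scalar_number <- function(x, name, finite = TRUE) {
  if (!is.numeric(x) || length(x) != 1L || (finite && !is.finite(x)))
    stop(sprintf("`%s` must be a single finite number", name), call. = FALSE)
  invisible(x)
}

stopifnot_count <- function(x, name, min = 1L) {
  stopifnot_scalar_number(x, name)
  if (x < min || x != as.integer(x))
    stop(sprintf("`%s` must be an integer >= %d", name, min), call. = FALSE)
  invisible(as.integer(x))
}

# Deterministic numeric formatting for TSV output: 10 significant digits,
# NA rendered as the literal "NA".
format_num <- function(x) {
  out <- formatC(x, digits = 10L, format = "g")
  out[is.na(x)] <- "NA"
  out
}
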