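# Internal helpers shared across modules.

#' Evaluate an expression under a temporary RNG state
#'
#' Seeds the generator locally and restores the caller's RNG state on exit,
#' so seeded generators do not disturb the session RNG stream.
#'
#' @param seed integer seed, or NULL to use the current stream.
#' @param expr expression to evaluate.
#' @return the value of `expr`.
#' @keywords internal
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    set.seed(NULL)
  }
  old <- get(".Random.seed", envir = globalenv())
  on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  set.seed(as.integer(seed))
  expr
}

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

warnf <- function(fmt, ...) warning(sprintf(fmt, ...), call. = FALSE)

is_count <- function(x) {
  length(x) == 1L && is.numeric(x) && is.finite(x) && x == as.integer(x) && x >= 1
}

# strictly increasing, equally spaced to float tolerance
check_wavelength_grid <- function(w, what = "wavelengths_nm") {
  if (length(w) < 2L) stopf("%s must have at least 2 channels", what)
  d <- diff(w)
  if (any(d <= 0)) stopf("%s must be strictly increasing", what)
  invisible(w)
}
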