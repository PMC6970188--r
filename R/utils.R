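#' Evaluate an expression under a temporary RNG seed
#'
#' Runs `code` with the global random-number stream set to `seed`, then
#' restores the previous stream so that seeded helpers do not perturb the
#' caller's randomness.
#'
#' @param seed integer seed.
#' @param code expression to evaluate.
#' @return The value of `code`.
#' @keywords internal
with_seed <- function(seed, code) {
  if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    stats::runif(1L)
  }
  old <- get(".Random.seed", envir = globalenv(), inherits = FALSE)
  on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  set.seed(as.integer(seed))
  force(code)
}

`%||%` <- function(x, y) if (is.null(x)) y else x

stop_ <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

#' @keywords internal
is_count <- function(x, min = 1) {
  length(x) == 1L && is.numeric(x) && !is.na(x) && x >= min && x == floor(x)
}
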