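# Internal helpers shared across modules.

#' Evaluate code with a temporarily seeded RNG
#'
#' Sets the RNG seed, runs `code`, and restores the caller's RNG state so that
#' seeded operations never perturb the global random stream.
#'
#' @param seed Integer seed, or `NULL` to use the current RNG state.
#' @param code Expression to evaluate.
#' @keywords internal
#' @noRd
with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE)) runif(1)
  old <- get(".Random.seed", envir = globalenv())
  on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  set.seed(as.integer(seed))
  force(code)
}

`%||%` <- function(x, y) if (is.null(x)) y else x

# stderr logging used by the I/O and pipeline layers
log_msg <- function(...) message(sprintf(...))

stopf <- function(...) stop(sprintf(...), call. = FALSE)
warnf <- function(...) warning(sprintf(...), call. = FALSE)

is_count <- function(x) is.numeric(x) && length(x) == 1L && !is.na(x) && x >= 0 && x == round(x)

# column standard deviations without the matrixStats dependency
col_sds <- function(m) apply(m, 2L, stats::sd)
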