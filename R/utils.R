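`%||%` <- function(a, b) if (is.null(a)) b else a

#' Evaluate an expression with a temporary RNG seed
#'
#' Sets the seed for the duration of `code` and restores the caller's RNG
#' state afterwards, so seeded package functions do not disturb the global
#' random stream. A `NULL` seed evaluates `code` with the current state.
#'
#' @param seed Integer seed or `NULL`.
#' @param code Expression to evaluate.
#' @return The value of `code`.
#' @keywords internal
with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    stats::runif(1L)
  }
  old <- get(".Random.seed", envir = globalenv(), inherits = FALSE)
  on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  set.seed(as.integer(seed))
  force(code)
}

# deterministic per-stage child seeds derived from one run seed
stage_seed <- function(seed, stage_index) {
  as.integer(seed) + 97L * as.integer(stage_index)
}

stop_lipidcap <- function(fmt, ...) {
  stop(sprintf(fmt, ...), call. = FALSE)
}
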