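# Internal helpers: typed error conditions and seeded evaluation.

bl_error <- function(id, msg, ...) {
  stop(errorCondition(sprintf(msg, ...), class = c(id, "bl_error")))
}

bl_warn <- function(msg, ...) warning(sprintf(msg, ...), call. = FALSE)

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Evaluate an expression under a local RNG seed
#'
#' Sets the seed for the duration of `code` and restores the caller's RNG
#' state afterwards, so seeded operations do not perturb the global stream.
#' With `seed = NULL` the expression runs on the current stream.
#'
#' @param seed integer seed or `NULL`.
#' @param code expression to evaluate.
#' @return The value of `code`.
#' @export
with_seed <- function(seed, code) {
  if (is.null(seed)) return(code)
  if (!is.numeric(seed) || length(seed) != 1 || !is.finite(seed))
    bl_error("bad_seed", "seed must be a single finite number")
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(as.integer(seed))
  code
}

# Deterministic significant-digit formatting used by all table writers.
format_num <- function(x, digits = 12L) {
  out <- vapply(x, function(v) {
    if (is.na(v)) return("NA")
    if (is.character(v)) return(v)
    if (is.logical(v)) return(if (v) "TRUE" else "FALSE")
    sprintf(paste0("%.", digits, "g"), v)
  }, character(1))
  out
}
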