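# internal helpers shared across modules

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Evaluate an expression under a temporary RNG seed
#'
#' Saves and restores `.Random.seed` so seeded package operations do not
#' disturb the caller's random-number stream. A `NULL` seed evaluates the
#' expression under the current stream.
#' @noRd
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  if (!is.numeric(seed) || length(seed) != 1L || !is.finite(seed)) {
    stop("`seed` must be a single finite number", call. = FALSE)
  }
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_seed) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  expr
}

stop_validation <- function(...) {
  stop(errorCondition(paste0(...), class = c("spautolog_validation_error", "error")))
}

check_binary <- function(y, what = "outcome") {
  if (anyNA(y)) stop_validation(what, " contains missing values")
  if (!is.numeric(y) || !all(y %in% c(0, 1))) {
    stop_validation(what, " must be a numeric vector of 0/1 values")
  }
  invisible(y)
}
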