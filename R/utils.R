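## Internal helpers shared across modules.

#' Evaluate an expression under a temporary RNG seed
#'
#' The global RNG state is saved, the seed set, the expression evaluated,
#' and the previous state restored, so simulation functions never leak
#' random state into the caller's session.
#'
#' @param seed single integer seed.
#' @param expr expression to evaluate.
#' @noRd
withSeed <- function(seed, expr) {
  if (!is.numeric(seed) || length(seed) != 1L || !is.finite(seed)) {
    stop("'seed' must be a single finite number", call. = FALSE)
  }
  hadSeed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (hadSeed) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      },
      add = TRUE
    )
  }
  set.seed(as.integer(seed))
  expr
}

## Validate a survival time / event pair; returns event as integer 0/1.
checkSurvival <- function(time, event) {
  if (length(time) != length(event)) {
    stop("'time' and 'event' must have the same length", call. = FALSE)
  }
  if (length(time) < 1L) stop("need at least one subject", call. = FALSE)
  if (anyNA(time) || anyNA(event)) {
    stop("'time' and 'event' must not contain missing values", call. = FALSE)
  }
  if (any(time < 0)) stop("survival times must be >= 0", call. = FALSE)
  if (!all(event %in% c(0, 1))) {
    stop("'event' must contain only 0 (censored) and 1 (event)", call. = FALSE)
  }
  as.integer(event)
}

checkScalarCount <- function(x, name, min = 1L) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x) || x < min ||
      x != round(x)) {
    stop(sprintf("'%s' must be a single integer >= %d", name, min),
         call. = FALSE)
  }
  as.integer(x)
}
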