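`%||%` <- function(a, b) if (is.null(a)) b else a

#' Evaluate an expression with a temporary RNG seed
#'
#' Saves and restores `.Random.seed` so that seeded internals (fold
#' assignment, weight initialisation, the mock embedder basis) do not
#' disturb the caller's random stream.
#'
#' @param seed integer seed.
#' @param expr expression to evaluate.
#' @return The value of `expr`.
#' @keywords internal
with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  eval.parent(substitute(expr))
}

stop_deamid <- function(..., class = character()) {
  stop(structure(class = unique(c(class, "deamid_error", "error", "condition")),
                 list(message = paste0(...), call = sys.call(-1))))
}

assert_that <- function(ok, ...) if (!isTRUE(ok)) stop_deamid(...)
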