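# internal helpers

#' Evaluate an expression with a temporary RNG state
#'
#' Runs `expr` after `set.seed(seed)` and restores the caller's RNG state on
#' exit, so generators are deterministic without clobbering the session RNG.
#'
#' @param seed integer seed.
#' @param expr expression to evaluate.
#' @keywords internal
with_seed <- function(seed, expr) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) {
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
  set.seed(seed)
  expr
}

vnorm <- function(v) sqrt(sum(v^2))

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_ <- function(..., class) {
  stop(structure(
    class = c(class, "lptcmorph_error", "error", "condition"),
    list(message = paste0(...), call = sys.call(-1))
  ))
}
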