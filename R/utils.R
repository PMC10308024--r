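#' @useDynLib hippseg, .registration = TRUE
#' @importFrom Rcpp evalCpp
#' @importFrom stats rnorm runif optim lm AIC coef predict pf p.adjust
#'   quantile sd approx spline setNames
#' @importFrom utils head tail write.csv read.csv
NULL

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Evaluate an expression under a local RNG seed
#'
#' Saves and restores the global `.Random.seed`, so generators behave as pure
#' functions of their seed and never leak RNG state.
#'
#' @param seed integer seed.
#' @param expr expression to evaluate.
#' @return value of `expr`.
#' @keywords internal
with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}

stopf <- function(...) stop(sprintf(...), call. = FALSE)

assert_that <- function(cond, ...) if (!isTRUE(cond)) stopf(...)
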