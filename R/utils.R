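#' @importFrom rlang abort warn .data
#' @importFrom tibble tibble as_tibble
#' @import dplyr
#' @importFrom tidyr pivot_longer pivot_wider
#' @importFrom purrr map map_dbl map_chr map2 imap pmap
#' @importFrom stats setNames runif
#' @importFrom Rcpp evalCpp
#' @useDynLib gatingflux, .registration = TRUE
NULL

# Evaluate `expr` under a fixed RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, expr) {
  if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    set.seed(NULL)
  }
  old <- get(".Random.seed", envir = globalenv())
  on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  set.seed(seed)
  eval.parent(substitute(expr))
}

log_uniform <- function(n, range) {
  exp(runif(n, log(range[1]), log(range[2])))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
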