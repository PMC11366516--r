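#' @importFrom rlang abort warn .data
#' @importFrom tibble tibble as_tibble
#' @importFrom stats var cor sd rnorm runif rbinom setNames model.matrix
#' @importFrom methods is as
#' @importFrom Matrix sparseMatrix Diagonal crossprod tcrossprod t diag solve
NULL

`%||%` <- function(x, y) if (is.null(x)) y else x

# population variance (denominator n); the scan statistic uses this by default
var_pop <- function(x) {
  m <- mean(x)
  mean((x - m)^2)
}

assert_that <- function(cond, msg) {
  if (!isTRUE(cond)) abort(msg)
}

# symmetrize a numerically near-symmetric matrix
symmetrize <- function(M) (M + t(M)) / 2
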