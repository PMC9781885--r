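#' @importFrom stats quantile sd rnorm runif rpois qnorm pnorm median prcomp rbinom
#' @importFrom utils read.csv write.csv head tail
#' @import data.table
NULL

`%||%` <- function(a, b) if (is.null(a)) b else a

abort <- function(fmt, ..., class = "mpezones_error") {
  stop(errorCondition(sprintf(fmt, ...), class = c(class, "error", "condition")))
}

#' Evaluate an expression with a temporary RNG seed
#'
#' Saves and restores \code{.Random.seed} so package functions are
#' deterministic under an explicit seed without disturbing the caller's
#' RNG stream.
#'
#' @param seed integer seed, or NULL to use the current stream.
#' @param expr expression to evaluate.
#' @return the value of \code{expr}.
#' @keywords internal
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}

## derive a child seed from a master seed; kept below 2^31 - 1
derive_seed <- function(seed, i) {
  as.integer((as.double(seed) * 48271 + i * 16807) %% 2147483587L)
}

#' Adjusted Rand index between two partitions
#'
#' Chance-corrected agreement between two labelings of the same items.
#' Used to score recovery of simulated intensity regimes by the clustering
#' pipeline; 1 is perfect agreement, 0 is chance level.
#'
#' @param a,b vectors of equal length; any label type.
#' @return numeric scalar in [-1, 1].
#' @export
#' @examples
#' adjusted_rand_index(c(1, 1, 2, 2), c("x", "x", "y", "y")) # 1
adjusted_rand_index <- function(a, b) {
  if (length(a) != length(b)) abort("partitions have different lengths (%d vs %d)",
                                    length(a), length(b))
  tab <- table(a, b)
  n <- sum(tab)
  comb2 <- function(x) x * (x - 1) / 2
  sum_ij <- sum(comb2(tab))
  sum_a <- sum(comb2(rowSums(tab)))
  sum_b <- sum(comb2(colSums(tab)))
  expected <- sum_a * sum_b / comb2(n)
  max_idx <- (sum_a + sum_b) / 2
  if (max_idx == expected) return(1)
  (sum_ij - expected) / (max_idx - expected)
}

## population (divide-by-n) standard deviation
pop_sd <- function(x) sqrt(mean((x - mean(x))^2))
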