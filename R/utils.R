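#' Evaluate an expression under a temporary RNG seed
#'
#' Saves the caller's RNG state, seeds it with `seed`, evaluates `expr`
#' and restores the state on exit, so seeded package functions never
#' disturb the session stream.
#'
#' @param seed single integer seed.
#' @param expr expression to evaluate.
#' @return the value of `expr`.
#' @keywords internal
#' @noRd
with_seed <- function(seed, expr) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else {
    NULL
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  expr
}

#' Adjusted Rand index between two partitions
#'
#' Pair-counting agreement between two labelings of the same items,
#' corrected for chance; 1 for identical partitions (up to relabeling),
#' about 0 for independent ones. Used to score recovery of the
#' generating regimes by the fitted clusters.
#'
#' @param a,b label vectors of equal length (any atomic type).
#' @return a single number in \[-1, 1\].
#' @examples
#' adjusted_rand_index(c(1, 1, 2, 2), c("x", "x", "y", "y"))  # 1
#' @export
adjusted_rand_index <- function(a, b) {
  stopifnot(length(a) == length(b), length(a) >= 2L)
  tab <- table(a, b)
  n <- sum(tab)
  choose2 <- function(x) x * (x - 1) / 2
  sum_ij <- sum(choose2(tab))
  sum_i <- sum(choose2(rowSums(tab)))
  sum_j <- sum(choose2(colSums(tab)))
  expected <- sum_i * sum_j / choose2(n)
  max_index <- (sum_i + sum_j) / 2
  if (abs(max_index - expected) < .Machine$double.eps^0.5) {
    return(1)  # both partitions trivial (all-one-cluster or all-singletons agree)
  }
  (sum_ij - expected) / (max_index - expected)
}

# stop() with a consistent prefix and no call echo
abort <- function(...) stop(..., call. = FALSE)
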