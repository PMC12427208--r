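#' @keywords internal
"_PACKAGE"

stopf <- function(...) stop(sprintf(...), call. = FALSE)
warnf <- function(...) warning(sprintf(...), call. = FALSE)

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Evaluate an expression with a temporary RNG seed
#'
#' All stochastic operations in the package route their randomness through
#' this helper so that a single integer seed fully determines the output and
#' the caller's RNG state is left untouched (no global side effects).
#'
#' @param seed Integer seed.
#' @param code Expression to evaluate.
#' @return The value of `code`.
#' @keywords internal
with_seed <- function(seed, code) {
  if (!is.numeric(seed) || length(seed) != 1L || is.na(seed)) {
    stopf("seed must be a single integer")
  }
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (has_old) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  force(code)
}

#' Adjusted Rand index between two partitions
#'
#' Pair-counting agreement between two labelings of the same items,
#' corrected for chance. 1 means identical partitions (up to relabeling),
#' around 0 means chance-level agreement.
#'
#' @param x,y Vectors of cluster labels of equal length.
#' @return A single number in (-1, 1].
#' @export
adjusted_rand_index <- function(x, y) {
  if (length(x) != length(y)) stopf("label vectors must have equal length")
  tab <- table(x, y)
  n <- sum(tab)
  sum_ij <- sum(choose(tab, 2))
  a <- sum(choose(rowSums(tab), 2))
  b <- sum(choose(colSums(tab), 2))
  expected <- a * b / choose(n, 2)
  max_index <- (a + b) / 2
  if (max_index == expected) return(1)
  (sum_ij - expected) / (max_index - expected)
}

## round-trip-stable numeric formatting used by all table writers
fmt_signif <- function(x, digits = 10L) {
  if (is.numeric(x)) signif(x, digits) else x
}
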