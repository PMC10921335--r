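#' @importFrom rlang abort warn %||%
#' @importFrom tibble tibble as_tibble
#' @import dplyr
#' @importFrom purrr map map_chr map_dbl map_int map2
NULL

# row-wise softmax with max-shift; x is a matrix
softmax_rows <- function(x) {
  m <- apply(x, 1L, max)
  e <- exp(x - m)
  e / rowSums(e)
}

log_sum_exp_rows <- function(x) {
  m <- apply(x, 1L, max)
  m + log(rowSums(exp(x - m)))
}

# cosine of each row of m against vector v (zero-safe: zero rows get cosine 0)
cosine_to <- function(m, v) {
  nv <- sqrt(sum(v^2))
  nm <- sqrt(rowSums(m^2))
  s <- as.vector(m %*% v)
  out <- numeric(length(s))
  ok <- nm > 0 & nv > 0
  out[ok] <- s[ok] / (nm[ok] * nv)
  out
}

l2_normalize_rows <- function(m) {
  n <- sqrt(rowSums(m^2))
  n[n == 0] <- 1
  m / n
}

# derive a child seed from a base seed; keeps results in 32-bit integer range
derive_seed <- function(seed, offset) {
  as.integer((as.numeric(seed) * 7919 + offset * 104729) %% 2147483647L)
}

#' Adjusted Rand index between two partitions
#'
#' Chance-corrected agreement between a clustering and a reference
#' partition, used to score recovery of planted clusters on synthetic
#' corpora. 1 means identical partitions (up to relabelling), 0 is the
#' expected value for independent random partitions.
#'
#' @param a,b Vectors of cluster labels of equal length (any atomic type).
#' @return A single number in \[-1, 1\].
#' @examples
#' adjusted_rand_index(c(1, 1, 2, 2), c("a", "a", "b", "b"))
#' @export
adjusted_rand_index <- function(a, b) {
  if (length(a) != length(b)) abort("partitions must have equal length")
  tab <- table(a, b)
  n <- length(a)
  comb2 <- function(x) x * (x - 1) / 2
  sum_ij <- sum(comb2(tab))
  sum_a <- sum(comb2(rowSums(tab)))
  sum_b <- sum(comb2(colSums(tab)))
  expected <- sum_a * sum_b / comb2(n)
  max_index <- (sum_a + sum_b) / 2
  if (max_index == expected) return(1)
  (sum_ij - expected) / (max_index - expected)
}
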