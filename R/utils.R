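#' Adjusted Rand Index between two partitions
#'
#' Chance-corrected agreement between two labelings of the same items;
#' 1 for identical partitions (up to label names), ~0 for independent ones.
#' Used to score recovery of planted guild structure.
#'
#' @param a,b label vectors of equal length.
#' @return numeric ARI.
#' @export
adjusted_rand_index <- function(a, b) {
  if (length(a) != length(b)) stop("a and b must have equal length")
  tab <- table(a, b)
  n <- length(a)
  sum_ij <- sum(choose(tab, 2))
  sum_a <- sum(choose(rowSums(tab), 2))
  sum_b <- sum(choose(colSums(tab), 2))
  expected <- sum_a * sum_b / choose(n, 2)
  max_idx <- (sum_a + sum_b) / 2
  if (max_idx == expected) return(1)  # both partitions trivial
  (sum_ij - expected) / (max_idx - expected)
}
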