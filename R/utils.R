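#' Adjusted Rand index between two partitions
#'
#' Chance-corrected agreement between two clusterings of the same items,
#' invariant to label names. Used to score recovery of the simulated cluster
#' structure.
#'
#' @param a,b vectors of cluster labels, same length.
#' @return numeric in \[-1, 1\]; 1 means identical partitions.
#' @export
adjusted_rand_index <- function(a, b) {
  stopifnot(length(a) == length(b))
  tab <- table(a, b)
  n <- sum(tab)
  sum_ij <- sum(choose(tab, 2))
  sum_a <- sum(choose(rowSums(tab), 2))
  sum_b <- sum(choose(colSums(tab), 2))
  expected <- sum_a * sum_b / choose(n, 2)
  max_index <- (sum_a + sum_b) / 2
  if (max_index == expected) return(1)
  (sum_ij - expected) / (max_index - expected)
}
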