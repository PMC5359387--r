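#' Adjusted Rand index between two labelings
#'
#' Chance-corrected agreement of two partitions of the same items,
#' computed from the contingency table:
#' ARI = (sum_ij C(n_ij,2) - E) / (max - E), where E is the expectation
#' of the pair count under random tables with fixed margins. 1 means
#' identical partitions, ~0 chance-level agreement.
#'
#' @param a,b vectors of cluster labels of equal length (any atomic
#'   type; NAs are treated as their own label).
#' @return numeric scalar.
#' @export
adjusted_rand_index <- function(a, b) {
  if (length(a) != length(b))
    format_error("labelings must have equal length")
  a <- addNA(factor(a), ifany = TRUE)
  b <- addNA(factor(b), ifany = TRUE)
  tab <- table(a, b)
  ch2 <- function(x) x * (x - 1) / 2
  sum_ij <- sum(ch2(tab))
  sum_a <- sum(ch2(rowSums(tab)))
  sum_b <- sum(ch2(colSums(tab)))
  n2 <- ch2(sum(tab))
  expected <- sum_a * sum_b / n2
  maxi <- (sum_a + sum_b) / 2
  if (maxi == expected) return(1)  # both partitions trivial
  (sum_ij - expected) / (maxi - expected)
}
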