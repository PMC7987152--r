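#' Area under the ROC curve (Mann-Whitney form)
#'
#' Computes AUROC as the probability that a random positive outscores a
#' random negative, with tied pairs counting one half:
#' `P(s+ > s-) + 0.5 P(s+ = s-)`. Evaluated in O(n log n) via rank sums,
#' which is exactly the normalised Mann-Whitney U statistic.
#'
#' @param scores numeric vector.
#' @param is_positive logical (or 0/1) vector, same length.
#' @return AUROC in `[0, 1]`.
#' @export
auroc <- function(scores, is_positive) {
  is_positive <- as.logical(is_positive)
  stopifnot(length(scores) == length(is_positive),
            !anyNA(scores), !anyNA(is_positive))
  n_pos <- sum(is_positive)
  n_neg <- sum(!is_positive)
  if (n_pos == 0L || n_neg == 0L) {
    stop("auroc needs at least one positive and one negative", call. = FALSE)
  }
  r <- rank(scores)  # midranks handle ties
  (sum(r[is_positive]) - n_pos * (n_pos + 1) / 2) / (n_pos * n_neg)
}

#' Adjusted Rand index between two partitions
#'
#' Chance-corrected agreement between two labelings of the same items,
#' computed from the contingency-table closed form.
#'
#' @param a,b label vectors of equal length (any atomic type).
#' @return ARI; 1 for identical partitions (up to relabeling), ~0 at chance.
#' @export
adjusted_rand_index <- function(a, b) {
  stopifnot(length(a) == length(b), length(a) >= 2L)
  tab <- table(a, b)
  choose2 <- function(x) x * (x - 1) / 2
  sum_ij <- sum(choose2(tab))
  sum_a <- sum(choose2(rowSums(tab)))
  sum_b <- sum(choose2(colSums(tab)))
  n2 <- choose2(length(a))
  expected <- sum_a * sum_b / n2
  max_index <- (sum_a + sum_b) / 2
  if (max_index == expected) return(if (sum_ij == expected) 1 else 0)
  (sum_ij - expected) / (max_index - expected)
}
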