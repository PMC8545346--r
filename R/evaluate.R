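# External validation of a predicted partition against ground truth by
# pair counting: every unordered sample pair is co-clustered or not in each
# partition, giving TP/FP/FN/TN from which the four indices follow.

#' Co-membership pair counts between two partitions
#'
#' @param predicted,truth Label vectors of equal length (`>= 2`); any
#'   atomic type, compared as categories.
#' @return A tibble with one row: `TP` (pairs co-clustered in both), `FP`
#'   (predicted only), `FN` (truth only), `TN` (neither); they sum to
#'   `n(n-1)/2`.
#' @export
pair_counts <- function(predicted, truth) {
  if (length(predicted) != length(truth)) {
    stop("label vectors differ in length", call. = FALSE)
  }
  n <- length(predicted)
  if (n < 2) stop("need at least 2 samples", call. = FALSE)
  ct <- table(as.character(predicted), as.character(truth))
  c2 <- function(x) sum(choose(x, 2))
  tp <- c2(ct)
  co_pred <- c2(rowSums(ct))
  co_true <- c2(colSums(ct))
  total <- choose(n, 2)
  tibble::tibble(TP = tp, FP = co_pred - tp, FN = co_true - tp,
                 TN = total - co_pred - co_true + tp)
}

#' Pair-counting agreement indices
#'
#' `jaccard_index` = TP / (TP + FP + FN); `fowlkes_mallows` =
#' TP / sqrt((TP + FP)(TP + FN)); `f1_score` = 2 TP / (2 TP + FP + FN),
#' the harmonic mean of pair-level precision TP / (TP + FP) and recall
#' TP / (TP + FN). Each is 0 when its denominator is 0.
#'
#' @param predicted,truth Label vectors of equal length.
#' @return A number in `[0, 1]`; 1 means identical partitions.
#' @export
jaccard_index <- function(predicted, truth) {
  pc <- pair_counts(predicted, truth)
  den <- pc$TP + pc$FP + pc$FN
  if (den == 0) 0 else pc$TP / den
}

#' @rdname jaccard_index
#' @export
fowlkes_mallows <- function(predicted, truth) {
  pc <- pair_counts(predicted, truth)
  den <- sqrt(pc$TP + pc$FP) * sqrt(pc$TP + pc$FN)
  if (den == 0) 0 else pc$TP / den
}

#' @rdname jaccard_index
#' @export
f1_score <- function(predicted, truth) {
  pc <- pair_counts(predicted, truth)
  den <- 2 * pc$TP + pc$FP + pc$FN
  if (den == 0) 0 else 2 * pc$TP / den
}

#' Adjusted Rand index
#'
#' Chance-corrected pair-counting agreement from the contingency table of
#' the two labelings: `(sum_ij C(n_ij,2) - E) / (0.5 * (sum_i C(a_i,2) +
#' sum_j C(b_j,2)) - E)` with `E = sum_i C(a_i,2) sum_j C(b_j,2) / C(n,2)`.
#' When the denominator is 0 (both partitions all-singletons or both one
#' block) the index is 1 if the partitions are identical as set partitions,
#' else 0.
#'
#' @param predicted,truth Label vectors of equal length.
#' @return A number `<= 1`; 1 means identical partitions, 0 the expected
#'   agreement of random labelings.
#' @export
adjusted_rand <- function(predicted, truth) {
  pc_tab <- table(as.character(predicted), as.character(truth))
  n <- length(predicted)
  if (n != length(truth)) stop("label vectors differ in length", call. = FALSE)
  if (n < 2) stop("need at least 2 samples", call. = FALSE)
  c2 <- function(x) sum(choose(x, 2))
  sum_ij <- c2(pc_tab)
  sum_a <- c2(rowSums(pc_tab))
  sum_b <- c2(colSums(pc_tab))
  e <- sum_a * sum_b / choose(n, 2)
  den <- (sum_a + sum_b) / 2 - e
  if (den == 0) {
    # degenerate: both extreme partitions of the same kind
    same <- sum_ij == sum_a && sum_ij == sum_b
    return(if (same) 1 else 0)
  }
  (sum_ij - e) / den
}

#' All four pair-counting indices at once
#'
#' @param predicted,truth Label vectors of equal length.
#' @return One-row tibble: `ari`, `jaccard`, `fowlkes_mallows`, `f1`.
#' @export
evaluate_partition <- function(predicted, truth) {
  tibble::tibble(
    ari = adjusted_rand(predicted, truth),
    jaccard = jaccard_index(predicted, truth),
    fowlkes_mallows = fowlkes_mallows(predicted, truth),
    f1 = f1_score(predicted, truth)
  )
}
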