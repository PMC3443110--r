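# Enumeration machinery shared by the exact test, the per-gene vectorized
# filter, and the achievable-p helpers. Combination matrices are memoised
# per (N, n): with the default cap of 14 total samples the largest is
# C(14,7) = 3432 columns.
.combo_cache <- new.env(parent = emptyenv())

rank_combos <- function(N, n) {
  key <- paste(N, n, sep = "_")
  if (is.null(.combo_cache[[key]]))
    .combo_cache[[key]] <- utils::combn(N, n)
  .combo_cache[[key]]
}

# 0/1 membership matrix (N x C(N,n)): column c marks the sample indices
# assigned to the second group under assignment c.
combo_indicator <- function(N, n) {
  key <- paste("ind", N, n, sep = "_")
  if (is.null(.combo_cache[[key]])) {
    cmb <- rank_combos(N, n)
    M <- matrix(0, N, ncol(cmb))
    M[cbind(as.vector(cmb), rep(seq_len(ncol(cmb)), each = n))] <- 1
    .combo_cache[[key]] <- M
  }
  .combo_cache[[key]]
}

.P_EPS <- 1e-9

#' Exact two-tailed Mann-Whitney rank-sum test for small groups
#'
#' Computes the Mann-Whitney U statistic (number of pairwise wins of group B
#' over group A, ties counting one half) and a permutation-exact two-tailed
#' p-value obtained by enumerating all `choose(m+n, n)` equally likely
#' assignments of the observed values into the two groups. The two-tailed
#' p is the null probability of a U at least as far from the center `mn/2`
#' as the observed one, which handles tied data without an asymmetric
#' doubling convention. Above `enumeration_cap` total samples a
#' tie-corrected normal approximation is used instead and flagged.
#'
#' @param values_a,values_b numeric vectors, both non-empty.
#' @param enumeration_cap maximum combined sample size for exact
#'   enumeration (default 14, i.e. at most 3432 assignments).
#' @return object of class `rank_test`: list with `U`, `p_two_tailed`,
#'   `m` (larger group size), `n` (smaller group size), `exact`.
#' @examples
#' exact_rank_sum(c(1, 2, 3), c(4, 5, 6))$p_two_tailed  # 0.1
#' @export
exact_rank_sum <- function(values_a, values_b, enumeration_cap = 14L) {
  if (!length(values_a) || !length(values_b))
    stop("both groups must be non-empty")
  stopifnot(all(is.finite(values_a)), all(is.finite(values_b)))
  na <- length(values_a); nb <- length(values_b)
  N <- na + nb
  r <- rank(c(values_a, values_b))  # mid-ranks for ties
  U <- sum(r[na + seq_len(nb)]) - nb * (nb + 1) / 2
  center <- na * nb / 2
  if (N <= enumeration_cap) {
    cmb <- rank_combos(N, nb)
    Usim <- colSums(matrix(r[cmb], nrow = nb)) - nb * (nb + 1) / 2
    p <- mean(abs(Usim - center) >= abs(U - center) - .P_EPS)
    exact <- TRUE
  } else {
    ties <- table(r)
    tie_term <- sum(ties^3 - ties) / (N * (N - 1))
    sigma2 <- na * nb / 12 * ((N + 1) - tie_term)
    if (sigma2 <= 0) {
      p <- 1
    } else {
      z <- (U - center) / sqrt(sigma2)
      p <- min(1, 2 * stats::pnorm(-abs(z)))
    }
    exact <- FALSE
  }
  structure(list(U = U, p_two_tailed = p, m = max(na, nb), n = min(na, nb),
                 exact = exact),
            class = "rank_test")
}

#' @export
print.rank_test <- function(x, ...) {
  cat(sprintf("Mann-Whitney rank-sum test (%s), groups %d vs %d\n",
              if (x$exact) "exact enumeration" else "normal approximation",
              x$m, x$n))
  cat(sprintf("U = %g, two-tailed p = %g\n", x$U, x$p_two_tailed))
  invisible(x)
}

#' Smallest achievable two-tailed exact p-value
#'
#' For groups of sizes m and n the most extreme possible ordering (complete
#' separation) has two-tailed p = `2 / choose(m+n, n)`, capped at 1. This is
#' the floor below which no p-value can fall: for 3 vs 3 it is 0.1, so a
#' stricter nominal cutoff must be relaxed to 0.1 for such designs.
#'
#' @param m,n positive group sizes.
#' @return the minimum achievable two-tailed p.
#' @examples
#' min_achievable_p(3, 3)  # 0.1
#' min_achievable_p(4, 4)  # 2/70
#' @export
min_achievable_p <- function(m, n) {
  if (!is.numeric(m) || !is.numeric(n) || m < 1 || n < 1)
    stop("group sizes must be positive")
  min(1, 2 / choose(m + n, n))
}

#' Two-tailed p of the k-th most extreme achievable test outcome
#'
#' Enumerates the exact null distribution of U for tie-free data and returns
#' the two-tailed p attached to the k-th most extreme distinct value of
#' `|U - mn/2|`. `k = 1` recovers [min_achievable_p()]; for 4 vs 4, `k = 2`
#' gives 4/70 = 0.0571, the value behind a printed cutoff of 0.057.
#'
#' @param m,n positive group sizes.
#' @param k rank of extremity (1 = most extreme).
#' @return the two-tailed p at that level.
#' @export
kth_smallest_p <- function(m, n, k) {
  if (!is.numeric(m) || !is.numeric(n) || m < 1 || n < 1)
    stop("group sizes must be positive")
  if (!is.numeric(k) || k < 1) stop("'k' must be >= 1")
  N <- m + n
  r <- seq_len(N)  # distinct values: ranks are 1..N
  cmb <- rank_combos(N, n)
  Usim <- colSums(matrix(r[cmb], nrow = n)) - n * (n + 1) / 2
  dev <- abs(Usim - m * n / 2)
  levels <- sort(unique(dev), decreasing = TRUE)
  if (k > length(levels))
    stop("'k' exceeds the number of distinct achievable levels (",
         length(levels), ")")
  mean(dev >= levels[k] - .P_EPS)
}

#' Fold difference between two mean log2 intensities
#'
#' Returns `2^(mean_log2_test - mean_log2_ref)`; values below 1 denote
#' decreases in the test group. Rounded to two decimals this reproduces the
#' "Fold Difference" rendering of the summary tables (e.g. mean log
#' intensities 11.11 vs 7.54 give 0.084, printed 0.08).
#'
#' @param mean_log2_ref,mean_log2_test finite log2 intensities.
#' @return the linear-scale fold ratio test/reference.
#' @export
fold_difference <- function(mean_log2_ref, mean_log2_test) {
  stopifnot(all(is.finite(mean_log2_ref)), all(is.finite(mean_log2_test)))
  2^(mean_log2_test - mean_log2_ref)
}
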