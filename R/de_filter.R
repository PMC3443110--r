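#' Differential-expression filter configuration
#'
#' The four selection criteria applied to each gene of a two-group contrast:
#' (1) the mean of the high-expression group exceeds `fold_threshold` times
#' the mean of the low group; (2) the high group holds at least
#' `min_present_high` Present detection calls (capped at the group size, so
#' 3-member groups require 3/3); (3) the exact two-tailed rank-sum p is at
#' most `p_max`, relaxed to the minimum achievable p of the design when
#' `adaptive_min_p` is on (for 3 vs 3 this raises a 0.057 cutoff to 0.1);
#' (4) of the m x n cross-group sample pairs (m the larger group), at least
#' (m-1) x n individually show a same-direction fold of `pairwise_fold` or
#' more on floored signals.
#'
#' @param fold_threshold group-mean fold ratio that must be exceeded
#'   (default 2).
#' @param min_present_high Present calls required in the high group
#'   (default 3).
#' @param p_max nominal p cutoff (default 0.057).
#' @param adaptive_min_p relax `p_max` to the design's minimum achievable p
#'   (default TRUE).
#' @param pairwise_rule apply criterion 4 (default TRUE).
#' @param pairwise_fold per-pair fold requirement (default 2).
#' @param enumeration_cap combined sample size up to which the rank test is
#'   enumerated exactly (default 14).
#' @return list of class `FilterConfig`.
#' @export
filter_config <- function(fold_threshold = 2, min_present_high = 3L,
                          p_max = 0.057, adaptive_min_p = TRUE,
                          pairwise_rule = TRUE, pairwise_fold = 2,
                          enumeration_cap = 14L) {
  stopifnot(fold_threshold > 1, p_max > 0, p_max <= 1,
            min_present_high >= 0, pairwise_fold >= 1,
            is.logical(adaptive_min_p), is.logical(pairwise_rule))
  structure(list(fold_threshold = fold_threshold,
                 min_present_high = as.integer(min_present_high),
                 p_max = p_max, adaptive_min_p = adaptive_min_p,
                 pairwise_rule = pairwise_rule,
                 pairwise_fold = pairwise_fold,
                 enumeration_cap = as.integer(enumeration_cap)),
            class = "FilterConfig")
}

effect_levels <- function() c("Increased", "Decreased", "Unchanged")

#' Compare two sample groups gene by gene
#'
#' Applies the four-criterion differential-expression filter to every gene
#' of a contrast between reference group A and test group B (e.g. WT vs
#' knockout at one age). Group means are arithmetic means of floored log2
#' signals; the fold is `2^(mean_b - mean_a)`, so folds below 1 are
#' decreases in group B. A gene's effect is `Increased` or `Decreased` only
#' if all four criteria pass, otherwise `Unchanged`.
#'
#' The exact rank-sum p is computed on floored signals, so values at or
#' below the floor tie, matching the fold arithmetic. Signals are expected
#' to be already scaled (see [scale_matrix()]); `scaling` supplies the floor.
#'
#' @param x an [expression_matrix()] of scaled signals.
#' @param group_a,group_b disjoint, non-empty sets of sample ids; A is the
#'   reference (e.g. WT), B the test group (e.g. KO).
#' @param config a [filter_config()].
#' @param scaling a [scaling_config()] (only the floor is used here).
#' @return data.frame of class `de_comparison`, one row per gene, with
#'   columns `gene_id`, `mean_log2_a`, `mean_log2_b`, `fold`,
#'   `n_present_high`, `p_two_tailed`, `pairwise_valid`, the four criterion
#'   flags `crit_fold`, `crit_present`, `crit_p`, `crit_pairwise`, and
#'   `effect`. Attributes record the groups, the effective p cutoff and the
#'   configurations.
#' @export
compare_groups <- function(x, group_a, group_b, config = filter_config(),
                           scaling = scaling_config()) {
  stopifnot(inherits(x, "ExpressionMatrix"),
            inherits(config, "FilterConfig"),
            inherits(scaling, "ScalingConfig"))
  if (!length(group_a) || !length(group_b))
    stop("both groups must be non-empty")
  if (length(intersect(group_a, group_b)))
    stop("groups overlap: ", intersect(group_a, group_b)[1L])
  missing <- setdiff(c(group_a, group_b), x$sample_ids)
  if (length(missing)) stop("sample id not in matrix: ", missing[1L])

  na <- length(group_a); nb <- length(group_b)
  m <- max(na, nb); n_small <- min(na, nb)
  Sf <- pmax(x$signals[, c(group_a, group_b), drop = FALSE], scaling$floor)
  L <- log2(Sf)
  ia <- seq_len(na); ib <- na + seq_len(nb)
  mean_a <- rowMeans(L[, ia, drop = FALSE])
  mean_b <- rowMeans(L[, ib, drop = FALSE])
  fold <- 2^(mean_b - mean_a)
  dirn <- sign(mean_b - mean_a)

  # criterion 1: strict ">" on the high/low mean ratio
  crit_fold <- pmax(fold, 1 / fold) > config$fold_threshold

  # criterion 2: Present calls in the higher-expressing group
  P <- x$calls[, c(group_a, group_b), drop = FALSE] == "P"
  nP_a <- rowSums(P[, ia, drop = FALSE])
  nP_b <- rowSums(P[, ib, drop = FALSE])
  high_is_b <- mean_b > mean_a
  n_present_high <- ifelse(high_is_b, nP_b, nP_a)
  size_high <- ifelse(high_is_b, nb, na)
  crit_present <- n_present_high >= pmin(config$min_present_high, size_high)

  # criterion 3: permutation-exact two-tailed rank-sum p, vectorized over
  # genes via the shared assignment-indicator matrix
  N <- na + nb
  center <- na * nb / 2
  R <- t(apply(Sf, 1L, rank))
  if (nrow(Sf) == 1L) R <- matrix(R, nrow = 1L)
  U <- rowSums(R[, ib, drop = FALSE]) - nb * (nb + 1) / 2
  if (N <= config$enumeration_cap) {
    M <- combo_indicator(N, nb)
    Usim <- R %*% M - nb * (nb + 1) / 2
    p <- rowMeans(abs(Usim - center) >= abs(U - center) - .P_EPS)
  } else {
    p <- vapply(seq_len(nrow(Sf)), function(g) {
      exact_rank_sum(Sf[g, ia], Sf[g, ib],
                     enumeration_cap = config$enumeration_cap)$p_two_tailed
    }, numeric(1L))
  }
  effective_p <- if (config$adaptive_min_p)
    max(config$p_max, min_achievable_p(m, n_small)) else config$p_max
  crit_p <- p <= effective_p + .P_EPS

  # criterion 4: same-direction >= pairwise_fold on each cross-group pair
  pairwise_valid <- integer(nrow(Sf))
  for (i in ia) for (j in ib) {
    ratio <- Sf[, j] / Sf[, i]
    pairwise_valid <- pairwise_valid +
      as.integer((dirn > 0 & ratio >= config$pairwise_fold) |
                 (dirn < 0 & 1 / ratio >= config$pairwise_fold))
  }
  need <- (m - 1L) * n_small
  crit_pairwise <- if (config$pairwise_rule) pairwise_valid >= need
                   else rep(TRUE, nrow(Sf))

  all_pass <- crit_fold & crit_present & crit_p & crit_pairwise
  effect <- factor(ifelse(all_pass & dirn > 0, "Increased",
                   ifelse(all_pass & dirn < 0, "Decreased", "Unchanged")),
                   levels = effect_levels())

  out <- data.frame(gene_id = x$gene_ids,
                    mean_log2_a = mean_a, mean_log2_b = mean_b,
                    fold = fold, n_present_high = n_present_high,
                    p_two_tailed = p, pairwise_valid = pairwise_valid,
                    crit_fold = crit_fold, crit_present = crit_present,
                    crit_p = crit_p, crit_pairwise = crit_pairwise,
                    effect = effect,
                    row.names = NULL, stringsAsFactors = FALSE)
  attr(out, "group_a") <- group_a
  attr(out, "group_b") <- group_b
  attr(out, "effective_p") <- effective_p
  attr(out, "config") <- config
  attr(out, "scaling") <- scaling
  class(out) <- c("de_comparison", "data.frame")
  out
}

#' Count differentially expressed genes in a contrast
#'
#' @param comparisons a `de_comparison` from [compare_groups()].
#' @return named integer vector `c(n_increased, n_decreased)`.
#' @export
summarize_contrast <- function(comparisons) {
  stopifnot(inherits(comparisons, "de_comparison"))
  c(n_increased = sum(comparisons$effect == "Increased"),
    n_decreased = sum(comparisons$effect == "Decreased"))
}

#' Top-k genes ranked by fold extremity
#'
#' Selects the genes called in one direction and orders them by extremity of
#' fold (ascending fold for decreases, descending for increases), breaking
#' ties by gene id for determinism. With an annotation table the output
#' mirrors the published top-50 table layout (symbol, description, the two
#' group mean log intensities, fold difference).
#'
#' @param comparisons a `de_comparison`.
#' @param direction `"Increased"` or `"Decreased"`.
#' @param k number of genes to keep (0 gives an empty table).
#' @param annotations optional annotation data.frame (see
#'   [read_annotations()]) used to add `symbol` and `description`.
#' @return data.frame of the selected rows in rank order.
#' @export
rank_by_fold <- function(comparisons, direction = c("Decreased", "Increased"),
                         k, annotations = NULL) {
  stopifnot(inherits(comparisons, "de_comparison"), k >= 0)
  direction <- match.arg(direction)
  sel <- comparisons[comparisons$effect == direction, , drop = FALSE]
  ord <- order(if (direction == "Decreased") sel$fold else -sel$fold,
               sel$gene_id)
  sel <- sel[ord, , drop = FALSE][seq_len(min(k, nrow(sel))), , drop = FALSE]
  out <- data.frame(gene_id = sel$gene_id,
                    mean_log2_a = sel$mean_log2_a,
                    mean_log2_b = sel$mean_log2_b,
                    fold = sel$fold,
                    row.names = NULL, stringsAsFactors = FALSE)
  if (!is.null(annotations)) {
    idx <- match(out$gene_id, annotations$gene_id)
    out <- cbind(out[, "gene_id", drop = FALSE],
                 symbol = annotations$symbol[idx],
                 description = annotations$description[idx],
                 out[, c("mean_log2_a", "mean_log2_b", "fold")])
  }
  out
}

#' Extract a gene -> effect map from a comparison
#'
#' @param comparisons a `de_comparison`.
#' @return named character vector of effect labels keyed by gene id, as
#'   consumed by [build_crosstab()] and [overlap_enrichment()].
#' @export
effect_map <- function(comparisons) {
  stopifnot(inherits(comparisons, "de_comparison"))
  stats::setNames(as.character(comparisons$effect), comparisons$gene_id)
}

#' @export
print.de_comparison <- function(x, ...) {
  n <- summarize_contrast(x)
  cat(sprintf("Two-group comparison: %d genes, %d vs %d samples\n",
              nrow(x), length(attr(x, "group_a")), length(attr(x, "group_b"))))
  cat(sprintf("effective p cutoff: %.4g\n", attr(x, "effective_p")))
  cat(sprintf("Increased: %d   Decreased: %d   Unchanged: %d\n",
              n[["n_increased"]], n[["n_decreased"]],
              nrow(x) - sum(n)))
  invisible(x)
}

#' @export
summary.de_comparison <- function(object, ...) {
  cfg <- attr(object, "config")
  cat("Four-criterion differential-expression filter\n")
  cat(sprintf("  fold > %g; Present >= %d in high group; p <= %.4g%s; ",
              cfg$fold_threshold, cfg$min_present_high,
              attr(object, "effective_p"),
              if (cfg$adaptive_min_p) " (adaptive)" else ""))
  cat(sprintf("pairwise %s\n",
              if (cfg$pairwise_rule)
                sprintf(">= (m-1)*n pairs at fold %g", cfg$pairwise_fold)
              else "off"))
  cat("Criterion pass rates:\n")
  print(vapply(object[c("crit_fold", "crit_present", "crit_p",
                        "crit_pairwise")], mean, numeric(1L)))
  print(table(object$effect))
  invisible(object)
}

#' Scatter plot of a two-group comparison
#'
#' Plots group-B vs group-A mean log2 intensity, highlighting called genes,
#' with the identity and fold-threshold guide lines.
#'
#' @param x a `de_comparison`.
#' @param ... passed to [graphics::plot()].
#' @export
plot.de_comparison <- function(x, ...) {
  cfg <- attr(x, "config")
  col <- c(Increased = "firebrick", Decreased = "navy",
           Unchanged = "grey70")[as.character(x$effect)]
  graphics::plot(x$mean_log2_a, x$mean_log2_b, col = col, pch = 20,
                 xlab = "mean log2 intensity (group A)",
                 ylab = "mean log2 intensity (group B)", ...)
  graphics::abline(0, 1, col = "grey40")
  graphics::abline(log2(cfg$fold_threshold), 1, lty = 2, col = "grey40")
  graphics::abline(-log2(cfg$fold_threshold), 1, lty = 2, col = "grey40")
  invisible(x)
}
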