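as_effect_factor <- function(labels, what) {
  if (is.null(names(labels)) || anyDuplicated(names(labels)))
    stop(what, " must be a named vector with unique gene ids")
  bad <- setdiff(unique(as.character(labels)), effect_levels())
  if (length(bad)) stop("unknown effect label in ", what, ": ", bad[1L])
  factor(as.character(labels), levels = effect_levels())
}

#' Three-way direction cross-tabulation
#'
#' Counts genes over the triple (effect at PN11, effect at PN56,
#' developmental change), each axis taking the three direction labels
#' Increased / Decreased / Unchanged. The three maps must cover the same
#' gene universe. This is the tabulation underlying a genome-wide breakdown
#' of knockout effects against normal maturation.
#'
#' @param effects_pn11,effects_pn56,effects_dev named character vectors of
#'   effect labels keyed by gene id (see [effect_map()]).
#' @return object of class `crosstab3`: a 3x3x3 integer array with dimnames
#'   `(pn11, pn56, dev)` and attribute `n_genes`.
#' @export
build_crosstab <- function(effects_pn11, effects_pn56, effects_dev) {
  f11 <- as_effect_factor(effects_pn11, "effects_pn11")
  ids <- names(effects_pn11)
  for (other in list(effects_pn56, effects_dev)) {
    d1 <- setdiff(ids, names(other)); d2 <- setdiff(names(other), ids)
    if (length(d1) || length(d2))
      stop("gene universes differ between effect maps (e.g. ",
           c(d1, d2)[1L], ")")
  }
  f56 <- as_effect_factor(effects_pn56[ids], "effects_pn56")
  fdev <- as_effect_factor(effects_dev[ids], "effects_dev")
  counts <- table(pn11 = f11, pn56 = f56, dev = fdev)
  counts <- array(as.integer(counts), dim = c(3L, 3L, 3L),
                  dimnames = list(pn11 = effect_levels(),
                                  pn56 = effect_levels(),
                                  dev = effect_levels()))
  structure(counts, class = "crosstab3", n_genes = length(ids))
}

#' Build a crosstab3 directly from a 3x3x3 count array
#'
#' For published count tables where per-gene labels are unavailable.
#'
#' @param counts 3x3x3 non-negative integer array indexed (pn11, pn56, dev),
#'   each axis ordered Increased, Decreased, Unchanged.
#' @return a `crosstab3`.
#' @export
crosstab_from_counts <- function(counts) {
  stopifnot(is.array(counts), identical(dim(counts), c(3L, 3L, 3L)),
            all(counts >= 0), all(counts == round(counts)))
  counts <- array(as.integer(counts), dim = c(3L, 3L, 3L),
                  dimnames = list(pn11 = effect_levels(),
                                  pn56 = effect_levels(),
                                  dev = effect_levels()))
  structure(counts, class = "crosstab3", n_genes = sum(counts))
}

#' @export
print.crosstab3 <- function(x, ...) {
  cat(sprintf("3x3x3 direction cross-tabulation of %d genes\n",
              attr(x, "n_genes")))
  cat("PN11 marginal:\n"); print(apply(unclass(x), 1L, sum))
  cat("PN56 marginal:\n"); print(apply(unclass(x), 2L, sum))
  cat("developmental marginal:\n"); print(apply(unclass(x), 3L, sum))
  invisible(x)
}

#' Concordant direction counts
#'
#' Genes called in the same non-Unchanged direction at both ages, summed
#' over the developmental axis.
#'
#' @param tab a `crosstab3`.
#' @return named integer vector
#'   `c(concordant_increase, concordant_decrease)`.
#' @export
concordant_counts <- function(tab) {
  stopifnot(inherits(tab, "crosstab3"))
  u <- unclass(tab)
  c(concordant_increase = sum(u["Increased", "Increased", ]),
    concordant_decrease = sum(u["Decreased", "Decreased", ]))
}

#' Developmental overlap of modulated vs unaffected genes
#'
#' First value: of the genes modulated at either age (non-Unchanged at PN11
#' or PN56), the percentage that also changed developmentally. Second value:
#' the same percentage among genes unaffected at both ages.
#'
#' @param tab a `crosstab3`.
#' @return named numeric vector
#'   `c(pct_modulated_also_dev, pct_unaffected_also_dev)`.
#' @export
modulated_overlap_percent <- function(tab) {
  stopifnot(inherits(tab, "crosstab3"))
  u <- unclass(tab)
  modulated <- u; modulated["Unchanged", "Unchanged", ] <- 0L
  n_mod <- sum(modulated)
  n_unaff <- sum(u["Unchanged", "Unchanged", ])
  if (n_mod == 0L || n_unaff == 0L)
    stop("empty denominator: need both modulated and unaffected genes")
  mod_dev <- sum(modulated[, , c("Increased", "Decreased")])
  unaff_dev <- sum(u["Unchanged", "Unchanged", c("Increased", "Decreased")])
  c(pct_modulated_also_dev = 100 * mod_dev / n_mod,
    pct_unaffected_also_dev = 100 * unaff_dev / n_unaff)
}

#' Overlap enrichment of two direction-labelled gene lists
#'
#' Cross-tabulates two effect-label maps over the same gene universe into a
#' 3x3 table and compares the concordant cells (Increased, Increased) and
#' (Decreased, Decreased) with their expected counts under independence
#' (`row_total * col_total / N`). Pearson's chi-square (no continuity
#' correction, df = 4) tests overall independence; because concordance can
#' be overwhelming in genome-scale lists, the p-value is also reported as
#' log10(p) to survive underflow.
#'
#' @param labels_x,labels_y named effect-label vectors over the same genes.
#' @return object of class `overlap_result`: list with `table` (3x3
#'   observed counts), `cells` (data.frame of observed, expected and fold
#'   enrichment for the two concordant cells), `chi2`, `df`, `p`, `log10_p`,
#'   `n`.
#' @export
overlap_enrichment <- function(labels_x, labels_y) {
  fx <- as_effect_factor(labels_x, "labels_x")
  ids <- names(labels_x)
  if (length(setdiff(ids, names(labels_y))) ||
      length(setdiff(names(labels_y), ids)))
    stop("gene universes differ between the two label maps")
  fy <- as_effect_factor(labels_y[ids], "labels_y")
  obs <- table(x = fx, y = fy)
  N <- sum(obs)
  expected <- outer(rowSums(obs), colSums(obs)) / N
  cells <- data.frame(
    cell = c("Increased/Increased", "Decreased/Decreased"),
    observed = c(obs["Increased", "Increased"], obs["Decreased", "Decreased"]),
    expected = c(expected["Increased", "Increased"],
                 expected["Decreased", "Decreased"]),
    stringsAsFactors = FALSE)
  if (any(cells$expected <= 0))
    stop("expected count is zero in a tested concordant cell")
  cells$fold_enrichment <- cells$observed / cells$expected
  nz <- expected > 0
  chi2 <- sum((obs[nz] - expected[nz])^2 / expected[nz])
  df <- 4L
  log10_p <- stats::pchisq(chi2, df, lower.tail = FALSE, log.p = TRUE) /
    log(10)
  structure(list(table = obs, cells = cells, chi2 = chi2, df = df,
                 p = stats::pchisq(chi2, df, lower.tail = FALSE),
                 log10_p = log10_p, n = N),
            class = "overlap_result")
}

#' @export
print.overlap_result <- function(x, ...) {
  cat(sprintf("Overlap of two direction-labelled lists over %d genes\n", x$n))
  print(x$cells, row.names = FALSE, digits = 4)
  cat(sprintf("chi-square = %.4g on %d df, p = %.3g (log10 p = %.2f)\n",
              x$chi2, x$df, x$p, x$log10_p))
  invisible(x)
}

#' Direction-aware Venn partition of two gene lists
#'
#' Splits two (gene, direction) lists into exclusive and shared parts; a
#' gene counts as shared only when both lists give it the same direction.
#'
#' @param list_a,list_b data.frames with columns `gene_id` and `direction`.
#' @return list with data.frames `only_a`, `only_b`, `both`.
#' @export
venn_sets <- function(list_a, list_b) {
  chk <- function(d, nm) {
    if (!is.data.frame(d) || !all(c("gene_id", "direction") %in% names(d)))
      stop(nm, " must have columns gene_id and direction")
    d[, c("gene_id", "direction")]
  }
  a <- chk(list_a, "list_a"); b <- chk(list_b, "list_b")
  key_a <- paste(a$gene_id, a$direction, sep = "\r")
  key_b <- paste(b$gene_id, b$direction, sep = "\r")
  list(only_a = a[!(key_a %in% key_b), , drop = FALSE],
       only_b = b[!(key_b %in% key_a), , drop = FALSE],
       both = a[key_a %in% key_b, , drop = FALSE])
}

#' Write a crosstab in the published nested layout
#'
#' Renders the 3x3x3 tensor as a tab-delimited table with the PN56 effect as
#' the outer row blocks, the developmental change nested within each block,
#' and the PN11 effect across the columns; plain integers only.
#'
#' @param tab a `crosstab3`.
#' @param path output path.
#' @return the rendered data.frame, invisibly.
#' @export
write_crosstab <- function(tab, path) {
  stopifnot(inherits(tab, "crosstab3"))
  u <- unclass(tab)
  lev <- effect_levels()
  rows <- expand.grid(dev = lev, pn56 = lev, stringsAsFactors = FALSE)
  rows <- rows[order(match(rows$pn56, lev), match(rows$dev, lev)), ]
  out <- data.frame(pn56_effect = rows$pn56, dev_change = rows$dev,
                    stringsAsFactors = FALSE)
  for (l11 in lev)
    out[[paste0("pn11_", l11)]] <-
      mapply(function(p56, dv) u[l11, p56, dv], rows$pn56, rows$dev)
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(out)
}
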