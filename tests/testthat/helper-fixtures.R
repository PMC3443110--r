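# Shared fixtures and independent oracles.

# Published 3x3x3 cross-tabulation of 21,815 unique characterized corneal
# genes: knockout effect at PN11 x knockout effect at PN56 x developmental
# change (PN56 WT vs PN11 WT). Axes ordered Increased, Decreased, Unchanged.
klf5_crosstab_counts <- function() {
  lev <- c("Increased", "Decreased", "Unchanged")
  u <- array(0L, c(3L, 3L, 3L), dimnames = list(pn11 = lev, pn56 = lev,
                                                dev = lev))
  # pn56 = Increased block, rows nested by developmental change
  u[, "Increased", "Increased"] <- c(37L, 0L, 16L)
  u[, "Increased", "Decreased"] <- c(99L, 1L, 175L)
  u[, "Increased", "Unchanged"] <- c(230L, 1L, 194L)
  # pn56 = Decreased block
  u[, "Decreased", "Increased"] <- c(0L, 25L, 47L)
  u[, "Decreased", "Decreased"] <- c(0L, 3L, 17L)
  u[, "Decreased", "Unchanged"] <- c(1L, 44L, 73L)
  # pn56 = Unchanged block
  u[, "Unchanged", "Increased"] <- c(58L, 31L, 1360L)
  u[, "Unchanged", "Decreased"] <- c(62L, 55L, 1503L)
  u[, "Unchanged", "Unchanged"] <- c(227L, 139L, 17417L)
  u
}

# Brute-force exact rank-sum oracle: U by explicit pairwise comparison,
# p by explicit enumeration of every group assignment. Independent of the
# rank-based implementation path.
oracle_rank_sum <- function(a, b) {
  na <- length(a); nb <- length(b)
  wins <- function(aa, bb) {
    u <- 0
    for (x in aa) for (y in bb) u <- u + (y > x) + 0.5 * (y == x)
    u
  }
  U <- wins(a, b)
  vals <- c(a, b)
  cmb <- utils::combn(na + nb, nb)
  devs <- apply(cmb, 2L, function(idx)
    abs(wins(vals[-idx], vals[idx]) - na * nb / 2))
  list(U = U, p = mean(devs >= abs(U - na * nb / 2) - 1e-9))
}

tiny_matrix <- function(signals, calls = NULL) {
  if (is.null(calls)) calls <- matrix("P", nrow(signals), ncol(signals))
  dimnames(calls) <- dimnames(signals)
  expression_matrix(signals, calls)
}

# Two-group matrix with explicit per-group gene values; all calls Present.
two_group_matrix <- function(A, B) {
  stopifnot(nrow(A) == nrow(B))
  s <- cbind(A, B)
  dimnames(s) <- list(sprintf("g%03d", seq_len(nrow(s))),
                      c(sprintf("a%d", seq_len(ncol(A))),
                        sprintf("b%d", seq_len(ncol(B)))))
  tiny_matrix(s)
}

group_ids <- function(prefix, n) sprintf("%s%d", prefix, seq_len(n))

random_effect_labels <- function(n, prob = c(0.2, 0.2, 0.6)) {
  stats::setNames(sample(c("Increased", "Decreased", "Unchanged"), n,
                         replace = TRUE, prob = prob),
                  sprintf("g%05d", seq_len(n)))
}
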