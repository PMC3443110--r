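test_that("the four criteria reproduce a hand-computed 3v3 example", {
  x <- two_group_matrix(matrix(c(50, 55, 60), 1, 3),
                        matrix(c(400, 420, 440), 1, 3))
  cmp <- compare_groups(x, group_ids("a", 3), group_ids("b", 3))
  expect_equal(attr(cmp, "effective_p"), 0.1)  # adaptive: max(0.057, 0.1)
  expect_equal(cmp$fold, 2^(mean(log2(c(400, 420, 440))) -
                            mean(log2(c(50, 55, 60)))))
  expect_gt(cmp$fold, 7.5); expect_lt(cmp$fold, 7.8)
  expect_equal(cmp$p_two_tailed, 0.1)
  expect_equal(cmp$pairwise_valid, 9L)
  expect_equal(cmp$n_present_high, 3)
  expect_true(all(cmp$crit_fold, cmp$crit_present, cmp$crit_p,
                  cmp$crit_pairwise))
  expect_equal(as.character(cmp$effect), "Increased")
})

test_that("identical groups are Unchanged with fold one", {
  x <- two_group_matrix(matrix(c(100, 120, 90), 1, 3),
                        matrix(c(100, 120, 90), 1, 3))
  cmp <- compare_groups(x, group_ids("a", 3), group_ids("b", 3))
  expect_equal(cmp$fold, 1)
  expect_equal(as.character(cmp$effect), "Unchanged")
  expect_false(cmp$crit_fold)
})

test_that("each criterion individually blocks a call", {
  base <- matrix(c(50, 55, 60), 1, 3)
  up4 <- base * 8
  # absent calls in the high group fail criterion 2
  s <- cbind(base, up4)
  dimnames(s) <- list("g001", c(group_ids("a", 3), group_ids("b", 3)))
  calls <- matrix(c("P", "P", "P", "P", "A", "A"), 1, 6,
                  dimnames = dimnames(s))
  cmp <- compare_groups(expression_matrix(s, calls),
                        group_ids("a", 3), group_ids("b", 3))
  expect_false(cmp$crit_present)
  expect_equal(as.character(cmp$effect), "Unchanged")
  expect_true(cmp$crit_fold && cmp$crit_p)

  # an overlapping ordering fails the exact-p criterion at 3v3
  x <- two_group_matrix(matrix(c(50, 55, 200), 1, 3),
                        matrix(c(60, 400, 440), 1, 3))
  cmp <- compare_groups(x, group_ids("a", 3), group_ids("b", 3))
  expect_gt(cmp$p_two_tailed, 0.1)
  expect_false(cmp$crit_p)

  # one weak pair out of nine fails the pairwise rule at (m-1)*n = 6...
  # 3v3 with three sub-2-fold pairs
  x <- two_group_matrix(matrix(c(50, 55, 300), 1, 3),
                        matrix(c(400, 420, 440), 1, 3))
  cmp <- compare_groups(x, group_ids("a", 3), group_ids("b", 3))
  expect_equal(cmp$pairwise_valid, 6L)
  expect_true(cmp$crit_pairwise)
  x <- two_group_matrix(matrix(c(50, 210, 250), 1, 3),
                        matrix(c(400, 420, 440), 1, 3))
  cmp <- compare_groups(x, group_ids("a", 3), group_ids("b", 3))
  expect_equal(cmp$pairwise_valid, 5L)
  expect_false(cmp$crit_pairwise)
  expect_equal(as.character(cmp$effect), "Unchanged")
})

test_that("sub-floor signals tie in the rank test and collapse folds", {
  # all signals below the floor: flooring makes both groups constant
  x <- two_group_matrix(matrix(c(1, 2, 3), 1, 3),
                        matrix(c(4, 6, 9), 1, 3))
  cmp <- compare_groups(x, group_ids("a", 3), group_ids("b", 3))
  expect_equal(cmp$fold, 1)
  expect_equal(cmp$p_two_tailed, 1)
  expect_equal(as.character(cmp$effect), "Unchanged")
})

test_that("raising the fold threshold never enlarges the selected set", {
  sim <- simulate_experiment(simulation_config(n_genes = 600, seed = 21,
                                               de_fraction = 0.1))
  x <- scale_matrix(sim$matrix)
  a <- samples_for(sim$samples, "WT", "PN56")
  b <- samples_for(sim$samples, "KO", "PN56")
  sets <- lapply(c(1.5, 2, 3, 5), function(th) {
    cmp <- compare_groups(x, a, b, filter_config(fold_threshold = th))
    cmp$gene_id[cmp$effect != "Unchanged"]
  })
  for (i in 2:4) expect_true(all(sets[[i]] %in% sets[[i - 1]]))
})

test_that("disabling the pairwise rule never shrinks the selected set", {
  sim <- simulate_experiment(simulation_config(n_genes = 600, seed = 22,
                                               de_fraction = 0.1,
                                               noise_sd = 0.5))
  x <- scale_matrix(sim$matrix)
  a <- samples_for(sim$samples, "WT", "PN56")
  b <- samples_for(sim$samples, "KO", "PN56")
  with_rule <- compare_groups(x, a, b, filter_config(pairwise_rule = TRUE))
  without <- compare_groups(x, a, b, filter_config(pairwise_rule = FALSE))
  sel_with <- with_rule$gene_id[with_rule$effect != "Unchanged"]
  sel_without <- without$gene_id[without$effect != "Unchanged"]
  expect_true(all(sel_with %in% sel_without))
})

test_that("null 3v3 data yields a call rate far below the p ceiling", {
  rates <- vapply(1:3, function(seed) {
    sim <- simulate_null(simulation_config(n_genes = 800, seed = seed,
                                           noise_sd = 0.4))
    x <- scale_matrix(sim$matrix)
    cmp <- compare_groups(x, samples_for(sim$samples, "WT", "PN11"),
                          samples_for(sim$samples, "KO", "PN11"))
    mean(cmp$effect != "Unchanged")
  }, numeric(1L))
  expect_true(all(rates <= 0.1))
  expect_lt(mean(rates), 0.02)
})

test_that("summarize_contrast recovers clean planted increases", {
  set.seed(31)
  n <- 500
  A <- matrix(2^(8 + rnorm(n * 4, 0, 0.05)), n, 4)
  eff <- c(rep(2, 100), rep(0, n - 100))
  B <- matrix(2^(8 + eff + rnorm(n * 4, 0, 0.05)), n, 4)
  x <- two_group_matrix(A, B)
  cmp <- compare_groups(x, group_ids("a", 4), group_ids("b", 4))
  counts <- summarize_contrast(cmp)
  expect_gte(counts[["n_increased"]], 98)
  expect_equal(counts[["n_decreased"]], 0L)

  # planted effects below the 2-fold threshold select nothing
  B2 <- matrix(2^(8 + c(rep(0.8, 50), rep(-0.8, 50), rep(0, n - 100)) +
                    rnorm(n * 4, 0, 0.05)), n, 4)
  cmp2 <- compare_groups(two_group_matrix(A, B2),
                         group_ids("a", 4), group_ids("b", 4))
  expect_equal(unname(summarize_contrast(cmp2)), c(0L, 0L))
})

test_that("rank_by_fold orders by extremity with deterministic ties", {
  set.seed(32)
  A <- matrix(2^(8 + rnorm(12, 0, 0.01)), 3, 4)
  B <- A * rep(c(8, 4, 2.5), 4)
  x <- two_group_matrix(A, B)
  cmp <- compare_groups(x, group_ids("a", 4), group_ids("b", 4))
  top <- rank_by_fold(cmp, "Increased", 3)
  expect_equal(top$gene_id, c("g001", "g002", "g003"))
  expect_true(all(diff(top$fold) < 0))
  expect_equal(nrow(rank_by_fold(cmp, "Increased", 0)), 0L)

  ann <- data.frame(gene_id = c("g001", "g002", "g003"),
                    symbol = c("S1", "S2", "S3"),
                    description = c("d1", "d2", "d3"),
                    go_bp_text = "")
  top <- rank_by_fold(cmp, "Increased", 2, annotations = ann)
  expect_identical(names(top), c("gene_id", "symbol", "description",
                                 "mean_log2_a", "mean_log2_b", "fold"))
})

test_that("group validation catches overlap and unknown samples", {
  x <- two_group_matrix(matrix(1:3 * 100, 1, 3), matrix(4:6 * 100, 1, 3))
  expect_error(compare_groups(x, c("a1", "a2"), c("a2", "b1")), "overlap")
  expect_error(compare_groups(x, c("a1", "zz"), c("b1")), "not in matrix")
  expect_error(compare_groups(x, character(0), c("b1")), "non-empty")
})

test_that("effect_map returns a named label vector over all genes", {
  x <- two_group_matrix(matrix(rep(100, 6), 2, 3), matrix(rep(100, 6), 2, 3))
  cmp <- compare_groups(x, group_ids("a", 3), group_ids("b", 3))
  m <- effect_map(cmp)
  expect_identical(names(m), c("g001", "g002"))
  expect_true(all(m == "Unchanged"))
})
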