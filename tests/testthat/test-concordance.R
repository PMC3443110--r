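test_that("crosstab counts label triples and validates its universe", {
  ids <- c("g1", "g2", "g3")
  u <- setNames(rep("Unchanged", 3), ids)
  tab <- build_crosstab(u, u, u)
  expect_equal(unclass(tab)["Unchanged", "Unchanged", "Unchanged"], 3L)
  expect_equal(sum(tab), 3L)
  expect_equal(attr(tab, "n_genes"), 3L)

  expect_error(build_crosstab(u, u[1:2], u), "universes differ")
  expect_error(build_crosstab(u, setNames(c("Up", "Up", "Up"), ids), u),
               "unknown effect label")

  # marginals reproduce label frequencies on random assignments
  set.seed(55)
  for (rep in 1:3) {
    l1 <- random_effect_labels(400); l2 <- random_effect_labels(400)
    l3 <- random_effect_labels(400)
    tab <- build_crosstab(l1, l2, l3)
    lev <- c("Increased", "Decreased", "Unchanged")
    expect_equal(unname(apply(unclass(tab), 1L, sum)),
                 as.vector(table(factor(l1, levels = lev))))
    expect_equal(unname(apply(unclass(tab), 2L, sum)),
                 as.vector(table(factor(l2, levels = lev))))
    expect_equal(unname(apply(unclass(tab), 3L, sum)),
                 as.vector(table(factor(l3, levels = lev))))
    expect_equal(sum(tab), 400L)
  }
})

test_that("concordant counts marginalize over the developmental axis", {
  tab <- crosstab_from_counts(klf5_crosstab_counts())
  expect_equal(concordant_counts(tab),
               c(concordant_increase = 366L, concordant_decrease = 72L))

  # permuting the developmental axis leaves concordance unchanged
  perm <- klf5_crosstab_counts()[, , c(3, 1, 2)]
  expect_equal(concordant_counts(crosstab_from_counts(perm)),
               concordant_counts(tab))

  u <- setNames(rep("Unchanged", 5), paste0("g", 1:5))
  expect_equal(unname(concordant_counts(build_crosstab(u, u, u))), c(0L, 0L))
})

test_that("developmental overlap percentages behave at the extremes", {
  # modulation and development perfectly aligned
  ids <- paste0("g", 1:100)
  lab <- setNames(c(rep("Increased", 40), rep("Unchanged", 60)), ids)
  tab <- build_crosstab(lab, lab, lab)
  expect_equal(unname(modulated_overlap_percent(tab)), c(100, 0))

  # independent labels: both percentages near the developmental change rate
  set.seed(66)
  n <- 20000
  mod <- random_effect_labels(n, prob = c(0.15, 0.15, 0.7))
  dev <- random_effect_labels(n, prob = c(0.15, 0.15, 0.7))
  tab <- build_crosstab(mod, setNames(rep("Unchanged", n), names(mod)), dev)
  pct <- modulated_overlap_percent(tab)
  expect_equal(unname(pct[1]), 30, tolerance = 0.05)
  expect_equal(unname(pct[2]), 30, tolerance = 0.05)

  all_mod <- setNames(rep("Increased", 5), paste0("g", 1:5))
  expect_error(modulated_overlap_percent(
    build_crosstab(all_mod, all_mod, all_mod)), "empty denominator")
})

test_that("overlap enrichment matches hand and library chi-square values", {
  # balanced 2x2-style fixture: chi2 = 6.667 with expected 15 per cell
  ids <- paste0("g", 1:60)
  x <- setNames(c(rep("Increased", 30), rep("Decreased", 30)), ids)
  y <- setNames(c(rep("Increased", 20), rep("Decreased", 10),
                  rep("Increased", 10), rep("Decreased", 20)), ids)
  res <- overlap_enrichment(x, y)
  expect_equal(res$chi2, 20 / 3, tolerance = 1e-12)
  expect_equal(res$df, 4L)
  expect_equal(res$cells$expected, c(15, 15))
  expect_equal(res$cells$fold_enrichment, c(20 / 15, 20 / 15))

  # engineered sevenfold concordant-increase enrichment:
  # row Inc = col Inc = 100 of 1000 genes, so expected (Inc,Inc) = 10
  ids <- paste0("g", 1:1000)
  x <- setNames(c(rep("Increased", 100), rep("Decreased", 50),
                  rep("Unchanged", 850)), ids)
  y <- setNames(rep("Unchanged", 1000), ids)
  y[c(1:70, 151:180)] <- "Increased"
  y[c(101:110, 181:220)] <- "Decreased"
  res <- overlap_enrichment(x, y)
  expect_equal(res$cells$expected[1], 10)
  expect_equal(res$cells$fold_enrichment[1], 7)

  # chi-square equals the independent library computation on random fixtures
  set.seed(77)
  for (rep in 1:10) {
    lx <- random_effect_labels(300)
    ly <- random_effect_labels(300)
    res <- overlap_enrichment(lx, ly)
    ref <- suppressWarnings(stats::chisq.test(table(lx, ly), correct = FALSE))
    expect_equal(res$chi2, unname(ref$statistic), tolerance = 1e-10)
    expect_equal(res$p, ref$p.value, tolerance = 1e-10)
    expect_equal(res$log10_p, log10(ref$p.value), tolerance = 1e-6)
  }
})

test_that("independent labels give near-unit enrichment and uniform p", {
  set.seed(88)
  n <- 5000
  lx <- random_effect_labels(n, prob = c(0.3, 0.3, 0.4))
  ly <- random_effect_labels(n, prob = c(0.3, 0.3, 0.4))
  res <- overlap_enrichment(lx, ly)
  expect_equal(res$cells$fold_enrichment, c(1, 1), tolerance = 0.15)

  # label-shuffled null: chi-square p approximately uniform
  lx <- random_effect_labels(400, prob = c(0.25, 0.25, 0.5))
  ly0 <- random_effect_labels(400, prob = c(0.25, 0.25, 0.5))
  ps <- replicate(1000, {
    ly <- setNames(sample(unname(ly0)), names(ly0))
    overlap_enrichment(lx, ly)$p
  })
  ks <- suppressWarnings(stats::ks.test(ps, "punif"))
  expect_gt(ks$p.value, 0.001)
  expect_gt(mean(ps > 0.5), 0.4)
})

test_that("venn partition is direction-aware", {
  a <- data.frame(gene_id = c("g1", "g2", "g3", "g4"),
                  direction = c("Increased", "Increased", "Decreased",
                                "Increased"))
  b <- data.frame(gene_id = c("g1", "g2", "g3", "g5"),
                  direction = c("Increased", "Increased", "Increased",
                                "Decreased"))
  v <- venn_sets(a, b)
  expect_equal(nrow(v$both), 2L)        # g3 differs in direction
  expect_equal(sort(v$both$gene_id), c("g1", "g2"))
  expect_equal(sort(v$only_a$gene_id), c("g3", "g4"))
  expect_equal(sort(v$only_b$gene_id), c("g3", "g5"))

  expect_equal(nrow(venn_sets(a, a)$only_a), 0L)
  d <- data.frame(gene_id = "g9", direction = "Increased")
  expect_equal(nrow(venn_sets(a, d)$both), 0L)
})

test_that("the crosstab writer emits the nested published layout", {
  tab <- crosstab_from_counts(klf5_crosstab_counts())
  path <- withr::local_tempfile(fileext = ".tsv")
  out <- write_crosstab(tab, path)
  expect_equal(nrow(out), 9L)
  expect_equal(sum(out[, 3:5]), 21815)
  # first row: PN56 Increased / dev Increased -> PN11 counts 37, 0, 16
  expect_equal(unname(unlist(out[1, 3:5])), c(37L, 0L, 16L))
  back <- utils::read.delim(path)
  expect_equal(sum(back[, 3:5]), 21815)
})
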