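test_that("GC comparison is degenerate-safe and matches the closed form", {
  g <- fixture_genes(gc_hgt = rep(40, 5), gc_native = rep(40, 5))
  res <- gc_compare(g)
  expect_equal(res$statistic, 0)
  expect_equal(res$p_value, 1)

  g2 <- fixture_genes(gc_hgt = c(40.2, 41.1, 39.8, 40.9),
                      gc_native = c(39.0, 39.5, 38.2, 39.9))
  res2 <- gc_compare(g2)
  want <- oracle_welch_t(c(40.2, 41.1, 39.8, 40.9), c(39.0, 39.5, 38.2, 39.9))
  expect_equal(res2$statistic, want$t, tolerance = 1e-10)
  expect_equal(res2$p_value, want$p, tolerance = 1e-10)
  expect_equal(res2$effect, mean(c(40.2, 41.1, 39.8, 40.9)) -
                 mean(c(39.0, 39.5, 38.2, 39.9)))
  expect_error(gc_compare(fixture_genes(gc_hgt = 40, gc_native = c(39, 39.5))),
               "at least 2")
})

test_that("exon-class Fisher test matches hypergeometric enumeration", {
  g <- fixture_genes(gc_hgt = rep(40, 10), gc_native = rep(39, 10),
                     exons_hgt = rep(c(1L, 2L), each = 5),
                     exons_native = rep(c(1L, 2L), each = 5))
  expect_equal(exon_class_test(g)$p_value, 1)

  g2 <- fixture_genes(gc_hgt = rep(40, 10), gc_native = rep(39, 10),
                      exons_hgt = rep(c(1L, 2L), c(8, 2)),
                      exons_native = rep(c(1L, 2L), c(2, 8)))
  res <- exon_class_test(g2)
  expect_equal(res$p_value, oracle_fisher(8, 10, 10, 10), tolerance = 1e-12)
  expect_equal(res$effect, 0.6)

  g3 <- fixture_genes(gc_hgt = rep(40, 4), gc_native = rep(39, 4),
                      exons_hgt = rep(1L, 4), exons_native = rep(1L, 4))
  expect_warning(res3 <- exon_class_test(g3), "zero margin")
  expect_equal(res3$p_value, 1)
})

test_that("permutation exon-count p matches exhaustive label enumeration", {
  hgt <- c(1L, 1L, 2L, 1L, 3L)
  nat <- c(4L, 3L, 5L, 2L, 6L)
  g <- fixture_genes(gc_hgt = rep(40, 5), gc_native = rep(39, 5),
                     exons_hgt = hgt, exons_native = nat)
  # exhaustive two-sided permutation p over all C(10,5) assignments
  x <- c(hgt, nat)
  r <- rank(x)
  mu <- 5 * 11 / 2
  obs <- sum(r[1:5])
  combos <- combn(10, 5)
  null_s <- apply(combos, 2, function(idx) sum(r[idx]))
  p_exact <- mean(abs(null_s - mu) >= abs(obs - mu) - 1e-9)
  res <- exon_count_test(g, n_bootstrap = 20000, seed = 42)
  expect_lt(abs(res$p_value - p_exact), 0.01)
  expect_equal(res$effect, mean(hgt) - mean(nat))
  expect_error(exon_count_test(fixture_genes(gc_hgt = 40, gc_native = 39)),
               "at least 2")
})

test_that("expression comparison reports class means and a rank-sum p", {
  g <- fixture_genes(gc_hgt = rep(40, 3), gc_native = rep(39, 3),
                     cpm_hgt = c(100, 200, 150), cpm_native = c(120, 80, 160))
  res <- expression_compare(g)
  expect_equal(res$extra$mean_hgt, 450 / 3)
  expect_equal(res$extra$mean_native, 360 / 3)
  expect_equal(res$effect, 30)
  expect_gt(res$p_value, 0.05)
  g0 <- fixture_genes(gc_hgt = rep(40, 3), gc_native = rep(39, 3),
                      cpm_hgt = rep(0, 3), cpm_native = rep(0, 3))
  expect_error(expression_compare(g0), "zero")
})

test_that("BH adjustment equals the step-up formula and validates input", {
  expect_equal(benjamini_hochberg(0.05), 0.05)
  expect_equal(benjamini_hochberg(c(0.01, 0.02, 0.03, 0.04)),
               rep(0.04, 4))
  set.seed(5)
  for (i in 1:50) {
    p <- runif(sample(1:40, 1))
    expect_equal(benjamini_hochberg(p), oracle_bh(p), tolerance = 1e-12)
  }
  expect_error(benjamini_hochberg(c(0.5, 1.2)), "\\[0, 1\\]")
  expect_error(benjamini_hochberg(c(0.5, -0.1)), "\\[0, 1\\]")
})

test_that("GO enrichment ranks a fully HGT-specific term first", {
  n <- 30
  g <- fixture_genes(gc_hgt = rep(40, n), gc_native = rep(39, n))
  g$go_terms <- c(rep("GO:X;GO:C", n), rep("GO:C", n))
  res <- go_enrichment(g)
  expect_identical(res$term[1], "GO:X")
  expect_lt(res$p_value[1], res$p_value[res$term == "GO:C"])
  expect_true(all(res$p_adjusted >= res$p_value))

  g$go_terms <- c("GO:rare", rep("", 2 * n - 1))
  expect_warning(out <- go_enrichment(g), "min_occurrence")
  expect_identical(nrow(out), 0L)
})

test_that("adjusted GO p-values match an independent step-up oracle", {
  set.seed(11)
  cfg <- sim_config(n_native_genes = 150, n_hgt_genes = 60, n_go_terms = 20,
                    seed = 31)
  g <- simulate_gene_table(cfg)
  g <- g[g$species == "Gs074W", ]
  res <- go_enrichment(g)
  expect_gte(nrow(res), 5)
  expect_equal(res$p_adjusted, oracle_bh(res$p_value), tolerance = 1e-12)
})
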