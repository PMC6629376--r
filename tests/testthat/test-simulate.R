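test_that("the same seed yields byte-identical simulations", {
  cfg <- sim_config(n_ogs = 25, hgt_fraction = 0.3, seed = 101)
  a <- simulate_og_trees(cfg)
  b <- simulate_og_trees(cfg)
  expect_identical(lapply(a$trees, function(t) ape::write.tree(t$phylo)),
                   lapply(b$trees, function(t) ape::write.tree(t$phylo)))
  expect_identical(a$truth, b$truth)
  expect_identical(simulate_gene_table(cfg), simulate_gene_table(cfg))
  expect_identical(simulate_pid_tables(cfg, n_hgt = 20, n_native = 40),
                   simulate_pid_tables(cfg, n_hgt = 20, n_native = 40))
})

test_that("planted tree labels are recovered exactly under clean supports", {
  cfg <- sim_config(n_ogs = 120, hgt_fraction = 0.35, egt_fraction = 0.1,
                    seed = 7)
  sim <- simulate_og_trees(cfg)
  calls <- classify_trees(sim$trees)
  expect_identical(calls$status, sim$truth$label)
  hgt <- sim$truth$label == "hgt"
  expect_identical(calls$pattern[hgt], sim$truth$pattern[hgt])
})

test_that("each planted pattern produces its own topology class", {
  cfg <- sim_config(seed = 3)
  for (pat in c("shared_ancient", "galdieria_exclusive",
                "cyanidioschyzon_exclusive", "replacement_galdieria",
                "replacement_cyanidioschyzon", "multiple_hgt", "uncertain")) {
    sim <- simulate_og_tree(cfg, "hgt", pattern = pat, og_id = pat)
    call <- classify_tree(sim$tree)
    expect_identical(call$status, sim$truth$label, info = pat)
    if (sim$truth$label == "hgt") {
      expect_identical(call$pattern, pat, info = pat)
    }
  }
  egt <- simulate_og_tree(cfg, "egt")
  expect_identical(classify_tree(egt$tree)$status, "egt_excluded")
  nat <- simulate_og_tree(cfg, "native")
  expect_identical(classify_tree(nat$tree)$status, "native")
})

test_that("gene tables carry the planted class effects", {
  cfg <- sim_config(seed = 19)
  g <- simulate_gene_table(cfg)
  gal <- g[g$lineage == "galdieria", ]
  # GC shift close to +1 in Galdieria
  eff <- mean(gal$gc_percent[gal$is_hgt]) - mean(gal$gc_percent[!gal$is_hgt])
  expect_lt(abs(eff - cfg$gc_shift_hgt), 0.3)
  # single-exon proportions near the planted values
  p_hgt <- mean(gal$exon_count[gal$is_hgt] == 1)
  p_nat <- mean(gal$exon_count[!gal$is_hgt] == 1)
  expect_lt(abs(p_hgt - cfg$single_exon_prob_hgt), 0.05)
  expect_lt(abs(p_nat - cfg$single_exon_prob_native), 0.05)
  # exon mean shift near the planted value
  ex_eff <- mean(gal$exon_count[gal$is_hgt]) - mean(gal$exon_count[!gal$is_hgt])
  expect_lt(abs(ex_eff - cfg$exon_mean_shift), 0.3)
  # no planted GC shift in Cyanidioschyzon
  cya <- g[g$lineage == "cyanidioschyzon", ]
  expect_lt(abs(mean(cya$gc_percent[cya$is_hgt]) -
                  mean(cya$gc_percent[!cya$is_hgt])), 0.5)
})

test_that("null generator settings yield non-significant tests", {
  hits <- 0
  for (seed in 1:20) {
    cfg <- sim_config(gc_shift_hgt = 0, n_native_genes = 600,
                      n_hgt_genes = 60, seed = seed)
    g <- simulate_gene_table(cfg)
    g1 <- g[g$species == "Gs074W", ]
    if (gc_compare(g1)$p_value <= 0.05) hits <- hits + 1
  }
  expect_lte(hits, 4)  # ~binomial(20, 0.05)
})

test_that("orthogroup-size erosion is bimodal as configured", {
  cfg <- sim_config(seed = 23)
  set.seed(23)
  sizes <- draw_galdieria_size <- replicate(4000, {
    cyanihgt:::draw_galdieria_size(cfg)
  })
  expect_lt(abs(mean(sizes == 11) - cfg$erosion_ancient), 0.03)
  expect_lt(abs(mean(sizes < 3) - cfg$erosion_recent), 0.03)
})

test_that("PID tables plant the donor-PID gap and rank correlation", {
  pid <- simulate_pid_tables(sim_config(seed = 29), n_hgt = 300,
                             n_native = 300)
  gap <- mean(pid$donor_pid[pid$class == "hgt"]) -
    mean(pid$donor_pid[pid$class == "native"])
  expect_lt(abs(gap - 6), 1.5)
  hgt <- pid[pid$class == "hgt", ]
  tau <- cor(hgt$within_pid, hgt$donor_pid, method = "kendall")
  expect_lt(abs(tau - 0.4), 0.12)
  expect_true(all(pid$og_size[pid$category %in% "cyanidioschyzon_only"] == 0))
})

test_that("read-alignment simulation respects the contamination fraction", {
  cfg <- sim_config(seed = 37)
  sim <- simulate_read_alignments(cfg, contamination_fraction = 0.2,
                                  n_hgt = 400, n_native = 500)
  res <- screen_colocalization(sim$alignments, sim$hgt_ids, sim$native_ids)
  expect_equal(res$n_candidates - res$n_colocalized, length(sim$contaminants))
  expect_lt(abs(length(sim$contaminants) / 400 - 0.2), 0.06)
})
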