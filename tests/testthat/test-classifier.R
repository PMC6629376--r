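test_that("maximal focal clades are found, including singletons", {
  tr <- fixture_tree("((E_gal1,E_gal2)90,(B_x,B_y)90)99;")
  cl <- focal_clades(tr)
  expect_length(cl, 1)
  expect_setequal(cl[[1]], c("E_gal1", "E_gal2"))

  tr2 <- fixture_tree("((E_gal1,B_x)90,(E_gal2,B_y)90)99;")
  cl2 <- focal_clades(tr2)
  expect_length(cl2, 2)
  expect_true(all(lengths(cl2) == 1))

  tr3 <- fixture_tree("((B_x,B_y)90,(B_z,B_w)90)99;")
  expect_length(focal_clades(tr3), 0)
})

test_that("focal clades match brute-force enumeration on random 50-leaf trees", {
  set.seed(42)
  for (i in 1:10) {
    tr <- random_support_tree(50, n_focal = sample(3:10, 1))
    got <- lapply(focal_clades(tr), function(x) sort(as.character(x)))
    want <- oracle_focal_clades(tr)
    expect_setequal(vapply(got, paste, "", collapse = "|"),
                    vapply(want, paste, "", collapse = "|"))
  }
})

test_that("nesting context classifies prokaryotic, eukaryotic and mixed", {
  tr <- fixture_tree("((E_gal1,E_gal2)95,(B_x,(B_y,B_z)90)92)99;")
  cx <- nesting_context(tr, focal_clades(tr)[[1]])
  expect_identical(cx$context, "prokaryotic")
  expect_setequal(cx$donor_taxa, c("x", "y", "z"))

  tr2 <- fixture_tree("((E_gal1,E_gal2)95,(E_o1,E_o2)92)99;")
  expect_identical(nesting_context(tr2, focal_clades(tr2)[[1]])$context,
                   "eukaryotic")

  tr3 <- fixture_tree("((E_gal1,E_gal2)95,(B_x,E_o1)92)99;")
  expect_identical(nesting_context(tr3, focal_clades(tr3)[[1]])$context,
                   "mixed")
})

test_that("the decision cascade reproduces the worked examples", {
  th <- hgt_thresholds()
  # clean HGT: two focal strains, three donors, high supports
  tr <- fixture_tree(
    "(((E_gal1,E_gal2)95,((B_s1,B_s2)91,B_s3)90)98,(E_o1,E_o2)97)99;")
  call <- classify_tree(tr, th)
  expect_identical(call$status, "hgt")
  expect_setequal(call$donor_taxa, c("s1", "s2", "s3"))

  # only two donors -> rejected
  tr2 <- fixture_tree("(((E_gal1,E_gal2)95,(B_s1,B_s2)91)98,(E_o1,E_o2)97)99;")
  expect_identical(classify_tree(tr2, th)$status, "rejected_few_donors")

  # two consecutive weak nodes on the focal-to-donor path -> rejected
  tr3 <- fixture_tree(
    "(((E_gal1,E_gal2)60,(B_s1,(B_s2,B_s3)80)55)58,(E_o1,E_o2)97)99;")
  expect_identical(classify_tree(tr3, th)$status, "rejected_low_support")

  # a single weak node does not reject
  tr4 <- fixture_tree(
    "(((E_gal1,E_gal2)60,((B_s1,B_s2)91,B_s3)90)98,(E_o1,E_o2)97)99;")
  expect_identical(classify_tree(tr4, th)$status, "hgt")

  # cyanobacteria as closest neighbors -> EGT even without annotation
  tr5 <- fixture_tree(
    "(((E_gal1,E_gal2)95,((B_c1,B_c2)91,B_c3)90)98,(E_o1,E_o2)97)99;",
    cyano = c("B_c1", "B_c2", "B_c3"))
  expect_identical(classify_tree(tr5, th)$status, "egt_excluded")

  # chlamydial donors: EGT only when the photosynthetic annotation is set
  tr5b <- fixture_tree(
    "(((E_gal1,E_gal2)95,((B_c1,B_c2)91,B_c3)90)98,(E_o1,E_o2)97)99;",
    chlam = c("B_c1", "B_c2", "B_c3"))
  expect_identical(
    classify_tree(tr5b, th, list(photosynthetic_annotation = TRUE))$status,
    "egt_excluded")
  expect_identical(classify_tree(tr5b, th)$status, "hgt")

  # lone focal strain -> singleton
  tr6 <- fixture_tree("((E_gal1,(B_s1,(B_s2,B_s3)90)90)95,(E_o1,E_o2)97)99;")
  expect_identical(classify_tree(tr6, th)$status, "singleton")

  # eukaryotic nesting -> native
  tr7 <- fixture_tree(
    "((((E_gal1,E_gal2)95,(E_o1,E_o2)95)95,(E_o3,E_o4)95)95,(B_x,B_y)95)99;")
  expect_identical(classify_tree(tr7, th)$status, "native")
})

test_that("acquisition patterns follow lineage membership and placement", {
  # both lineages in one prokaryote-nested clade: ancient shared transfer
  tr <- fixture_tree(
    "((((E_gal1,E_gal2)95,E_cya1)95,((B_s1,B_s2)91,B_s3)90)98,(E_o1,E_o2)97)99;")
  expect_identical(classify_tree(tr)$pattern, "shared_ancient")

  # Galdieria nested among prokaryotes, Cyanidioschyzon among eukaryotes
  tr2 <- fixture_tree(paste0(
    "((((E_gal1,E_gal2)95,((B_s1,B_s2)91,B_s3)90)98,",
    "(((E_cya1,E_cya2)95,(E_o1,E_o2)95)95,(E_o3,E_o4)95)95)99,B_far)99;"))
  call2 <- classify_tree(tr2)
  expect_identical(call2$status, "hgt")
  expect_identical(call2$pattern, "replacement_galdieria")

  # two focal clades with donors from different phyla: multiple transfers
  tr3 <- fixture_tree(paste0(
    "(((((E_gal1,E_gal2)95,(B_p1,B_p2)95)96,B_p3)97,",
    "(((E_cya1,E_cya2)95,(B_f1,B_f2)95)96,B_f3)97)98,(E_o1,E_o2)95)99;"),
    phylum = c(B_p1 = "Proteobacteria", B_p2 = "Proteobacteria",
               B_p3 = "Proteobacteria", B_f1 = "Firmicutes",
               B_f2 = "Firmicutes", B_f3 = "Firmicutes"))
  call3 <- classify_tree(tr3)
  expect_identical(call3$status, "hgt")
  expect_identical(call3$pattern, "multiple_hgt")
  expect_setequal(call3$donor_phyla, c("Proteobacteria", "Firmicutes"))

  # same topology with a weak split node: uncertain
  tr4 <- fixture_tree(paste0(
    "(((((E_gal1,E_gal2)95,(B_p1,B_p2)95)96,B_p3)97,",
    "(((E_cya1,E_cya2)95,(B_f1,B_f2)95)96,B_f3)97)55,(E_o1,E_o2)95)99;"),
    phylum = c(B_p1 = "Proteobacteria", B_p2 = "Proteobacteria",
               B_p3 = "Proteobacteria", B_f1 = "Firmicutes",
               B_f2 = "Firmicutes", B_f3 = "Firmicutes"))
  expect_identical(classify_tree(tr4)$pattern, "uncertain")
})

test_that("classification is invariant to leaf input order", {
  a <- fixture_tree(
    "(((E_gal1,E_gal2)95,((B_s1,B_s2)91,B_s3)90)98,(E_o1,E_o2)97)99;")
  b <- fixture_tree(
    "((E_o2,E_o1)97,((B_s3,(B_s2,B_s1)91)90,(E_gal2,E_gal1)95)98)99;")
  ca <- classify_tree(a); cb <- classify_tree(b)
  expect_identical(ca$status, cb$status)
  expect_identical(ca$pattern, cb$pattern)
  expect_setequal(ca$donor_taxa, cb$donor_taxa)
})

test_that("raising min_donor_taxa never converts a non-HGT call to HGT", {
  set.seed(99)
  for (i in 1:20) {
    tr <- random_support_tree(20, n_focal = sample(2:6, 1))
    s3 <- tryCatch(suppressWarnings(
      classify_tree(tr, hgt_thresholds(min_donor_taxa = 3))$status),
      error = function(e) "error")
    s5 <- tryCatch(suppressWarnings(
      classify_tree(tr, hgt_thresholds(min_donor_taxa = 5))$status),
      error = function(e) "error")
    if (s3 != "hgt") expect_false(s5 == "hgt")
  }
})

test_that("classifier agrees with the independent rule-by-rule oracle", {
  set.seed(7)
  n_agree <- 0
  for (i in 1:200) {
    tr <- random_support_tree(sample(10:30, 1), n_focal = sample(2:6, 1))
    got <- tryCatch(suppressWarnings(classify_tree(tr)),
                    error = function(e) list(status = "error"))
    want <- tryCatch(suppressWarnings(oracle_classify(tr)),
                     error = function(e) list(status = "error"))
    expect_identical(got$status, want$status, info = paste("tree", i))
    if (got$status == "hgt") {
      expect_identical(got$pattern, want$pattern, info = paste("tree", i))
    }
    n_agree <- n_agree + 1
  }
  expect_identical(n_agree, 200)
})

test_that("presence matrix entries match a leaf-count recount", {
  cfg <- sim_config(n_ogs = 40, hgt_fraction = 0.5, seed = 13)
  sim <- simulate_og_trees(cfg)
  calls <- classify_trees(sim$trees)
  strains <- cyanidiales_strains()$strain
  pm <- presence_matrix(calls, strains)
  hgt <- calls[calls$status == "hgt", ]
  expect_identical(rownames(pm), hgt$og_id)
  for (i in seq_len(nrow(hgt))) {
    present <- strsplit(hgt$focal_strains[i], ";")[[1]]
    expect_equal(unname(rowSums(pm)[i]), length(present))
    expect_setequal(colnames(pm)[pm[i, ] == 1], present)
  }
})

test_that("degenerate trees raise contract errors", {
  tr <- fixture_tree("((B_x,B_y)90,(B_z,B_w)90)99;")
  expect_error(classify_tree(tr), "no focal leaves")
  tr2 <- fixture_tree("((E_gal1,E_gal2)90,(E_gal3,E_gal4)90)99;")
  expect_error(classify_tree(tr2), "unrootable")
})
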