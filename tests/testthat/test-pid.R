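test_that("pairwise identity uses gap-excluded aligned columns", {
  expect_equal(pairwise_pid("AAAA", "AAAA"), 100)
  expect_equal(pairwise_pid("AAAA", "AAAT"), 75)
  seq20 <- "MKVLITGGAGFIGSHLVDRL"
  expect_equal(pairwise_pid(seq20, seq20), 100)
  expect_error(pairwise_pid("", "AAAA"), "empty")
})

test_that("pairwise identity matches an independent alignment recomputation", {
  set.seed(3)
  aas <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]
  for (i in 1:10) {
    a <- paste(sample(aas, 30, replace = TRUE), collapse = "")
    b <- paste(sample(aas, 30, replace = TRUE), collapse = "")
    aln <- Biostrings::pairwiseAlignment(a, b, type = "global",
                                         substitutionMatrix = "BLOSUM62",
                                         gapOpening = 10, gapExtension = 0.5)
    pa <- strsplit(as.character(Biostrings::pattern(aln)), "")[[1]]
    pb <- strsplit(as.character(Biostrings::subject(aln)), "")[[1]]
    # recompute column-wise with explicit loops
    num <- 0; den <- 0
    for (k in seq_along(pa)) {
      if (pa[k] != "-" && pb[k] != "-") {
        den <- den + 1
        if (pa[k] == pb[k]) num <- num + 1
      }
    }
    expect_equal(pairwise_pid(a, b), 100 * num / den)
  }
})

test_that("orthogroup PID summaries aggregate all pairs", {
  seqs <- c(f1 = "MKVLITGGAG", f2 = "MKVLITGGAG", d1 = "MKVLILLLLL")
  s <- og_pid_summary(seqs, focal_ids = c("f1", "f2"), donor_ids = "d1")
  expect_equal(unname(s$pid_within), c(100, 100, 100))
  expect_equal(unname(s$pid_to_donor["mean"]), pairwise_pid(seqs["f1"], seqs["d1"]))

  # 3 focal x 2 donors: donor stats over all six pairs, hand-enumerated
  set.seed(8)
  aas <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]
  rs <- function() paste(sample(aas, 25, replace = TRUE), collapse = "")
  seqs2 <- c(f1 = rs(), f2 = rs(), f3 = rs(), d1 = rs(), d2 = rs())
  s2 <- og_pid_summary(seqs2, c("f1", "f2", "f3"), c("d1", "d2"))
  pairs <- expand.grid(f = c("f1", "f2", "f3"), d = c("d1", "d2"),
                       stringsAsFactors = FALSE)
  pid6 <- mapply(function(f, d) pairwise_pid(seqs2[[f]], seqs2[[d]]),
                 pairs$f, pairs$d)
  expect_equal(unname(s2$pid_to_donor), unname(pid_stats_check <- c(mean(pid6), min(pid6), max(pid6))))
  expect_equal(s2$max_candidate_pid, max(pid6))
  expect_error(og_pid_summary(seqs2, character()), "at least one focal")
})

test_that("the seventy-percent audit is strict at the boundary", {
  s <- data.frame(og_id = c("a", "b", "c"), class = "hgt",
                  max_candidate_pid = c(69.9, 70, 70.1),
                  donor_phyla = c("Firmicutes", "Firmicutes", "Cyanobacteria"))
  audit <- seventy_rule_audit(s)
  expect_identical(audit$n_hgt_over, 1L)
  expect_identical(audit$flagged$og_id, "c")
  expect_true(audit$flagged$egt_attributable)
  expect_identical(audit$n_under + audit$n_hgt_over + audit$n_native_over,
                   3L)
  none <- seventy_rule_audit(s, threshold = 100)
  expect_identical(none$n_hgt_over, 0L)
})

test_that("Kendall trend handles perfect order, ties, and constants", {
  expect_equal(kendall_trend(1:5, c(2, 4, 6, 8, 10))$statistic, 1)
  expect_equal(kendall_trend(1:5, c(10, 8, 6, 4, 2))$statistic, -1)
  expect_error(kendall_trend(1:5, rep(3, 5)), "constant")

  # n = 6 with one tie: exact p equals full enumeration of 720 permutations
  x <- c(1, 2, 3, 4, 5, 6)
  y <- c(2, 1, 4, 4, 6, 5)
  res <- kendall_trend(x, y)
  expect_equal(res$statistic, cor(x, y, method = "kendall"))
  expect_equal(res$p_value, oracle_kendall_p(x, y), tolerance = 1e-12)
})

test_that("Jonckheere-Terpstra matches exhaustive enumeration and is invariant", {
  res <- jonckheere_terpstra(list(c(1, 2), c(3, 4), c(5, 6)), "increasing")
  expect_equal(res$statistic, 12)  # maximum over 3 x 4 cross-comparisons
  null <- oracle_jt_null(list(c(1, 2), c(3, 4), c(5, 6)))
  expect_equal(res$p_value, mean(null >= 12 - 1e-9), tolerance = 1e-12)

  # all observations equal: JT = null mean, p ~ 1
  eq <- jonckheere_terpstra(list(rep(2, 3), rep(2, 3), rep(2, 3)), "two.sided")
  expect_equal(eq$statistic, eq$extra$null_mean)
  expect_equal(eq$p_value, 1)

  # invariance under a monotone transform
  g <- list(c(0.3, 1.2), c(0.8, 2.0, 1.4), c(2.2, 3.1))
  expect_equal(jonckheere_terpstra(g, "increasing")$statistic,
               jonckheere_terpstra(lapply(g, exp), "increasing")$statistic)
  expect_error(jonckheere_terpstra(list(1:3, 4:6)), "3 ordered groups")
  expect_error(jonckheere_terpstra(list(1:3, numeric(0), 4:6)), "non-empty")
})

test_that("JT and Kendall agree in sign on two-group-collapsed data", {
  set.seed(14)
  lo <- rnorm(6, 0); hi <- rnorm(6, 2)
  jt <- jonckheere_terpstra(list(lo, hi, hi + 1), "increasing")
  tau <- kendall_trend(rep(c(1, 2, 3), each = 6), c(lo, hi, hi + 1))
  expect_gt(jt$effect, 0)
  expect_gt(tau$statistic, 0)
})

test_that("the cumulative-effects suite wires its four comparisons", {
  pid <- simulate_pid_tables(sim_config(seed = 17), n_hgt = 96, n_native = 300)
  ce <- cumulative_effects_suite(pid, n_perm = 300, seed = 1)
  expect_s3_class(ce$global, "stat_result")
  expect_equal(ce$global$effect, mean(pid$donor_pid[pid$class == "hgt"]) -
                 mean(pid$donor_pid[pid$class == "native"]))
  expect_false(is.null(ce$trend_native))
  expect_false(is.null(ce$by_size))
  expect_true(all(ce$by_size$p_adjusted >= ce$by_size$p_value))
  expect_false(is.null(ce$by_category))
  # all-equal fixture: nothing significant
  flat <- data.frame(og_id = sprintf("o%d", 1:60),
                     class = rep(c("hgt", "native"), 30),
                     og_size = rep(1:3, 20), donor_pid = 50,
                     category = "shared")
  ce2 <- cumulative_effects_suite(flat, n_perm = 200, seed = 2)
  expect_gt(ce2$global$p_value, 0.05)
  expect_gt(ce2$trend_hgt$p_value, 0.05)
  # one class empty: skipped with warning
  expect_warning(cumulative_effects_suite(flat[flat$class == "hgt", ],
                                          n_perm = 50), "skipped")
})

test_that("seed-reproducibility of permutation p-values", {
  g <- list(rnorm(8), rnorm(8), rnorm(8), rnorm(8))
  a <- jonckheere_terpstra(g, "increasing", n_perm = 200, seed = 5,
                           max_exact = 1)
  b <- jonckheere_terpstra(g, "increasing", n_perm = 200, seed = 5,
                           max_exact = 1)
  expect_identical(a$p_value, b$p_value)
})
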