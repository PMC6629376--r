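# HGT-vs-native feature statistics: GC content (t-test), exon structure
# (Fisher on single/multi, permutation rank-sum on exon counts),
# expression (rank-sum on CPM), GO enrichment (per-term Fisher + BH).

stat_result <- function(method, statistic, p_value, n1, n2, effect,
                        p_adjusted = NA_real_, extra = list()) {
  structure(
    list(method = method, statistic = unname(statistic),
         p_value = unname(p_value), p_adjusted = p_adjusted,
         n1 = n1, n2 = n2, effect = unname(effect), extra = extra),
    class = "stat_result"
  )
}

#' @export
print.stat_result <- function(x, ...) {
  cat(sprintf("%s: statistic = %.4g, p = %.4g (n1 = %d, n2 = %d), effect = %.4g\n",
              x$method, x$statistic, x$p_value, x$n1, x$n2, x$effect))
  if (!is.na(x$p_adjusted)) cat(sprintf("  adjusted p = %.4g\n", x$p_adjusted))
  invisible(x)
}

split_classes <- function(genes) {
  if (!is.logical(genes$is_hgt)) genes$is_hgt <- as.logical(genes$is_hgt)
  list(hgt = genes[genes$is_hgt, , drop = FALSE],
       native = genes[!genes$is_hgt, , drop = FALSE])
}

#' Compare GC content of HGT candidates and native genes
#'
#' Two-sided two-sample t-test on percent GC within one species
#' (transcript GC is close to normal in these genomes). Welch's
#' unequal-variance form by default; set `var_equal = TRUE` for the pooled
#' Student form. Effect is mean(HGT) - mean(native) in GC percentage
#' points.
#'
#' @param genes Gene table rows of a single species (columns `gc_percent`,
#'   `is_hgt`).
#' @param var_equal Pool variances (classical Student's t)?
#' @return A `stat_result`.
#' @export
gc_compare <- function(genes, var_equal = FALSE) {
  cl <- split_classes(genes)
  if (nrow(cl$hgt) < 2 || nrow(cl$native) < 2) {
    stop("gc_compare needs at least 2 genes in each class")
  }
  if (stats::sd(genes$gc_percent) == 0) {
    return(stat_result("t-test (GC%)", 0, 1, nrow(cl$hgt), nrow(cl$native), 0))
  }
  tt <- stats::t.test(cl$hgt$gc_percent, cl$native$gc_percent,
                      var.equal = var_equal)
  stat_result(
    if (var_equal) "Student t-test (GC%)" else "Welch t-test (GC%)",
    tt$statistic, tt$p.value, nrow(cl$hgt), nrow(cl$native),
    mean(cl$hgt$gc_percent) - mean(cl$native$gc_percent),
    extra = list(mean_hgt = mean(cl$hgt$gc_percent),
                 mean_native = mean(cl$native$gc_percent))
  )
}

#' Test association between origin and single- vs multi-exon structure
#'
#' Fisher's exact test on the 2x2 table HGT/native by single-/multi-exon.
#' Two-sided p sums all tables with point probability at most that of the
#' observed table. Effect is the difference in single-exon proportions
#' (HGT minus native). A zero margin yields p = 1 with a warning.
#'
#' @param genes Gene table rows of one species (`exon_count`, `is_hgt`).
#' @return A `stat_result`; the 2x2 table is in `$extra$table`.
#' @export
exon_class_test <- function(genes) {
  cl <- split_classes(genes)
  tab <- rbind(
    hgt = c(single = sum(cl$hgt$exon_count == 1),
            multi = sum(cl$hgt$exon_count > 1)),
    native = c(single = sum(cl$native$exon_count == 1),
               multi = sum(cl$native$exon_count > 1))
  )
  eff <- tab["hgt", "single"] / max(1, sum(tab["hgt", ])) -
    tab["native", "single"] / max(1, sum(tab["native", ]))
  if (any(rowSums(tab) == 0) || any(colSums(tab) == 0)) {
    warning("degenerate 2x2 table (zero margin); p set to 1")
    return(stat_result("Fisher exact (single vs multi exon)", NA_real_, 1,
                       sum(tab["hgt", ]), sum(tab["native", ]), eff,
                       extra = list(table = tab)))
  }
  ft <- stats::fisher.test(tab)
  stat_result("Fisher exact (single vs multi exon)",
              unname(ft$estimate), ft$p.value,
              sum(tab["hgt", ]), sum(tab["native", ]), eff,
              extra = list(table = tab))
}

# rank-sum statistic (sum of ranks of group 1 in the pooled sample)
rank_sum_stat <- function(x, g1) sum(rank(x)[g1])

#' Permutation rank-sum test on exons per gene
#'
#' Wilcoxon-Mann-Whitney comparison of exon counts between HGT candidates
#' and native genes, with the null distribution obtained by `n_bootstrap`
#' random label permutations (the exact rank-sum p-value from
#' [stats::wilcox.test()] is reported alongside in `$extra$p_ranksum`).
#' Two-sided: permuted rank sums at least as far from the null mean as the
#' observed one count against it. Effect is mean(HGT) - mean(native)
#' exons per gene.
#'
#' @param genes Gene table rows of one species.
#' @param n_bootstrap Number of label permutations.
#' @param seed Optional integer seed for reproducibility.
#' @return A `stat_result`.
#' @export
exon_count_test <- function(genes, n_bootstrap = 1000, seed = NULL) {
  cl <- split_classes(genes)
  n1 <- nrow(cl$hgt); n2 <- nrow(cl$native)
  if (n1 < 2 || n2 < 2) stop("exon_count_test needs at least 2 genes per class")
  if (!is.null(seed)) set.seed(seed)
  x <- c(cl$hgt$exon_count, cl$native$exon_count)
  g1 <- seq_len(n1)
  obs <- rank_sum_stat(x, g1)
  mu <- n1 * (length(x) + 1) / 2
  r <- rank(x)
  perm <- vapply(seq_len(n_bootstrap), function(i) {
    sum(r[sample.int(length(x), n1)])
  }, numeric(1))
  p <- (1 + sum(abs(perm - mu) >= abs(obs - mu) - 1e-9)) / (n_bootstrap + 1)
  wt <- suppressWarnings(stats::wilcox.test(cl$hgt$exon_count,
                                            cl$native$exon_count))
  stat_result("permutation rank-sum (exons/gene)", obs, p, n1, n2,
              mean(cl$hgt$exon_count) - mean(cl$native$exon_count),
              extra = list(p_ranksum = wt$p.value, null_mean = mu))
}

#' Compare transcript abundance (CPM) of HGT candidates and native genes
#'
#' Wilcoxon-Mann-Whitney rank-sum test on counts-per-million (CPM is
#' heavy-tailed, so no normality is assumed). Class means are reported in
#' `$extra` for comparison with the per-species averages.
#'
#' @param genes Gene table rows of one species (`cpm`, `is_hgt`).
#' @return A `stat_result` with effect = mean(HGT) - mean(native) CPM.
#' @export
expression_compare <- function(genes) {
  cl <- split_classes(genes)
  if (all(genes$cpm == 0)) stop("all CPM values are zero")
  wt <- suppressWarnings(stats::wilcox.test(cl$hgt$cpm, cl$native$cpm))
  stat_result("Wilcoxon rank-sum (CPM)", wt$statistic, wt$p.value,
              nrow(cl$hgt), nrow(cl$native),
              mean(cl$hgt$cpm) - mean(cl$native$cpm),
              extra = list(mean_hgt = mean(cl$hgt$cpm),
                           mean_native = mean(cl$native$cpm)))
}

#' Benjamini-Hochberg step-up adjustment
#'
#' False-discovery-rate step-up adjustment with monotone enforcement; the
#' mapping back to input order is preserved.
#'
#' @param p_values Numeric vector of p-values in \[0, 1\].
#' @return Adjusted p-values in input order.
#' @export
benjamini_hochberg <- function(p_values) {
  if (any(is.na(p_values)) || any(p_values < 0 | p_values > 1)) {
    stop("p-values must lie in [0, 1]")
  }
  stats::p.adjust(p_values, method = "BH")
}

split_go <- function(go) {
  if (is.list(go)) return(go)
  strsplit(ifelse(is.na(go), "", go), ";", fixed = TRUE)
}

#' GO-term enrichment of HGT candidates against native genes
#'
#' For every GO term occurring at least `min_occurrence` times among the
#' HGT genes, a 2x2 Fisher's exact test compares term membership between
#' the HGT and native gene sets; p-values are Benjamini-Hochberg adjusted
#' across all tested terms. The gene universe is all genes supplied
#' (pool species before calling for a global test).
#'
#' @param genes Gene table with a `go_terms` column (semicolon-separated
#'   string or list of character vectors).
#' @param min_occurrence Minimum occurrences of a term among HGT genes for
#'   it to be tested; rarer terms are excluded.
#' @return `data.frame` with one row per tested term: `term`, `n_hgt`,
#'   `n_native`, `p_value`, `p_adjusted`, `effect` (difference in term
#'   frequency). Empty (with a warning) when nothing passes the filter.
#' @export
go_enrichment <- function(genes, min_occurrence = 2) {
  cl <- split_classes(genes)
  go_h <- split_go(cl$hgt$go_terms)
  go_n <- split_go(cl$native$go_terms)
  counts_h <- table(unlist(go_h))
  terms <- names(counts_h)[counts_h >= min_occurrence]
  if (!length(terms)) {
    warning("no GO term passes min_occurrence among HGT genes")
    return(data.frame(term = character(), n_hgt = integer(),
                      n_native = integer(), p_value = numeric(),
                      p_adjusted = numeric(), effect = numeric()))
  }
  counts_n <- table(unlist(go_n))
  nh <- length(go_h); nn <- length(go_n)
  res <- do.call(rbind, lapply(terms, function(tm) {
    a <- unname(counts_h[tm])
    b <- if (tm %in% names(counts_n)) unname(counts_n[tm]) else 0L
    tab <- matrix(c(a, nh - a, b, nn - b), nrow = 2, byrow = TRUE)
    data.frame(term = tm, n_hgt = a, n_native = b,
               p_value = stats::fisher.test(tab)$p.value,
               effect = a / nh - b / nn,
               stringsAsFactors = FALSE)
  }))
  res$p_adjusted <- benjamini_hochberg(res$p_value)
  res <- res[order(res$p_value, res$term), c("term", "n_hgt", "n_native",
                                             "p_value", "p_adjusted", "effect")]
  rownames(res) <- NULL
  res
}

#' Run the full per-species feature-statistics suite
#'
#' Applies [gc_compare()], [exon_class_test()], [exon_count_test()] and
#' [expression_compare()] to each species in the gene table, plus a pooled
#' [go_enrichment()] when GO terms are present.
#'
#' @param genes Full gene table.
#' @param thresholds An [hgt_thresholds()] object (`alpha`, `n_bootstrap`).
#' @param seed Optional seed for the permutation test.
#' @return List with `per_species` (named list of `stat_result` lists) and
#'   `go` (enrichment table or `NULL`).
#' @export
feature_stats_suite <- function(genes, thresholds = hgt_thresholds(),
                                seed = NULL) {
  per_species <- lapply(split(genes, genes$species), function(g) {
    res <- list()
    res$gc <- tryCatch(gc_compare(g), error = function(e) NULL)
    res$exon_class <- tryCatch(exon_class_test(g), error = function(e) NULL)
    res$exon_count <- tryCatch(
      exon_count_test(g, n_bootstrap = thresholds$n_bootstrap, seed = seed),
      error = function(e) NULL)
    res$expression <- tryCatch(expression_compare(g), error = function(e) NULL)
    res
  })
  go <- if ("go_terms" %in% names(genes)) {
    tryCatch(go_enrichment(genes), warning = function(w) NULL)
  }
  list(per_species = per_species, go = go)
}
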