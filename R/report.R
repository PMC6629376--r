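# Pipeline orchestration and headline summary numbers.

#' Mean HGT gene count per strain
#'
#' @param per_strain_counts Numeric vector of per-strain HGT gene counts.
#' @return Arithmetic mean rounded to 1 decimal.
#' @examples
#' strain_mean_hgt(c(10, 10)) # 10
#' @export
strain_mean_hgt <- function(per_strain_counts) {
  if (!length(per_strain_counts)) stop("need at least one strain")
  round(mean(per_strain_counts), 1)
}

#' Headline summary of an HGT classification run
#'
#' Computes the quantities a pipeline report leads with: the number and
#' percentage of HGT orthogroups, per-pattern counts, the per-strain HGT
#' orthogroup counts (from the presence matrix), the implied transfer
#' rate in Ma per event given a lineage age, and the co-localization
#' fraction when a screen result is supplied. Every percentage is
#' recomputable from the integer counts in the same summary, which
#' `print` verifies.
#'
#' @param calls Calls `data.frame` from [classify_trees()].
#' @param coloc Optional `coloc_result`.
#' @param age_ma Lineage age in Ma used for the transfer rate.
#' @param strains Strain panel (defaults to the 13 Cyanidiales strains).
#' @return List of class `pipeline_summary`.
#' @export
summarize_pipeline <- function(calls, coloc = NULL, age_ma = 1400,
                               strains = cyanidiales_strains()$strain) {
  if (!is.data.frame(calls)) calls <- calls_to_frame(calls)
  n_total <- nrow(calls)
  hgt <- calls[calls$status == "hgt", , drop = FALSE]
  n_hgt <- nrow(hgt)
  pm <- presence_matrix(calls, strains)
  per_strain <- colSums(pm)
  pattern_counts <- table(factor(hgt$pattern, levels = c(
    "shared_ancient", "galdieria_exclusive", "replacement_galdieria",
    "cyanidioschyzon_exclusive", "replacement_cyanidioschyzon",
    "multiple_hgt", "uncertain")))
  status_counts <- table(calls$status)
  structure(
    list(
      n_ogs_total = n_total,
      n_hgt_ogs = n_hgt,
      hgt_og_percent = round(100 * n_hgt / n_total, 2),
      n_hgt_genes = sum(vapply(strsplit(hgt$focal_leaves, ";", fixed = TRUE),
                               length, integer(1))),
      pattern_counts = pattern_counts,
      status_counts = status_counts,
      per_strain_hgt = per_strain,
      strain_mean = strain_mean_hgt(per_strain),
      coloc_fraction = if (!is.null(coloc)) round(coloc$fraction, 2) else NA_real_,
      age_ma = age_ma,
      rate_ma_per_event = if (n_hgt > 0) round(age_ma / n_hgt, 1) else NA_real_
    ),
    class = "pipeline_summary"
  )
}

#' @export
print.pipeline_summary <- function(x, ...) {
  stopifnot(isTRUE(all.equal(x$hgt_og_percent,
                             round(100 * x$n_hgt_ogs / x$n_ogs_total, 2))))
  cat(sprintf("HGT pipeline summary: %d/%d orthogroups called HGT (%.2f%%)\n",
              x$n_hgt_ogs, x$n_ogs_total, x$hgt_og_percent))
  cat(sprintf("  %d HGT gene candidates; mean %.1f HGT orthogroups per strain\n",
              x$n_hgt_genes, x$strain_mean))
  if (!is.na(x$rate_ma_per_event)) {
    cat(sprintf("  one transfer every %.1f Ma over %g Ma\n",
                x$rate_ma_per_event, x$age_ma))
  }
  if (!is.na(x$coloc_fraction)) {
    cat(sprintf("  %.2f%% of candidates co-localize with native genes on reads\n",
                x$coloc_fraction))
  }
  pats <- x$pattern_counts[x$pattern_counts > 0]
  if (length(pats)) {
    cat("  patterns:", paste(sprintf("%s=%d", names(pats), pats),
                             collapse = ", "), "\n")
  }
  invisible(x)
}

#' Run the simulated end-to-end pipeline
#'
#' Simulates orthogroup trees, classifies them, simulates and screens read
#' alignments, runs the feature statistics and the PID cumulative-effects
#' suite, and (optionally) writes every table to a directory. Re-running
#' with the same configuration is byte-identical.
#'
#' @param cfg A [sim_config()].
#' @param thresholds An [hgt_thresholds()] object.
#' @param out_dir Optional output directory for TSV artifacts (created if
#'   needed): `calls.tsv`, `genes.tsv`, `coloc.tsv`, `truth.tsv`,
#'   `pid_summaries.tsv` and `run_log.txt` echoing seed and thresholds.
#' @return List with `calls`, `truth`, `summary`, `coloc`, `stats`,
#'   `pid_summaries`, `cumulative`.
#' @export
run_hgt_pipeline <- function(cfg = sim_config(), thresholds = hgt_thresholds(),
                             out_dir = NULL) {
  sim <- simulate_og_trees(cfg)
  calls <- classify_trees(sim$trees, thresholds)
  genes <- simulate_gene_table(cfg, seed = cfg$seed + 1L)
  stats_suite <- feature_stats_suite(genes, thresholds, seed = cfg$seed + 2L)
  aln <- simulate_read_alignments(cfg, contamination_fraction = 0,
                                  n_hgt = 200, n_native = 500,
                                  seed = cfg$seed + 3L)
  coloc <- screen_colocalization(aln$alignments, aln$hgt_ids, aln$native_ids,
                                 thresholds)
  pid <- simulate_pid_tables(cfg, seed = cfg$seed + 4L)
  cumulative <- cumulative_effects_suite(pid, n_perm = thresholds$n_bootstrap,
                                         seed = cfg$seed + 5L)
  summary <- summarize_pipeline(calls, coloc)
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    write_calls(calls, file.path(out_dir, "calls.tsv"))
    write_gene_table(genes, file.path(out_dir, "genes.tsv"))
    coloc_report(coloc, file.path(out_dir, "coloc.tsv"))
    write_tsv(sim$truth, file.path(out_dir, "truth.tsv"))
    write_tsv(pid, file.path(out_dir, "pid_summaries.tsv"))
    log <- c(sprintf("cyanihgt %s", as.character(utils::packageVersion("cyanihgt"))),
             sprintf("seed\t%d", cfg$seed),
             sprintf("%s\t%g", names(unclass(thresholds)),
                     unlist(thresholds)))
    writeLines(log, file.path(out_dir, "run_log.txt"))
  }
  list(calls = calls, truth = sim$truth, summary = summary, coloc = coloc,
       stats = stats_suite, pid_summaries = pid, cumulative = cumulative)
}
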