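#' Threshold configuration for the HGT detection pipeline
#'
#' Bundles every numeric cutoff used across the pipeline stages: the
#' similarity-search e-value cutoff, the per-database-volume hit cap, the
#' taxonomic genera budget used for hit balancing, the minimum number of
#' focal (Cyanidiales) sequences and non-eukaryotic donor species a gene
#' tree must show before it can be called HGT, the ultrafast-bootstrap
#' support floor, the percent-identity threshold of the seventy-percent-rule
#' audit, and the read-screen bitscore floor.
#'
#' @param evalue_cutoff Maximum e-value retained when reading hit tables.
#' @param hits_per_volume Top-N hits kept per database volume before merging.
#' @param genera_budget Total genera budget divided among phyla when
#'   balancing hits (cap per phylum = `floor(budget / n_phyla)`, at least 1).
#' @param min_focal_sequences Minimum distinct focal strains in the
#'   candidate clade for an HGT call (candidates below this are singletons).
#' @param min_donor_taxa Minimum distinct non-eukaryotic donor species.
#' @param min_support Ultrafast-bootstrap support floor in percent; two or
#'   more consecutive nodes below it reject the tree.
#' @param pid_rule_threshold Percent-identity threshold audited by
#'   [seventy_rule_audit()].
#' @param alpha Nominal significance level for the statistics suite.
#' @param n_bootstrap Resamples for permutation null distributions.
#' @param tblastn_min_bitscore Bitscore floor for read alignments in the
#'   co-localization screen.
#' @param donor_neighborhood_depth How many successive outer clades around a
#'   focal clade are collected as the donor neighborhood: 1 = sister only,
#'   2 = sister plus one (default).
#'
#' @return An object of class `hgt_thresholds` (a named list).
#' @examples
#' th <- hgt_thresholds()
#' th$min_donor_taxa
#' @export
hgt_thresholds <- function(evalue_cutoff = 1e-5,
                           hits_per_volume = 2000,
                           genera_budget = 180,
                           min_focal_sequences = 2,
                           min_donor_taxa = 3,
                           min_support = 70,
                           pid_rule_threshold = 70,
                           alpha = 0.05,
                           n_bootstrap = 1000,
                           tblastn_min_bitscore = 75,
                           donor_neighborhood_depth = 2) {
  th <- list(
    evalue_cutoff = evalue_cutoff,
    hits_per_volume = hits_per_volume,
    genera_budget = genera_budget,
    min_focal_sequences = min_focal_sequences,
    min_donor_taxa = min_donor_taxa,
    min_support = min_support,
    pid_rule_threshold = pid_rule_threshold,
    alpha = alpha,
    n_bootstrap = n_bootstrap,
    tblastn_min_bitscore = tblastn_min_bitscore,
    donor_neighborhood_depth = donor_neighborhood_depth
  )
  num <- vapply(th, is.numeric, logical(1))
  if (!all(num)) stop("all thresholds must be numeric")
  if (any(unlist(th) <= 0)) stop("all thresholds must be strictly positive")
  for (f in c("min_support", "pid_rule_threshold")) {
    if (th[[f]] > 100) stop(sprintf("%s must lie in (0, 100]", f))
  }
  if (!th$donor_neighborhood_depth %in% c(1, 2)) {
    stop("donor_neighborhood_depth must be 1 (sister only) or 2 (sister plus one)")
  }
  structure(th, class = "hgt_thresholds")
}

#' @export
print.hgt_thresholds <- function(x, ...) {
  cat("HGT pipeline thresholds\n")
  for (nm in names(x)) cat(sprintf("  %-25s %g\n", nm, x[[nm]]))
  invisible(x)
}
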