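# Long-read co-localization screen: an HGT candidate supported only by
# reads that never also carry a native gene is flagged as potential
# contamination.

#' Screen HGT candidates for co-localization with native genes on reads
#'
#' Alignments are filtered at both the e-value cutoff and the bitscore
#' floor; a candidate is co-localized when at least one retained read
#' carries both the candidate and a native gene. Candidates with no
#' retained alignments at all are listed separately (`no_data`), which
#' distinguishes "no evidence" from "contradicted".
#'
#' @param alignments `data.frame` of read alignments with columns
#'   `read_id`, `gene_id`, `bitscore`, `evalue` (tblastn tabular style).
#' @param hgt_ids Character vector of HGT candidate gene ids.
#' @param native_ids Character vector of native gene ids; must be disjoint
#'   from `hgt_ids`.
#' @param thresholds An [hgt_thresholds()] object (`evalue_cutoff`,
#'   `tblastn_min_bitscore`).
#' @return An object of class `coloc_result`: list with `per_candidate`
#'   (`data.frame`: candidate_id, n_supporting_reads, co_localized,
#'   no_data), `n_candidates`, `n_colocalized`, `fraction` (percent),
#'   `n_coloc_reads` (distinct reads carrying at least one HGT and one
#'   native hit) and `no_data` ids.
#' @export
screen_colocalization <- function(alignments, hgt_ids, native_ids,
                                  thresholds = hgt_thresholds()) {
  if (length(intersect(hgt_ids, native_ids))) {
    stop("hgt_ids and native_ids must be disjoint")
  }
  if (!length(hgt_ids)) stop("empty candidate set")
  keep <- alignments$evalue <= thresholds$evalue_cutoff &
    alignments$bitscore >= thresholds$tblastn_min_bitscore
  aln <- alignments[keep, , drop = FALSE]
  native_reads <- unique(aln$read_id[aln$gene_id %in% native_ids])
  hgt_aln <- aln[aln$gene_id %in% hgt_ids, , drop = FALSE]
  supp <- tapply(hgt_aln$read_id, hgt_aln$gene_id,
                 function(r) unique(r[r %in% native_reads]), simplify = FALSE)
  n_reads_any <- tapply(hgt_aln$read_id, hgt_aln$gene_id,
                        function(r) length(unique(r)))
  per <- data.frame(
    candidate_id = sort(hgt_ids),
    stringsAsFactors = FALSE
  )
  per$n_supporting_reads <- vapply(per$candidate_id, function(g) {
    s <- supp[[g]]
    if (is.null(s)) 0L else length(s)
  }, integer(1))
  per$no_data <- !(per$candidate_id %in% names(n_reads_any))
  per$co_localized <- per$n_supporting_reads >= 1L
  rownames(per) <- NULL
  n_coloc_reads <- length(intersect(unique(hgt_aln$read_id), native_reads))
  structure(
    list(per_candidate = per,
         n_candidates = length(hgt_ids),
         n_colocalized = sum(per$co_localized),
         fraction = 100 * sum(per$co_localized) / length(hgt_ids),
         n_coloc_reads = n_coloc_reads,
         no_data = per$candidate_id[per$no_data]),
    class = "coloc_result"
  )
}

#' Report a co-localization screen as TSV plus a summary line
#'
#' @param result A `coloc_result` from [screen_colocalization()].
#' @param path Optional path for the per-candidate TSV (sorted by
#'   candidate id; deterministic).
#' @return The summary line, e.g. `"629/641 (98.12%)"`, invisibly when a
#'   path is written.
#' @export
coloc_report <- function(result, path = NULL) {
  stopifnot(inherits(result, "coloc_result"))
  if (result$n_candidates == 0) stop("empty candidate set")
  line <- sprintf("%d/%d (%.2f%%)", result$n_colocalized,
                  result$n_candidates, result$fraction)
  if (!is.null(path)) {
    write_tsv(result$per_candidate, path)
    return(invisible(line))
  }
  line
}

#' @export
print.coloc_result <- function(x, ...) {
  cat("Read co-localization screen:", coloc_report(x), "co-localized\n")
  cat(sprintf("  %d distinct co-localization reads; %d candidate(s) with no alignments\n",
              x$n_coloc_reads, length(x$no_data)))
  invisible(x)
}
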