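#' Merge per-volume hit lists into one bitscore-sorted list
#'
#' Each database volume (bacteria, metazoa, remaining taxa, MMETSP) is
#' queried independently; its hits are truncated to the top
#' `cap_per_volume` by bitscore before merging, the merged list is sorted
#' by descending bitscore, and duplicate subjects are collapsed keeping the
#' highest-scoring occurrence. Ties in bitscore are broken by ascending
#' e-value, then lexicographic subject id, so the result is deterministic.
#'
#' @param per_volume_hits Named list of hit `data.frame`s (as from
#'   [read_hit_table()]), one per volume. Empty volumes are allowed.
#' @param cap_per_volume Top-N cap applied per volume before merging.
#' @return A single merged hit `data.frame` with a `volume` column.
#' @export
merge_volumes <- function(per_volume_hits, cap_per_volume = 2000) {
  stopifnot(cap_per_volume >= 1)
  kept <- lapply(names(per_volume_hits), function(v) {
    h <- per_volume_hits[[v]]
    if (is.null(h) || !nrow(h)) return(NULL)
    h <- h[hit_order(h), , drop = FALSE]
    h <- utils::head(h, cap_per_volume)
    h$volume <- v
    h
  })
  merged <- do.call(rbind, kept)
  if (is.null(merged)) {
    return(data.frame(sseqid = character(), bitscore = numeric()))
  }
  merged <- merged[hit_order(merged), , drop = FALSE]
  merged <- merged[!duplicated(merged$sseqid), , drop = FALSE]
  rownames(merged) <- NULL
  merged
}

hit_order <- function(h) {
  order(-h$bitscore, h$evalue, h$sseqid, method = "radix")
}

#' Per-phylum genera cap for taxonomically balanced hit selection
#'
#' The genera budget is divided evenly among the unique phyla observed in
#' the merged hit list: `floor(budget / n_unique_phyla)`, clamped to at
#' least one genus per phylum.
#'
#' @param n_unique_phyla Number of distinct phyla in the hit list (>= 1).
#' @param budget Total genera budget (default 180).
#' @return Integer cap on distinct genera admitted per phylum.
#' @examples
#' phylum_genus_cap(4, 180) # 45
#' @export
phylum_genus_cap <- function(n_unique_phyla, budget = 180) {
  if (n_unique_phyla < 1) stop("n_unique_phyla must be >= 1")
  max(1L, as.integer(budget %/% n_unique_phyla))
}

#' Select a taxonomically balanced hit set
#'
#' Walks the bitscore-sorted hit list and admits a hit if its phylum has
#' admitted fewer than the per-phylum cap of distinct genera, or if its
#' genus is already admitted for that phylum (all hits of an admitted genus
#' remain eligible: the cap limits genera, not sequences). Phyla are
#' counted from the full input list; genus identity is the (phylum, genus)
#' pair. Hits with an empty phylum are assigned the sentinel phylum
#' `"unclassified"` and reported via `message()`.
#'
#' @param hits Merged hit `data.frame` sorted by descending bitscore (as
#'   from [merge_volumes()]); must carry `phylum` and `genus` columns.
#' @param budget Total genera budget; see [phylum_genus_cap()].
#' @param one_per_species Retain only the best-bitscore sequence per
#'   subject species after genus balancing (the representative set passed
#'   on to alignment).
#' @return An object of class `balanced_hits`: list with `selected` (hit
#'   rows admitted, in bitscore order), `per_phylum_cap`, `phyla_seen` and
#'   `query_id`.
#' @export
balance_hits <- function(hits, budget = 180, one_per_species = FALSE) {
  if (!nrow(hits)) {
    return(structure(list(selected = hits, per_phylum_cap = NA_integer_,
                          phyla_seen = character(), query_id = NA_character_),
                     class = "balanced_hits"))
  }
  hits <- hits[hit_order(hits), , drop = FALSE]
  empty <- is.na(hits$phylum) | !nzchar(hits$phylum)
  if (any(empty)) {
    message(sprintf("balance_hits: %d hit(s) with empty phylum assigned to 'unclassified'",
                    sum(empty)))
    hits$phylum[empty] <- "unclassified"
  }
  phyla <- unique(hits$phylum)
  cap <- phylum_genus_cap(length(phyla), budget)
  admitted_genera <- new.env(parent = emptyenv())
  count <- stats::setNames(integer(length(phyla)), phyla)
  take <- logical(nrow(hits))
  for (i in seq_len(nrow(hits))) {
    ph <- hits$phylum[i]
    key <- paste0(ph, "\r", hits$genus[i])
    if (!is.null(admitted_genera[[key]])) {
      take[i] <- TRUE
    } else if (count[[ph]] < cap) {
      admitted_genera[[key]] <- TRUE
      count[[ph]] <- count[[ph]] + 1L
      take[i] <- TRUE
    }
  }
  sel <- hits[take, , drop = FALSE]
  if (one_per_species) sel <- sel[!duplicated(sel$species), , drop = FALSE]
  rownames(sel) <- NULL
  structure(
    list(selected = sel, per_phylum_cap = cap, phyla_seen = phyla,
         query_id = if ("qseqid" %in% names(hits)) hits$qseqid[1] else NA_character_),
    class = "balanced_hits"
  )
}

#' @export
print.balanced_hits <- function(x, ...) {
  cat(sprintf("balanced_hits: %d of input hits admitted, cap %s genera over %d phyla\n",
              nrow(x$selected), x$per_phylum_cap, length(x$phyla_seen)))
  invisible(x)
}
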