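#' Read a Newick gene tree with bootstrap supports and bind taxonomy
#'
#' Internal node labels, when present, are interpreted as ultrafast
#' bootstrap percentages (integers 0-100). Unlabeled internal nodes get
#' missing support, which downstream support filters treat as passing (a
#' warning notes this once per tree). Unrooted trees are midpoint-rooted,
#' carrying the supports along, and the rooting method is recorded because
#' the nesting classification depends on it.
#'
#' @param path Path to a Newick file, or a Newick string (must end in
#'   `";"`).
#' @param taxonomy A [taxon_table()] covering every leaf, or `NULL` to fall
#'   back on the `A_`/`B_`/`E_` label-prefix convention.
#' @return An object of class `support_tree`: a list with elements `phylo`
#'   (an [ape::read.tree()] tree), `support` (integer vector over internal
#'   nodes, `NA` = missing), `taxonomy` (rows ordered as `tip.label`) and
#'   `rooting` (`"as-supplied"` or `"midpoint"`).
#' @export
read_newick_with_supports <- function(path, taxonomy = NULL) {
  if (length(path) == 1 && grepl(";[[:space:]]*$", path) && !file.exists(path)) {
    phy <- ape::read.tree(text = path)
  } else {
    phy <- ape::read.tree(path)
  }
  if (is.null(phy)) stop("malformed Newick input: ", path)
  support_tree(phy, taxonomy)
}

#' Construct a support tree from an ape phylo object
#'
#' @param phy An [ape::read.tree()] `phylo` object whose `node.label`, when
#'   present, hold integer supports 0-100.
#' @inheritParams read_newick_with_supports
#' @return A `support_tree`; see [read_newick_with_supports()].
#' @export
support_tree <- function(phy, taxonomy = NULL) {
  if (!inherits(phy, "phylo")) stop("'phy' must be a phylo object")
  if (ape::Ntip(phy) < 3) stop("tree must have at least 3 leaves")
  rooting <- "as-supplied"
  if (!ape::is.rooted(phy)) {
    phy <- phangorn::midpoint(phy, node.labels = "support")
    rooting <- "midpoint"
    message("unrooted tree midpoint-rooted; nesting calls depend on rooting")
  }
  support <- parse_supports(phy)
  if (is.null(taxonomy)) {
    taxonomy <- taxonomy_from_labels(phy$tip.label)
  } else {
    missing_leaves <- setdiff(phy$tip.label, taxonomy$leaf_id)
    if (length(missing_leaves)) {
      stop("leaf absent from taxonomy map: ",
           paste(missing_leaves, collapse = ", "))
    }
    taxonomy <- taxonomy[match(phy$tip.label, taxonomy$leaf_id), , drop = FALSE]
    rownames(taxonomy) <- NULL
  }
  structure(
    list(phylo = phy, support = support, taxonomy = taxonomy,
         rooting = rooting),
    class = "support_tree"
  )
}

parse_supports <- function(phy) {
  n_node <- phy$Nnode
  lab <- phy$node.label
  if (is.null(lab) || !length(lab)) {
    return(rep(NA_integer_, n_node))
  }
  lab[!nzchar(lab)] <- NA_character_
  sup <- suppressWarnings(as.numeric(lab))
  bad <- !is.na(lab) & (is.na(sup) | sup < 0 | sup > 100 | sup != floor(sup))
  if (any(bad)) {
    stop("internal node label(s) do not parse as integer supports 0-100: ",
         paste(lab[bad], collapse = ", "))
  }
  as.integer(sup)
}

#' @export
print.support_tree <- function(x, ...) {
  cat(sprintf("support_tree: %d leaves (%d focal), %d internal nodes, rooting %s\n",
              ape::Ntip(x$phylo), sum(x$taxonomy$is_focal),
              x$phylo$Nnode, x$rooting))
  if (all(is.na(x$support))) cat("  all internal supports missing\n")
  invisible(x)
}

#' Write a support tree back to Newick
#'
#' Supports are serialized as internal node labels; missing supports become
#' empty labels. Round-trips with [read_newick_with_supports()].
#'
#' @param tree A `support_tree`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_newick_with_supports <- function(tree, path) {
  phy <- tree$phylo
  phy$node.label <- ifelse(is.na(tree$support), "", as.character(tree$support))
  ape::write.tree(phy, file = path)
  invisible(path)
}

#' Read a tabular similarity-search hit table
#'
#' Expects the 12 standard tabular columns (qseqid, sseqid, pident, length,
#' mismatch, gapopen, qstart, qend, sstart, send, evalue, bitscore) plus
#' taxonomy columns `kingdom`, `phylum`, `genus`, `species`, and optionally
#' `volume` (which database volume the hit came from). Rows with e-value
#' above the cutoff are dropped and the number of dropped rows is reported
#' via `message()`.
#'
#' @param path Path to the TSV (header line; `#` comments ignored).
#' @param thresholds An [hgt_thresholds()] object; only `evalue_cutoff` is
#'   used here. The boundary is inclusive: e-value equal to the cutoff is
#'   retained.
#' @return A `data.frame` of hits, sorted as in the file.
#' @export
read_hit_table <- function(path, thresholds = hgt_thresholds()) {
  d <- read_tsv_checked(path)
  std <- c("qseqid", "sseqid", "pident", "length", "mismatch", "gapopen",
           "qstart", "qend", "sstart", "send", "evalue", "bitscore")
  taxo <- c("kingdom", "phylum", "genus", "species")
  miss <- setdiff(c(std, taxo), names(d))
  if (length(miss)) stop("hit table lacks column(s): ", paste(miss, collapse = ", "))
  if (!nrow(d)) return(d)
  for (col in c("evalue", "bitscore")) {
    v <- suppressWarnings(as.numeric(d[[col]]))
    bad <- which(is.na(v) & !is.na(d[[col]]))
    if (length(bad)) {
      stop(sprintf("non-numeric %s at data line %d of %s", col, bad[1], path))
    }
    d[[col]] <- v
  }
  if (!all(is.finite(d$bitscore))) stop("bitscore must be finite")
  keep <- d$evalue <= thresholds$evalue_cutoff
  if (any(!keep)) {
    message(sprintf("read_hit_table: dropped %d of %d rows above e-value cutoff %g",
                    sum(!keep), nrow(d), thresholds$evalue_cutoff))
  }
  d <- d[keep, , drop = FALSE]
  rownames(d) <- NULL
  d
}

#' Read and validate a per-gene feature table
#'
#' Columns: `gene_id`, `species`, `lineage`, `gc_percent`, `exon_count`,
#' `cpm`, `is_hgt`, `og_id`, and optionally `go_terms`
#' (semicolon-separated). Validation enforces unique gene ids, GC content
#' in \[0, 100\] and at least one exon per gene.
#'
#' @param path Path to the TSV.
#' @return A validated `data.frame` of gene records.
#' @export
read_gene_table <- function(path) {
  d <- read_tsv_checked(path)
  need <- c("gene_id", "species", "lineage", "gc_percent", "exon_count",
            "cpm", "is_hgt", "og_id")
  miss <- setdiff(need, names(d))
  if (length(miss)) stop("gene table lacks column(s): ", paste(miss, collapse = ", "))
  d$is_hgt <- as.logical(d$is_hgt)
  validate_gene_table(d)
  d
}

validate_gene_table <- function(d) {
  if (anyDuplicated(d$gene_id)) {
    stop("duplicate gene_id: ",
         paste(unique(d$gene_id[duplicated(d$gene_id)]), collapse = ", "))
  }
  if (any(d$gc_percent < 0 | d$gc_percent > 100)) {
    stop("gc_percent outside [0, 100]")
  }
  if (any(d$exon_count < 1 | d$exon_count != floor(d$exon_count))) {
    stop("exon_count must be an integer >= 1")
  }
  if (any(d$cpm < 0)) stop("cpm must be non-negative")
  invisible(d)
}

#' Write a gene table deterministically
#'
#' Rows are sorted by `og_id`, then `gene_id`, so that writes are
#' byte-reproducible and round-trip losslessly with [read_gene_table()].
#'
#' @param genes Gene table `data.frame`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_gene_table <- function(genes, path) {
  validate_gene_table(genes)
  genes <- genes[order(genes$og_id, genes$gene_id), , drop = FALSE]
  write_tsv(genes, path)
  invisible(path)
}

#' Write per-orthogroup HGT calls to TSV
#'
#' Set-valued fields (focal leaves, donor species and phyla) are serialized
#' semicolon-separated; rows sorted by orthogroup id for determinism.
#'
#' @param calls A `data.frame` of calls as returned by [classify_trees()],
#'   or a list of `hgt_call` objects.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_calls <- function(calls, path) {
  if (!is.data.frame(calls)) calls <- calls_to_frame(calls)
  calls <- calls[order(calls$og_id), , drop = FALSE]
  write_tsv(calls, path)
  invisible(path)
}

#' Read per-orthogroup HGT calls written by [write_calls()]
#' @param path Path to the calls TSV.
#' @return A `data.frame` of calls.
#' @export
read_calls <- function(path) {
  d <- read_tsv_checked(path)
  for (col in c("focal_leaves", "focal_strains", "donor_taxa", "donor_phyla")) {
    if (col %in% names(d)) d[[col]][is.na(d[[col]])] <- ""
  }
  d
}
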