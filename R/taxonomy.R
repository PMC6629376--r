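#' Construct a leaf-level taxonomy table
#'
#' Each row binds one gene-tree leaf to its taxonomic context: kingdom
#' (`A` = Archaea, `B` = Bacteria, `E` = Eukaryota), phylum, genus, species,
#' whether the leaf belongs to the focal eukaryotic group (the Cyanidiales),
#' its focal lineage (`galdieria`, `cyanidioschyzon`, or `other`), strain,
#' and flags used by the endosymbiotic-gene-transfer exclusion rules.
#'
#' @param leaf_id Character vector of unique leaf labels.
#' @param kingdom One of `"A"`, `"B"`, `"E"` per leaf.
#' @param species,genus,phylum Taxonomic names (species defaults to the
#'   leaf id stripped of its kingdom prefix).
#' @param is_focal Logical: member of the focal group.
#' @param lineage `"galdieria"`, `"cyanidioschyzon"`, or `"other"`.
#' @param strain Strain identifier for focal leaves.
#' @param is_cyanobacteria,is_chlamydiae,is_photosynthetic_eukaryote
#'   Logical flags consumed by the EGT rules.
#'
#' @return A `data.frame` of class `taxon_table`.
#' @export
taxon_table <- function(leaf_id,
                        kingdom,
                        species = NULL,
                        genus = NULL,
                        phylum = NULL,
                        is_focal = FALSE,
                        lineage = "other",
                        strain = NA_character_,
                        is_cyanobacteria = FALSE,
                        is_chlamydiae = FALSE,
                        is_photosynthetic_eukaryote = FALSE) {
  n <- length(leaf_id)
  if (anyDuplicated(leaf_id)) {
    stop("duplicate leaf_id: ",
         paste(unique(leaf_id[duplicated(leaf_id)]), collapse = ", "))
  }
  if (is.null(species)) species <- sub("^[ABE]_", "", leaf_id)
  if (is.null(genus)) genus <- species
  if (is.null(phylum)) phylum <- rep("unclassified", n)
  tax <- data.frame(
    leaf_id = as.character(leaf_id),
    kingdom = as.character(kingdom),
    species = rep_len(as.character(species), n),
    genus = rep_len(as.character(genus), n),
    phylum = rep_len(as.character(phylum), n),
    is_focal = rep_len(as.logical(is_focal), n),
    lineage = rep_len(as.character(lineage), n),
    strain = rep_len(as.character(strain), n),
    is_cyanobacteria = rep_len(as.logical(is_cyanobacteria), n),
    is_chlamydiae = rep_len(as.logical(is_chlamydiae), n),
    is_photosynthetic_eukaryote = rep_len(as.logical(is_photosynthetic_eukaryote), n),
    stringsAsFactors = FALSE
  )
  validate_taxon_table(tax)
  class(tax) <- c("taxon_table", "data.frame")
  tax
}

validate_taxon_table <- function(tax) {
  if (!all(tax$kingdom %in% c("A", "B", "E"))) {
    stop("kingdom must be one of 'A', 'B', 'E'")
  }
  if (!all(tax$lineage %in% c("galdieria", "cyanidioschyzon", "other"))) {
    stop("lineage must be 'galdieria', 'cyanidioschyzon' or 'other'")
  }
  if (any(tax$is_focal & tax$kingdom != "E")) {
    stop("focal leaves must be eukaryotic (kingdom 'E')")
  }
  if (any(tax$is_cyanobacteria & tax$kingdom != "B")) {
    stop("cyanobacteria must be bacterial (kingdom 'B')")
  }
  if (any(tax$lineage != "other" & !tax$is_focal)) {
    stop("a named focal lineage implies is_focal")
  }
  invisible(tax)
}

#' Derive a taxonomy table from kingdom-prefixed leaf labels
#'
#' Fallback used when no explicit taxonomy is supplied: the first letter of
#' each tip label names the kingdom (`A_`/`B_`/`E_` prefix convention).
#' Focal membership and lineages cannot be inferred this way and default to
#' non-focal; supply an explicit table whenever focal calls are needed.
#'
#' @param labels Character vector of tip labels, each starting `A_`, `B_`
#'   or `E_`.
#' @return A `taxon_table`.
#' @export
taxonomy_from_labels <- function(labels) {
  pref <- substr(labels, 1, 2)
  bad <- !pref %in% c("A_", "B_", "E_")
  if (any(bad)) {
    stop("cannot infer kingdom for leaf label(s): ",
         paste(labels[bad], collapse = ", "))
  }
  taxon_table(leaf_id = labels, kingdom = substr(labels, 1, 1))
}

#' Read a taxonomy table from TSV
#'
#' @param path Path to a tab-separated file with a header line; lines
#'   starting with `#` are ignored. Must contain at least `leaf_id` and
#'   `kingdom`; missing optional columns are filled with defaults.
#' @return A `taxon_table`.
#' @export
read_taxonomy <- function(path) {
  d <- read_tsv_checked(path)
  need <- c("leaf_id", "kingdom")
  miss <- setdiff(need, names(d))
  if (length(miss)) stop("taxonomy file lacks column(s): ", paste(miss, collapse = ", "))
  get <- function(col, default) if (col %in% names(d)) d[[col]] else default
  taxon_table(
    leaf_id = d$leaf_id,
    kingdom = d$kingdom,
    species = get("species", NULL),
    genus = get("genus", NULL),
    phylum = get("phylum", NULL),
    is_focal = as.logical(get("is_focal", FALSE)),
    lineage = get("lineage", "other"),
    strain = get("strain", NA_character_),
    is_cyanobacteria = as.logical(get("is_cyanobacteria", FALSE)),
    is_chlamydiae = as.logical(get("is_chlamydiae", FALSE)),
    is_photosynthetic_eukaryote = as.logical(get("is_photosynthetic_eukaryote", FALSE))
  )
}

# shared TSV reader: header line, '#' comments skipped
read_tsv_checked <- function(path) {
  utils::read.delim(path, header = TRUE, sep = "\t", comment.char = "#",
                    stringsAsFactors = FALSE, check.names = FALSE,
                    blank.lines.skip = TRUE)
}

write_tsv <- function(d, path) {
  utils::write.table(d, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE)
}
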