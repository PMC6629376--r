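# Shared fixture builders: small hand-made taxonomies and trees.

# taxonomy for leaves named E_gal*, E_cya* (focal), E_* (other eukaryotes,
# optionally photosynthetic via phot=), B_*/A_* (prokaryotes); phylum and
# EGT flags can be overridden per leaf id.
fixture_taxonomy <- function(leaves, phylum = NULL, cyano = character(),
                             chlam = character(), phot = character()) {
  kingdom <- substr(leaves, 1, 1)
  focal <- grepl("^E_(gal|cya)", leaves)
  lineage <- ifelse(grepl("^E_gal", leaves), "galdieria",
                    ifelse(grepl("^E_cya", leaves), "cyanidioschyzon", "other"))
  ph <- rep("unclassified", length(leaves))
  ph[kingdom %in% c("A", "B")] <- "Firmicutes"
  ph[leaves %in% cyano] <- "Cyanobacteria"
  ph[leaves %in% chlam] <- "Chlamydiae"
  if (!is.null(phylum)) ph[match(names(phylum), leaves)] <- phylum
  taxon_table(
    leaf_id = leaves, kingdom = kingdom,
    species = sub("^[ABE]_", "", leaves),
    phylum = ph, is_focal = focal, lineage = lineage,
    strain = ifelse(focal, sub("^E_", "", leaves), NA_character_),
    is_cyanobacteria = leaves %in% cyano,
    is_chlamydiae = leaves %in% chlam,
    is_photosynthetic_eukaryote = leaves %in% phot
  )
}

fixture_tree <- function(newick, ...) {
  leaves <- ape::read.tree(text = newick)$tip.label
  read_newick_with_supports(newick, fixture_taxonomy(leaves, ...))
}

# random tree with random kingdoms/supports for oracle-equivalence sweeps
random_support_tree <- function(n_leaves = 15, n_focal = 3, p_na_support = 0.1) {
  phy <- ape::rtree(n_leaves)
  kingdom <- sample(c("A", "B", "E"), n_leaves, replace = TRUE,
                    prob = c(0.1, 0.5, 0.4))
  focal_idx <- sample(n_leaves, n_focal)
  kingdom[focal_idx] <- "E"
  lin <- sample(c("gal", "cya"), n_leaves, replace = TRUE, prob = c(0.8, 0.2))
  labels <- sprintf("%s_sp%02d", kingdom, seq_len(n_leaves))
  labels[focal_idx] <- sprintf("E_%s%02d", lin[focal_idx], focal_idx)
  phy$tip.label <- labels
  sup <- sample(40:100, phy$Nnode, replace = TRUE)
  sup[runif(phy$Nnode) < p_na_support] <- NA
  phy$node.label <- ifelse(is.na(sup), "", as.character(sup))
  cyano <- labels[kingdom == "B" & runif(n_leaves) < 0.15]
  phot <- labels[!seq_len(n_leaves) %in% focal_idx & kingdom == "E" &
                   runif(n_leaves) < 0.2]
  tax <- fixture_taxonomy(labels, cyano = cyano, phot = phot)
  tax$phylum[tax$kingdom %in% c("A", "B") & !tax$is_cyanobacteria] <-
    sample(c("Proteobacteria", "Firmicutes", "Actinobacteria"),
           sum(tax$kingdom %in% c("A", "B") & !tax$is_cyanobacteria),
           replace = TRUE)
  read_newick_with_supports(ape::write.tree(phy), tax)
}

# minimal gene-record frame
fixture_genes <- function(gc_hgt, gc_native, exons_hgt = NULL,
                          exons_native = NULL, cpm_hgt = NULL,
                          cpm_native = NULL) {
  n1 <- length(gc_hgt); n2 <- length(gc_native)
  data.frame(
    gene_id = sprintf("g%04d", seq_len(n1 + n2)),
    species = "Gs074W", lineage = "galdieria",
    gc_percent = c(gc_hgt, gc_native),
    exon_count = c(if (is.null(exons_hgt)) rep(1L, n1) else exons_hgt,
                   if (is.null(exons_native)) rep(1L, n2) else exons_native),
    cpm = c(if (is.null(cpm_hgt)) rep(10, n1) else cpm_hgt,
            if (is.null(cpm_native)) rep(10, n2) else cpm_native),
    is_hgt = rep(c(TRUE, FALSE), c(n1, n2)),
    og_id = "OG1", stringsAsFactors = FALSE
  )
}
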