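# Gene-tree HGT classification: find maximal focal (Cyanidiales) clades,
# characterize what they are nested in, and run the acceptance/rejection
# cascade (singleton, native, EGT exclusion, donor count, bootstrap
# support, split inconsistency, multiple/uncertain HGT, pattern).

n_tips <- function(phy) length(phy$tip.label)

node_children <- function(phy, node) phy$edge[phy$edge[, 1] == node, 2]

node_parent <- function(phy, node) {
  p <- phy$edge[phy$edge[, 2] == node, 1]
  if (length(p)) p else NA_integer_
}

root_node <- function(phy) n_tips(phy) + 1L

node_support <- function(tree, node) {
  nt <- n_tips(tree$phylo)
  if (node <= nt) return(NA_integer_)
  tree$support[node - nt]
}

# tip indices under each node, for all nodes
all_tip_sets <- function(phy) {
  phangorn::Descendants(phy, seq_len(n_tips(phy) + phy$Nnode), type = "tips")
}

#' Maximal monophyletic focal clades of a gene tree
#'
#' Returns the maximal clades whose leaves are all focal (Cyanidiales).
#' A lone focal leaf nested among non-focal taxa is a clade of size one.
#'
#' @param tree A `support_tree`.
#' @return A list of character vectors of leaf ids, one per maximal focal
#'   clade, each with attribute `"node"` giving the clade's node index.
#'   Empty list if the tree has no focal leaves.
#' @export
focal_clades <- function(tree) {
  phy <- tree$phylo
  focal <- tree$taxonomy$is_focal
  tipsets <- all_tip_sets(phy)
  all_focal <- vapply(tipsets, function(s) all(focal[s]), logical(1))
  if (!any(all_focal)) return(list())
  nodes <- which(all_focal)
  maximal <- vapply(nodes, function(nd) {
    p <- node_parent(phy, nd)
    is.na(p) || !all_focal[p]
  }, logical(1))
  lapply(nodes[maximal], function(nd) {
    structure(phy$tip.label[tipsets[[nd]]], node = nd)
  })
}

#' Nesting context of a focal clade
#'
#' Classifies the neighborhood a focal clade is embedded in: the sister
#' clade plus (by default) the next outer clade. `prokaryotic` if every
#' neighborhood leaf is Archaea or Bacteria, `eukaryotic` if all are
#' Eukaryota, `mixed` otherwise. The non-eukaryotic species of the
#' neighborhood are returned as the potential donor set.
#'
#' @param tree A `support_tree`.
#' @param clade A clade as returned by [focal_clades()] (character vector
#'   with a `"node"` attribute) or an internal/tip node index.
#' @param depth Neighborhood depth: 1 = sister only, 2 = sister plus one
#'   outer clade (default).
#' @return A list with `context` (`"prokaryotic"`, `"eukaryotic"`,
#'   `"mixed"`), `donor_taxa` and `donor_phyla` (character), `sister_leaves`,
#'   `neighborhood_leaves`, `path_nodes` (ancestor chain from the clade node
#'   to the neighborhood root) and `sister_nodes`.
#' @export
nesting_context <- function(tree, clade, depth = 2) {
  phy <- tree$phylo
  tax <- tree$taxonomy
  node <- if (is.numeric(clade)) as.integer(clade) else attr(clade, "node")
  if (is.null(node)) stop("clade must carry a 'node' attribute or be a node index")
  if (node == root_node(phy) || length(setdiff(seq_len(n_tips(phy)),
                                               unlist(phangorn::Descendants(phy, node, "tips")))) == 0) {
    stop("clade spans the whole tree: nesting context is unrootable")
  }
  tipsets <- all_tip_sets(phy)
  clade_tips <- tipsets[[node]]
  p1 <- node_parent(phy, node)
  sisters <- setdiff(node_children(phy, p1), node)
  sister_tips <- unique(unlist(tipsets[sisters]))
  nb_root <- p1
  outer_tips <- integer()
  if (depth >= 2 && p1 != root_node(phy)) {
    p2 <- node_parent(phy, p1)
    outer <- setdiff(node_children(phy, p2), p1)
    outer_tips <- unique(unlist(tipsets[outer]))
    nb_root <- p2
  }
  nb_tips <- setdiff(unique(c(sister_tips, outer_tips)), clade_tips)
  kingdoms <- tax$kingdom[nb_tips]
  context <- if (length(kingdoms) == 0) {
    "mixed"
  } else if (all(kingdoms %in% c("A", "B"))) {
    "prokaryotic"
  } else if (all(kingdoms == "E")) {
    "eukaryotic"
  } else {
    "mixed"
  }
  noneuk <- nb_tips[tax$kingdom[nb_tips] != "E"]
  path <- node
  cur <- node
  while (cur != nb_root) {
    cur <- node_parent(phy, cur)
    path <- c(path, cur)
  }
  list(
    context = context,
    donor_taxa = sort(unique(tax$species[noneuk])),
    donor_phyla = sort(unique(tax$phylum[noneuk])),
    sister_leaves = phy$tip.label[setdiff(sister_tips, clade_tips)],
    neighborhood_leaves = phy$tip.label[nb_tips],
    path_nodes = path,
    sister_nodes = sisters
  )
}

# >= 2 consecutive sub-threshold supports along the ancestor chain
has_weak_span <- function(supports, min_support) {
  weak <- !is.na(supports) & supports < min_support
  if (length(weak) < 2) return(FALSE)
  any(weak[-1] & weak[-length(weak)])
}

#' Classify one orthogroup gene tree
#'
#' Runs the full decision cascade, in order: (1) fewer than
#' `min_focal_sequences` distinct focal strains in the candidate clade gives
#' `singleton`; (2) a eukaryotic nesting context gives `native`; (3) a donor
#' neighborhood dominated (>= 50 percent of donor leaves) by cyanobacteria
#' or Chlamydiae, when the cyanobacterium is the closest neighbor, the gene
#' carries a photosynthetic annotation, or photosynthetic eukaryotes
#' elsewhere in the tree hold homologs, gives `egt_excluded`; (4) fewer than
#' `min_donor_taxa` distinct donor species gives `rejected_few_donors`;
#' (5) two or more consecutive nodes under the support floor on the
#' focal-to-donor path give `rejected_low_support`; (6) focal strains
#' scattered over more than two prokaryote-nested clades give
#' `rejected_inconsistent`, while exactly two such clades with different
#' donor phyla give an `hgt` call of pattern `multiple_hgt` (or `uncertain`
#' when the split node fails the support floor); (7) otherwise `hgt`, with
#' the pattern assigned by [assign_pattern()]. Missing supports pass the
#' support filters (with a warning the first time).
#'
#' @param tree A `support_tree`.
#' @param thresholds An [hgt_thresholds()] object.
#' @param egt_flags List with element `photosynthetic_annotation` (flag:
#'   the gene's functional annotation is photosynthetic).
#' @param og_id Orthogroup identifier carried into the call.
#' @return An object of class `hgt_call`: list with `og_id`, `status`,
#'   `reason`, `pattern`, `focal_leaves`, `focal_strains`, `donor_taxa`,
#'   `donor_phyla`, `support_on_path`, `n_focal_strains`.
#' @export
classify_tree <- function(tree, thresholds = hgt_thresholds(),
                          egt_flags = list(photosynthetic_annotation = FALSE),
                          og_id = "OG") {
  stopifnot(inherits(tree, "support_tree"))
  th <- thresholds
  tax <- tree$taxonomy
  if (!any(tax$is_focal)) stop("tree has no focal leaves: ", og_id)
  if (all(tax$is_focal)) stop("all leaves focal; nesting context unrootable: ", og_id)
  clades <- focal_clades(tree)
  ctxs <- lapply(clades, function(cl)
    nesting_context(tree, cl, depth = th$donor_neighborhood_depth))
  pref <- vapply(ctxs, function(cx)
    match(cx$context, c("prokaryotic", "mixed", "eukaryotic")), integer(1))
  sizes <- vapply(clades, length, integer(1))
  ord <- order(pref, -sizes, vapply(clades, function(cl) attr(cl, "node"), integer(1)))
  cand_i <- ord[1]
  cand <- clades[[cand_i]]
  cx <- ctxs[[cand_i]]
  cand_strains <- unique(stats::na.omit(tax$strain[match(cand, tax$leaf_id)]))
  cand_lineages <- unique(tax$lineage[match(cand, tax$leaf_id)])

  sup_chain <- vapply(cx$path_nodes, function(nd) node_support(tree, nd),
                      integer(1))
  sup_sisters <- vapply(cx$sister_nodes, function(nd) node_support(tree, nd),
                        integer(1))
  if (any(is.na(sup_chain[cx$path_nodes > n_tips(tree$phylo)]))) {
    warning("missing internal-node support treated as passing the support filter",
            call. = FALSE)
  }

  call <- list(
    og_id = og_id, status = NA_character_, reason = NA_character_,
    pattern = "none", focal_leaves = as.character(cand),
    focal_strains = cand_strains,
    donor_taxa = cx$donor_taxa, donor_phyla = cx$donor_phyla,
    support_on_path = c(sup_chain, sup_sisters),
    n_focal_strains = length(cand_strains)
  )
  done <- function(status, reason = status, pattern = "none") {
    call$status <- status
    call$reason <- reason
    call$pattern <- pattern
    structure(call, class = "hgt_call")
  }

  # (1) singleton
  if (length(cand_strains) < th$min_focal_sequences) {
    return(done("singleton", "fewer than min_focal_sequences distinct focal strains"))
  }
  # (2) native
  if (cx$context == "eukaryotic") {
    return(done("native", "focal clade nested among eukaryotes"))
  }
  # (3) EGT exclusion
  nb_leaves <- cx$neighborhood_leaves
  nb_tax <- tax[match(nb_leaves, tax$leaf_id), , drop = FALSE]
  donors_nb <- nb_tax[nb_tax$kingdom != "E", , drop = FALSE]
  if (nrow(donors_nb)) {
    frac_egt <- mean(donors_nb$is_cyanobacteria | donors_nb$is_chlamydiae)
    sister_tax <- tax[match(cx$sister_leaves, tax$leaf_id), , drop = FALSE]
    cyano_sister <- any(sister_tax$is_cyanobacteria)
    phot_elsewhere <- any(tax$is_photosynthetic_eukaryote[
      !tax$leaf_id %in% cand])
    if (frac_egt >= 0.5 &&
        (cyano_sister || isTRUE(egt_flags$photosynthetic_annotation) ||
         phot_elsewhere)) {
      return(done("egt_excluded",
                  "donor neighborhood dominated by cyanobacteria/Chlamydiae"))
    }
  }
  # (4) donor count
  if (length(cx$donor_taxa) < th$min_donor_taxa) {
    return(done("rejected_few_donors",
                "fewer than min_donor_taxa distinct donor species"))
  }
  # (5) support span
  if (has_weak_span(sup_chain, th$min_support)) {
    return(done("rejected_low_support",
                "consecutive nodes under the support floor on the focal-to-donor path"))
  }
  # (6) split structure across multiple prokaryote-nested clades
  prok_i <- which(vapply(ctxs, function(z) z$context == "prokaryotic", logical(1)))
  if (length(prok_i) > 2) {
    return(done("rejected_inconsistent",
                "focal strains scattered over more than two prokaryote-nested clades"))
  }
  if (length(prok_i) == 2) {
    d1 <- ctxs[[prok_i[1]]]$donor_phyla
    d2 <- ctxs[[prok_i[2]]]$donor_phyla
    enough <- length(ctxs[[prok_i[1]]]$donor_taxa) >= th$min_donor_taxa &&
      length(ctxs[[prok_i[2]]]$donor_taxa) >= th$min_donor_taxa
    if (enough && !length(intersect(d1, d2))) {
      all_focal_leaves <- unique(c(clades[[prok_i[1]]], clades[[prok_i[2]]]))
      call$focal_leaves <- all_focal_leaves
      call$focal_strains <- unique(stats::na.omit(
        tax$strain[match(all_focal_leaves, tax$leaf_id)]))
      call$n_focal_strains <- length(call$focal_strains)
      call$donor_taxa <- sort(unique(c(ctxs[[prok_i[1]]]$donor_taxa,
                                       ctxs[[prok_i[2]]]$donor_taxa)))
      call$donor_phyla <- sort(unique(c(d1, d2)))
      split_node <- ape::getMRCA(tree$phylo,
                                 match(all_focal_leaves, tree$phylo$tip.label))
      split_sup <- node_support(tree, split_node)
      pat <- if (!is.na(split_sup) && split_sup < th$min_support) {
        "uncertain"
      } else {
        "multiple_hgt"
      }
      return(done("hgt", "two independent prokaryote-nested acquisitions", pat))
    }
  }
  # (7) HGT
  done("hgt", "prokaryote-nested monophyletic focal clade",
       assign_pattern(tree, cand, clades = clades, contexts = ctxs))
}

#' Assign the acquisition pattern of an HGT call
#'
#' `shared_ancient` when the prokaryote-nested focal clade contains both the
#' Galdieria and the Cyanidioschyzon lineage (a transfer predating their
#' split); `galdieria_exclusive` / `cyanidioschyzon_exclusive` when only one
#' lineage is nested among prokaryotes and the other is absent from the
#' tree; `replacement_galdieria` / `replacement_cyanidioschyzon` when the
#' other lineage is present but clusters with eukaryotes (the transfer
#' replaced, or complements, the native gene in one lineage only).
#'
#' @param tree A `support_tree`.
#' @param clade The candidate focal clade (from [focal_clades()]).
#' @param clades,contexts Optional precomputed [focal_clades()] list and
#'   matching [nesting_context()] results; recomputed when `NULL`.
#' @return A pattern string.
#' @export
assign_pattern <- function(tree, clade, clades = NULL, contexts = NULL) {
  tax <- tree$taxonomy
  if (is.null(clades)) clades <- focal_clades(tree)
  if (is.null(contexts)) {
    contexts <- lapply(clades, function(cl) nesting_context(tree, cl))
  }
  lin <- unique(tax$lineage[match(clade, tax$leaf_id)])
  lin <- setdiff(lin, "other")
  if (all(c("galdieria", "cyanidioschyzon") %in% lin)) return("shared_ancient")
  this_lin <- lin[1]
  other_lin <- setdiff(c("galdieria", "cyanidioschyzon"), this_lin)
  node <- attr(clade, "node")
  other_euk <- FALSE
  for (i in seq_along(clades)) {
    if (identical(attr(clades[[i]], "node"), node)) next
    lin_i <- tax$lineage[match(clades[[i]], tax$leaf_id)]
    if (any(lin_i == other_lin) && contexts[[i]]$context == "eukaryotic") {
      other_euk <- TRUE
    }
  }
  if (other_euk) {
    if (this_lin == "galdieria") "replacement_galdieria" else "replacement_cyanidioschyzon"
  } else {
    if (this_lin == "galdieria") "galdieria_exclusive" else "cyanidioschyzon_exclusive"
  }
}

#' @export
print.hgt_call <- function(x, ...) {
  cat(sprintf("hgt_call %s: %s (pattern %s)\n", x$og_id, x$status, x$pattern))
  cat(sprintf("  %d focal strains; %d donor species in %d phyla\n",
              x$n_focal_strains, length(x$donor_taxa), length(x$donor_phyla)))
  invisible(x)
}

calls_to_frame <- function(calls) {
  join <- function(v) paste(v, collapse = ";")
  do.call(rbind, lapply(calls, function(cl) {
    data.frame(
      og_id = cl$og_id, status = cl$status, reason = cl$reason,
      pattern = cl$pattern,
      n_focal_strains = cl$n_focal_strains,
      focal_leaves = join(cl$focal_leaves),
      focal_strains = join(cl$focal_strains),
      donor_taxa = join(cl$donor_taxa),
      donor_phyla = join(cl$donor_phyla),
      stringsAsFactors = FALSE
    )
  }))
}

#' Classify a list of gene trees
#'
#' @param trees Named list of `support_tree` objects (names become og ids).
#' @param thresholds An [hgt_thresholds()] object.
#' @param egt_flags Either one flag list applied to all trees or a named
#'   list of per-tree flag lists.
#' @return A `data.frame` of calls, one row per tree (set-valued fields
#'   semicolon-joined), with the `hgt_call` objects in attribute `"calls"`.
#' @export
classify_trees <- function(trees, thresholds = hgt_thresholds(),
                           egt_flags = list(photosynthetic_annotation = FALSE)) {
  ids <- names(trees)
  if (is.null(ids)) ids <- sprintf("OG%07d", seq_along(trees))
  per_tree <- !is.null(names(egt_flags)) && all(ids %in% names(egt_flags))
  calls <- lapply(seq_along(trees), function(i) {
    fl <- if (per_tree) egt_flags[[ids[i]]] else egt_flags
    classify_tree(trees[[i]], thresholds, fl, og_id = ids[i])
  })
  out <- calls_to_frame(calls)
  attr(out, "calls") <- calls
  out
}

#' Presence/absence matrix of focal strains across HGT orthogroups
#'
#' @param calls Calls `data.frame` from [classify_trees()] (or list of
#'   `hgt_call`s); only rows with status `hgt` contribute.
#' @param strains Character vector of the focal strain panel (columns).
#' @return Binary matrix, orthogroups x strains; an entry is 1 when the
#'   strain contributes at least one leaf to the HGT clade. Row sums define
#'   orthogroup size.
#' @export
presence_matrix <- function(calls, strains) {
  if (!is.data.frame(calls)) calls <- calls_to_frame(calls)
  hgt <- calls[calls$status == "hgt", , drop = FALSE]
  m <- matrix(0L, nrow = nrow(hgt), ncol = length(strains),
              dimnames = list(hgt$og_id, strains))
  for (i in seq_len(nrow(hgt))) {
    present <- strsplit(hgt$focal_strains[i], ";", fixed = TRUE)[[1]]
    m[i, strains %in% present] <- 1L
  }
  m
}
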