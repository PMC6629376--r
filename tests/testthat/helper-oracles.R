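# Independent oracle implementations used to cross-check the package:
# plain-recursion tree classifier, brute-force hit balancing,
# hypergeometric enumeration for Fisher, step-up formula for BH,
# exhaustive permutation nulls for Kendall and Jonckheere-Terpstra.

# --- rule-by-rule gene-tree classifier, base-R recursion only -------------
oracle_classify <- function(tree, th = hgt_thresholds(),
                            egt_flags = list(photosynthetic_annotation = FALSE)) {
  phy <- tree$phylo
  tax <- tree$taxonomy
  nt <- length(phy$tip.label)
  root <- nt + 1L
  nn <- nt + phy$Nnode
  kids <- vector("list", nn)
  for (r in seq_len(nrow(phy$edge))) {
    a <- phy$edge[r, 1]; b <- phy$edge[r, 2]
    kids[[a]] <- c(kids[[a]], b)
  }
  par <- rep(NA_integer_, nn)
  par[phy$edge[, 2]] <- phy$edge[, 1]
  tips_under <- function(nd) {
    if (nd <= nt) return(nd)
    unlist(lapply(kids[[nd]], tips_under))
  }
  sup <- function(nd) if (nd <= nt) NA_integer_ else tree$support[nd - nt]
  focal <- tax$is_focal
  allfoc <- vapply(seq_len(nn), function(nd) all(focal[tips_under(nd)]),
                   logical(1))
  maximal <- Filter(function(nd) {
    allfoc[nd] && (nd == root || !allfoc[par[nd]])
  }, seq_len(nn))
  if (!length(maximal)) stop("no focal leaves")
  if (any(maximal == root)) stop("all leaves focal")
  ctx_of <- function(nd) {
    p1 <- par[nd]
    sis <- setdiff(kids[[p1]], nd)
    nb <- unlist(lapply(sis, tips_under))
    nbroot <- p1
    if (th$donor_neighborhood_depth >= 2 && p1 != root) {
      p2 <- par[p1]
      outer <- setdiff(kids[[p2]], p1)
      nb <- c(nb, unlist(lapply(outer, tips_under)))
      nbroot <- p2
    }
    own <- tips_under(nd)
    nb <- setdiff(unique(nb), own)
    kg <- tax$kingdom[nb]
    context <- if (!length(kg)) "mixed"
      else if (all(kg %in% c("A", "B"))) "prokaryotic"
      else if (all(kg == "E")) "eukaryotic" else "mixed"
    chain <- integer(0)
    cur <- nd
    chain <- sup(cur)
    while (cur != nbroot) { cur <- par[cur]; chain <- c(chain, sup(cur)) }
    list(node = nd, tips = own, context = context,
         donors = sort(unique(tax$species[nb][tax$kingdom[nb] != "E"])),
         phyla = sort(unique(tax$phylum[nb][tax$kingdom[nb] != "E"])),
         nb = nb, sis = unlist(lapply(sis, tips_under)), chain = chain)
  }
  ctxs <- lapply(maximal, ctx_of)
  rank <- vapply(ctxs, function(z)
    match(z$context, c("prokaryotic", "mixed", "eukaryotic")), integer(1))
  size <- vapply(ctxs, function(z) length(z$tips), integer(1))
  node <- vapply(ctxs, function(z) z$node, integer(1))
  best <- order(rank, -size, node)[1]
  cx <- ctxs[[best]]
  strains <- unique(na.omit(tax$strain[cx$tips]))
  out <- function(status, pattern = "none") list(status = status, pattern = pattern)

  if (length(strains) < th$min_focal_sequences) return(out("singleton"))
  if (cx$context == "eukaryotic") return(out("native"))
  donors_nb <- cx$nb[tax$kingdom[cx$nb] != "E"]
  if (length(donors_nb)) {
    frac <- mean(tax$is_cyanobacteria[donors_nb] | tax$is_chlamydiae[donors_nb])
    cy_sis <- any(tax$is_cyanobacteria[setdiff(cx$sis, cx$tips)])
    phot <- any(tax$is_photosynthetic_eukaryote[setdiff(seq_len(nt), cx$tips)])
    if (frac >= 0.5 &&
        (cy_sis || isTRUE(egt_flags$photosynthetic_annotation) || phot)) {
      return(out("egt_excluded"))
    }
  }
  if (length(cx$donors) < th$min_donor_taxa) return(out("rejected_few_donors"))
  weak <- !is.na(cx$chain) & cx$chain < th$min_support
  if (length(weak) >= 2 && any(weak[-1] & weak[-length(weak)])) {
    return(out("rejected_low_support"))
  }
  prok <- which(vapply(ctxs, function(z) z$context == "prokaryotic", logical(1)))
  if (length(prok) > 2) return(out("rejected_inconsistent"))
  if (length(prok) == 2) {
    c1 <- ctxs[[prok[1]]]; c2 <- ctxs[[prok[2]]]
    if (length(c1$donors) >= th$min_donor_taxa &&
        length(c2$donors) >= th$min_donor_taxa &&
        !length(intersect(c1$phyla, c2$phyla))) {
      tipset <- c(c1$tips, c2$tips)
      split_nd <- c1$node
      anc <- function(nd) { a <- nd; while (!is.na(par[nd])) { nd <- par[nd]; a <- c(a, nd) }; a }
      common <- intersect(anc(c1$node), anc(c2$node))
      split_nd <- common[1]
      s <- sup(split_nd)
      return(out("hgt", if (!is.na(s) && s < th$min_support) "uncertain"
                        else "multiple_hgt"))
    }
  }
  lin <- setdiff(unique(tax$lineage[cx$tips]), "other")
  if (all(c("galdieria", "cyanidioschyzon") %in% lin)) {
    return(out("hgt", "shared_ancient"))
  }
  other <- setdiff(c("galdieria", "cyanidioschyzon"), lin[1])
  other_euk <- FALSE
  for (i in seq_along(ctxs)) {
    if (i == best) next
    if (any(tax$lineage[ctxs[[i]]$tips] == other) &&
        ctxs[[i]]$context == "eukaryotic") other_euk <- TRUE
  }
  pat <- if (other_euk) paste0("replacement_", lin[1])
         else paste0(lin[1], if (lin[1] == "galdieria") "_exclusive" else "_exclusive")
  if (lin[1] == "cyanidioschyzon" && !other_euk) pat <- "cyanidioschyzon_exclusive"
  if (lin[1] == "galdieria" && !other_euk) pat <- "galdieria_exclusive"
  out("hgt", pat)
}

# --- brute-force maximal all-focal clades ---------------------------------
oracle_focal_clades <- function(tree) {
  phy <- tree$phylo
  nt <- length(phy$tip.label)
  focal <- tree$taxonomy$is_focal
  sets <- list()
  for (nd in seq_len(nt + phy$Nnode)) {
    tips <- unlist(phangorn::Descendants(phy, nd, "tips"))
    if (all(focal[tips])) sets[[length(sets) + 1]] <- sort(tips)
  }
  maximal <- Filter(function(s) {
    !any(vapply(sets, function(t2) length(t2) > length(s) && all(s %in% t2),
                logical(1)))
  }, sets)
  lapply(maximal, function(s) sort(phy$tip.label[s]))
}

# --- brute-force genus-capped hit selection -------------------------------
oracle_balance <- function(hits, budget) {
  hits <- hits[order(-hits$bitscore, hits$evalue, hits$sseqid,
                     method = "radix"), ]
  hits$phylum[is.na(hits$phylum) | !nzchar(hits$phylum)] <- "unclassified"
  cap <- max(1, floor(budget / length(unique(hits$phylum))))
  genera <- character(0)
  counts <- list()
  keep <- logical(nrow(hits))
  for (i in seq_len(nrow(hits))) {
    key <- paste(hits$phylum[i], hits$genus[i])
    ph <- hits$phylum[i]
    n_ph <- if (is.null(counts[[ph]])) 0 else counts[[ph]]
    if (key %in% genera) {
      keep[i] <- TRUE
    } else if (n_ph < cap) {
      genera <- c(genera, key)
      counts[[ph]] <- n_ph + 1
      keep[i] <- TRUE
    }
  }
  hits[keep, ]
}

# --- hypergeometric enumeration for the two-sided Fisher p ----------------
oracle_fisher <- function(x, m, n, k) {
  sup <- max(0, k - n):min(k, m)
  d <- dhyper(sup, m, n, k)
  sum(d[d <= d[sup == x] * (1 + 1e-7)])
}

# --- BH step-up formula ---------------------------------------------------
oracle_bh <- function(p) {
  n <- length(p)
  o <- order(p)
  adj <- numeric(n)
  sorted <- p[o]
  run <- rev(cummin(rev(pmin(1, n * sorted / seq_len(n)))))
  adj[o] <- run
  adj
}

# --- exhaustive permutation p for Kendall (loops, own generator) ----------
oracle_perms <- function(v) {
  if (length(v) == 1) return(list(v))
  out <- list()
  for (i in seq_along(v)) {
    for (rest in oracle_perms(v[-i])) out[[length(out) + 1]] <- c(v[i], rest)
  }
  out
}

oracle_kendall_p <- function(x, y) {
  conc <- function(a, b) {
    s <- 0
    for (i in seq_along(a)) for (j in seq_along(a)) if (i < j) {
      s <- s + sign(a[i] - a[j]) * sign(b[i] - b[j])
    }
    s
  }
  obs <- abs(conc(x, y))
  ps <- oracle_perms(y)
  mean(vapply(ps, function(p) abs(conc(x, p)) >= obs - 1e-9, logical(1)))
}

# --- exhaustive JT null over all orderings of the pooled sample -----------
oracle_jt_stat <- function(groups) {
  s <- 0
  k <- length(groups)
  for (i in seq_len(k - 1)) for (j in seq(i + 1, k)) {
    for (a in groups[[i]]) for (b in groups[[j]]) {
      s <- s + (a < b) + 0.5 * (a == b)
    }
  }
  s
}

oracle_jt_null <- function(groups) {
  sizes <- vapply(groups, length, integer(1))
  pooled <- unlist(groups)
  vapply(oracle_perms(seq_along(pooled)), function(idx) {
    v <- pooled[idx]
    ends <- cumsum(sizes)
    starts <- c(1, head(ends, -1) + 1)
    oracle_jt_stat(lapply(seq_along(sizes), function(i) v[starts[i]:ends[i]]))
  }, numeric(1))
}

# --- closed-form two-sample t (pooled, Welch) -----------------------------
oracle_welch_t <- function(a, b) {
  va <- var(a) / length(a); vb <- var(b) / length(b)
  t <- (mean(a) - mean(b)) / sqrt(va + vb)
  df <- (va + vb)^2 / (va^2 / (length(a) - 1) + vb^2 / (length(b) - 1))
  list(t = t, p = 2 * pt(-abs(t), df))
}
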