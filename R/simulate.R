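# Synthetic-data generator. Emits gene trees with planted HGT / native /
# EGT labels, per-gene feature tables, read alignments for the
# co-localization screen, and per-orthogroup PID summaries, all with the
# statistical structure the analysis stages assume, so that every stage
# is testable without any external data.

#' The focal strain panel: 11 Galdieria and 2 Cyanidioschyzon strains
#'
#' @return `data.frame` with columns `strain`, `species`, `lineage`.
#' @export
cyanidiales_strains <- function() {
  gald <- c("Gs074W", "GsMS1", "GsRT22", "GsSAG21", "GsMtSh", "GsAzora",
            "GsYNP5587", "Gs5572", "Gs002", "GpDBV009", "GpSoos")
  cyan <- c("Cm10D", "CmSoos")
  data.frame(
    strain = c(gald, cyan),
    species = c(gald, cyan),
    lineage = c(rep("galdieria", length(gald)),
                rep("cyanidioschyzon", length(cyan))),
    stringsAsFactors = FALSE
  )
}

# donor phylum weights mirroring the observed sister-phylum frequencies
donor_phylum_weights <- function() {
  c(Proteobacteria = 53, Firmicutes = 28, Actinobacteria = 19,
    Chloroflexi = 12, Bacteroidetes = 10, Euryarchaeota = 6)
}

#' Simulation configuration
#'
#' Defaults encode the study conditions the generator emulates: 13 focal
#' strains (11 Galdieria, 2 Cyanidioschyzon), roughly 1 percent of
#' orthogroups HGT-derived, a +1 GC-percentage-point shift of Galdieria
#' HGT candidates, single-exon probabilities 0.42 (HGT) vs 0.192 (native),
#' 1.2 fewer exons per HGT gene, donor-PID means of 45 (HGT orthogroups)
#' vs 39 (native orthogroups with prokaryotic hits), and a bimodal
#' orthogroup-size distribution produced by a three-component erosion
#' mixture (ancient/fixed, intermediate, recent).
#'
#' @param n_ogs Number of orthogroup trees to simulate.
#' @param hgt_fraction,egt_fraction Fractions of orthogroups with planted
#'   HGT and EGT labels; the remainder are native.
#' @param gc_native_galdieria,gc_native_cyanidioschyzon,gc_sd GC-content
#'   means (percent) and common standard deviation.
#' @param gc_shift_hgt GC shift of Galdieria HGT candidates (percentage
#'   points; Cyanidioschyzon gets none).
#' @param single_exon_prob_native,single_exon_prob_hgt Single-exon
#'   probabilities in the Galdieria lineage.
#' @param exon_mean_shift Planted difference in mean exons per gene (HGT
#'   minus native; negative = fewer).
#' @param cpm_mean Mean transcript abundance (counts per million, no class
#'   shift: expression is a planted null).
#' @param donor_pid_hgt,donor_pid_native Mean percent identity to
#'   non-eukaryotes per orthogroup class.
#' @param pid_within_mean Mean within-Cyanidiales percent identity.
#' @param pid_rank_correlation Kendall rank correlation planted between
#'   within-PID and donor-PID (Gaussian copula).
#' @param donor_pid_size_slope_native Donor-PID change per additional
#'   Galdieria strain in native orthogroups (negative: smaller orthogroups
#'   are closer to prokaryotes); the HGT class gets no size trend.
#' @param erosion_recent,erosion_ancient Mixture weights of the recent
#'   (1-2 strains) and ancient/fixed (all 11) components of HGT
#'   orthogroup-size erosion; remainder is intermediate (3-10).
#' @param n_native_genes,n_hgt_genes Genes per species per class in the
#'   feature table.
#' @param n_go_terms,n_go_enriched GO vocabulary size and number of terms
#'   enriched in the HGT class.
#' @param seed Integer seed used by every generator unless overridden.
#' @return List of class `sim_config`.
#' @export
sim_config <- function(n_ogs = 500,
                       hgt_fraction = 0.01,
                       egt_fraction = 0.005,
                       gc_native_galdieria = 39.5,
                       gc_native_cyanidioschyzon = 55.5,
                       gc_sd = 2,
                       gc_shift_hgt = 1.0,
                       single_exon_prob_native = 0.192,
                       single_exon_prob_hgt = 0.42,
                       exon_mean_shift = -1.2,
                       cpm_mean = 154,
                       donor_pid_hgt = 45,
                       donor_pid_native = 39,
                       pid_within_mean = 72,
                       pid_rank_correlation = 0.4,
                       donor_pid_size_slope_native = -0.5,
                       erosion_recent = 0.53,
                       erosion_ancient = 0.267,
                       n_native_genes = 5000,
                       n_hgt_genes = 50,
                       n_go_terms = 40,
                       n_go_enriched = 8,
                       seed = 1L) {
  cfg <- as.list(environment())
  probs <- c(cfg$hgt_fraction, cfg$egt_fraction, cfg$erosion_recent,
             cfg$erosion_ancient, cfg$single_exon_prob_native,
             cfg$single_exon_prob_hgt)
  if (any(probs < 0 | probs > 1)) stop("probabilities must lie in [0, 1]")
  if (cfg$gc_sd <= 0) stop("gc_sd must be positive")
  if (cfg$erosion_recent + cfg$erosion_ancient > 1) {
    stop("erosion mixture weights must sum to at most 1")
  }
  structure(cfg, class = "sim_config")
}

rcat <- function(n, probs) {
  sample(names(probs), n, replace = TRUE, prob = probs)
}

# orthogroup size (number of Galdieria strains retained) under the
# three-component erosion mixture
draw_galdieria_size <- function(cfg, n = 1) {
  comp <- rcat(n, c(recent = cfg$erosion_recent,
                    ancient = cfg$erosion_ancient,
                    mid = 1 - cfg$erosion_recent - cfg$erosion_ancient))
  vapply(comp, function(cm) {
    switch(cm,
           recent = sample(1:2, 1, prob = c(0.7, 0.3)),
           ancient = 11L,
           mid = sample(3:10, 1))
  }, numeric(1))
}

draw_native_galdieria_size <- function(n = 1) {
  comp <- rcat(n, c(full = 0.525, low = 0.361, mid = 0.114))
  vapply(comp, function(cm) {
    switch(cm,
           full = sample(10:11, 1, prob = c(0.3, 0.7)),
           low = sample(1:2, 1, prob = c(0.5, 0.5)),
           mid = sample(3:9, 1))
  }, numeric(1))
}

sup_draw <- function(noisy = FALSE) {
  if (noisy) sample(40:100, 1) else sample(95:100, 1)
}

nwk <- function(children, support) {
  sprintf("(%s)%d", paste(children, collapse = ","), support)
}

donor_leaves <- function(phylum, n, offset = 0) {
  kingdom <- if (phylum == "Euryarchaeota") "A" else "B"
  sprintf("%s_%s_sp%02d", kingdom, phylum, offset + seq_len(n))
}

#' Simulate one orthogroup gene tree with a planted label
#'
#' Native orthogroups place the focal clade among eukaryotic outgroups with
#' a distant prokaryote pair (so the orthogroup still counts as "native
#' with prokaryotic hits"); HGT orthogroups nest the focal clade inside a
#' donor clade from a phylum drawn with realistic sister-phylum weights;
#' EGT orthogroups use a cyanobacterial sister plus a photosynthetic
#' eukaryote homolog elsewhere in the tree. Supports are drawn in 95-100
#' unless `noisy_supports`. Erosion of the focal strain panel follows the
#' configured mixture; a tree eroded to one focal strain is emitted with
#' truth label `singleton`, keeping the truth consistent with the tree.
#'
#' @param cfg A [sim_config()].
#' @param og_label `"hgt"`, `"native"` or `"egt"`.
#' @param pattern For HGT: one of `"shared_ancient"`,
#'   `"galdieria_exclusive"`, `"cyanidioschyzon_exclusive"`,
#'   `"replacement_galdieria"`, `"replacement_cyanidioschyzon"`,
#'   `"multiple_hgt"`, `"uncertain"`; ignored otherwise.
#' @param og_id Orthogroup identifier.
#' @param noisy_supports Draw supports in 40-100 instead of 95-100.
#' @return List with `tree` (a `support_tree`) and `truth` (list: `og_id`,
#'   `label` = expected classifier status, `pattern`, `donor_phyla`,
#'   `strains` present).
#' @export
simulate_og_tree <- function(cfg, og_label = c("hgt", "native", "egt"),
                             pattern = "galdieria_exclusive",
                             og_id = "OG0000001", noisy_supports = FALSE) {
  og_label <- match.arg(og_label)
  panel <- cyanidiales_strains()
  gald <- panel$strain[panel$lineage == "galdieria"]
  cyan <- panel$strain[panel$lineage == "cyanidioschyzon"]
  s <- function() sup_draw(noisy_supports)
  weights <- donor_phylum_weights()

  focal_leaf <- function(strains) paste0("E_", strains)
  euks <- sprintf("E_euk%d", 1:4)
  tax_rows <- list()
  add_focal <- function(strains) {
    idx <- match(strains, panel$strain)
    tax_rows[[length(tax_rows) + 1]] <<- data.frame(
      leaf_id = focal_leaf(strains), kingdom = "E", species = panel$species[idx],
      genus = ifelse(panel$lineage[idx] == "galdieria", "Galdieria",
                     "Cyanidioschyzon"),
      phylum = "Rhodophyta", is_focal = TRUE, lineage = panel$lineage[idx],
      strain = strains, is_cyanobacteria = FALSE, is_chlamydiae = FALSE,
      is_photosynthetic_eukaryote = FALSE, stringsAsFactors = FALSE)
  }
  add_euks <- function(leaves, photosynthetic = FALSE) {
    tax_rows[[length(tax_rows) + 1]] <<- data.frame(
      leaf_id = leaves, kingdom = "E", species = sub("^E_", "", leaves),
      genus = sub("^E_", "", leaves), phylum = "Chlorophyta",
      is_focal = FALSE, lineage = "other", strain = NA_character_,
      is_cyanobacteria = FALSE, is_chlamydiae = FALSE,
      is_photosynthetic_eukaryote = photosynthetic, stringsAsFactors = FALSE)
  }
  add_donors <- function(leaves, phylum) {
    tax_rows[[length(tax_rows) + 1]] <<- data.frame(
      leaf_id = leaves, kingdom = substr(leaves, 1, 1),
      species = sub("^[AB]_", "", leaves),
      genus = sub("_sp[0-9]+$", "", sub("^[AB]_", "", leaves)),
      phylum = phylum, is_focal = FALSE, lineage = "other",
      strain = NA_character_, is_cyanobacteria = phylum == "Cyanobacteria",
      is_chlamydiae = phylum == "Chlamydiae",
      is_photosynthetic_eukaryote = FALSE, stringsAsFactors = FALSE)
  }
  euk_block <- function(lv = euks) {
    nwk(c(nwk(lv[1:2], s()), nwk(lv[3:4], s())), s())
  }
  # focal clade nested in a donor neighborhood: sister = 2+ donors,
  # outer = the rest, giving a fully prokaryotic context
  prok_nest <- function(strains, phylum, n_donor, offset = 0) {
    dl <- donor_leaves(phylum, n_donor, offset)
    add_donors(dl, phylum)
    add_focal(strains)
    fc <- if (length(strains) > 1) nwk(focal_leaf(strains), s()) else focal_leaf(strains)
    sister <- nwk(dl[1:2], s())
    outer <- if (n_donor - 2 > 1) nwk(dl[-(1:2)], s()) else dl[n_donor]
    nwk(c(nwk(c(fc, sister), s()), outer), s())
  }

  truth_label <- og_label
  truth_pattern <- "none"
  donor_phyla <- character()
  strains <- character()

  if (og_label == "native") {
    size <- max(2, draw_native_galdieria_size())
    strains <- sample(gald, size)
    if (stats::runif(1) < 0.5) strains <- c(strains, sample(cyan, 2))
    add_focal(strains)
    far_phylum <- rcat(1, weights)
    far <- donor_leaves(far_phylum, 2)
    add_donors(far, far_phylum)
    fc <- nwk(focal_leaf(strains), s())
    inner <- nwk(c(fc, nwk(euks[1:2], s())), s())
    mid <- nwk(c(inner, nwk(euks[3:4], s())), s())
    add_euks(euks)
    newick <- sprintf("(%s,%s);", mid, nwk(far, s()))
  } else if (og_label == "egt") {
    size <- max(2, draw_galdieria_size(cfg))
    strains <- sample(gald, size)
    add_focal(strains)
    cy <- donor_leaves("Cyanobacteria", 4)
    add_donors(cy, "Cyanobacteria")
    add_euks("E_phot1", photosynthetic = TRUE)
    add_euks(euks[1:3])
    donor_phyla <- "Cyanobacteria"
    truth_label <- "egt_excluded"
    fc <- nwk(focal_leaf(strains), s())
    block <- nwk(c(nwk(c(fc, nwk(cy[1:2], s())), s()), nwk(cy[3:4], s())), s())
    eukpart <- nwk(c(nwk(c("E_phot1", euks[1]), s()), nwk(euks[2:3], s())), s())
    newick <- sprintf("(%s,%s);", block, eukpart)
  } else {
    # hgt
    phylum <- rcat(1, weights)
    n_donor <- sample(3:6, 1)
    donor_phyla <- phylum
    if (pattern == "shared_ancient") {
      strains <- c(sample(gald, max(1, draw_galdieria_size(cfg))),
                   sample(cyan, sample(1:2, 1, prob = c(0.05, 0.95))))
      truth_pattern <- "shared_ancient"
      block <- prok_nest(strains, phylum, n_donor)
      add_euks(euks)
      newick <- sprintf("(%s,%s);", block, euk_block())
    } else if (pattern %in% c("galdieria_exclusive", "cyanidioschyzon_exclusive")) {
      strains <- if (pattern == "galdieria_exclusive") {
        sample(gald, draw_galdieria_size(cfg))
      } else {
        sample(cyan, sample(1:2, 1, prob = c(0.05, 0.95)))
      }
      truth_pattern <- pattern
      block <- prok_nest(strains, phylum, n_donor)
      add_euks(euks)
      newick <- sprintf("(%s,%s);", block, euk_block())
    } else if (pattern %in% c("replacement_galdieria", "replacement_cyanidioschyzon")) {
      if (pattern == "replacement_galdieria") {
        strains <- sample(gald, max(2, draw_galdieria_size(cfg)))
        other <- sample(cyan, 2)
      } else {
        strains <- sample(cyan, 2)
        other <- sample(gald, max(2, min(11, draw_galdieria_size(cfg))))
      }
      truth_pattern <- pattern
      block <- prok_nest(strains, phylum, n_donor)
      add_focal(other)
      add_euks(euks)
      oc <- nwk(focal_leaf(other), s())
      eukpart <- nwk(c(nwk(c(oc, nwk(euks[1:2], s())), s()),
                       nwk(euks[3:4], s())), s())
      newick <- sprintf("(%s,%s);", block, eukpart)
    } else if (pattern %in% c("multiple_hgt", "uncertain")) {
      ph2 <- rcat(1, weights[names(weights) != phylum])
      donor_phyla <- c(phylum, ph2)
      g_str <- sample(gald, max(2, draw_galdieria_size(cfg)))
      c_str <- sample(cyan, 2)
      strains <- c(g_str, c_str)
      truth_pattern <- pattern
      b1 <- prok_nest(g_str, phylum, sample(3:5, 1))
      b2 <- prok_nest(c_str, ph2, sample(3:5, 1), offset = 10)
      split_sup <- if (pattern == "uncertain") sample(40:69, 1) else sup_draw(FALSE)
      add_euks(euks)
      newick <- sprintf("(%s,%s);", nwk(c(b1, b2), split_sup),
                        nwk(euks[1:2], s()))
      # keep the third/fourth outgroup leaves out: root children are the
      # two-acquisition block and a eukaryote pair
    } else {
      stop("unknown pattern: ", pattern)
    }
    n_focal_strains <- length(unique(strains))
    if (n_focal_strains < 2) {
      truth_label <- "singleton"
      truth_pattern <- "none"
    } else {
      truth_label <- "hgt"
    }
  }
  tax <- do.call(rbind, tax_rows)
  tree <- read_newick_with_supports(newick, taxon_table(
    leaf_id = tax$leaf_id, kingdom = tax$kingdom, species = tax$species,
    genus = tax$genus, phylum = tax$phylum, is_focal = tax$is_focal,
    lineage = tax$lineage, strain = tax$strain,
    is_cyanobacteria = tax$is_cyanobacteria,
    is_chlamydiae = tax$is_chlamydiae,
    is_photosynthetic_eukaryote = tax$is_photosynthetic_eukaryote))
  list(tree = tree,
       truth = list(og_id = og_id, label = truth_label,
                    pattern = truth_pattern,
                    donor_phyla = sort(donor_phyla),
                    strains = sort(unique(strains))))
}

hgt_pattern_weights <- function() {
  c(shared_ancient = 10, galdieria_exclusive = 48, replacement_galdieria = 6,
    cyanidioschyzon_exclusive = 15, replacement_cyanidioschyzon = 8,
    multiple_hgt = 2, uncertain = 1)
}

#' Simulate a full set of orthogroup trees with planted truth
#'
#' @param cfg A [sim_config()].
#' @param seed Seed (defaults to `cfg$seed`).
#' @param noisy_supports Passed to [simulate_og_tree()].
#' @return List with `trees` (named list of `support_tree`) and `truth`
#'   (`data.frame`: `og_id`, `label`, `pattern`, `donor_phyla`
#'   semicolon-joined, `n_strains`).
#' @export
simulate_og_trees <- function(cfg = sim_config(), seed = cfg$seed,
                              noisy_supports = FALSE) {
  if (!is.null(seed)) set.seed(seed)
  n <- cfg$n_ogs
  labels <- rcat(n, c(hgt = cfg$hgt_fraction, egt = cfg$egt_fraction,
                      native = 1 - cfg$hgt_fraction - cfg$egt_fraction))
  patterns <- rep("none", n)
  patterns[labels == "hgt"] <- rcat(sum(labels == "hgt"),
                                    hgt_pattern_weights())
  ids <- sprintf("OG%07d", seq_len(n))
  sims <- lapply(seq_len(n), function(i) {
    simulate_og_tree(cfg, labels[i], patterns[i], og_id = ids[i],
                     noisy_supports = noisy_supports)
  })
  trees <- lapply(sims, `[[`, "tree")
  names(trees) <- ids
  truth <- do.call(rbind, lapply(sims, function(x) {
    data.frame(og_id = x$truth$og_id, label = x$truth$label,
               pattern = x$truth$pattern,
               donor_phyla = paste(x$truth$donor_phyla, collapse = ";"),
               n_strains = length(x$truth$strains),
               strains = paste(x$truth$strains, collapse = ";"),
               stringsAsFactors = FALSE)
  }))
  list(trees = trees, truth = truth)
}

#' Simulate a per-gene feature table with planted class effects
#'
#' Galdieria HGT candidates get the configured GC shift, higher
#' single-exon probability and fewer exons per gene; Cyanidioschyzon gets
#' no GC shift (its high native GC makes HGT indistinguishable) and an
#' almost entirely single-exon transcriptome. CPM is heavy-tailed
#' (log-normal) with no class shift. GO terms are drawn from a small
#' vocabulary whose first `n_go_enriched` terms are over-represented in
#' HGT genes.
#'
#' @param cfg A [sim_config()].
#' @param seed Seed (defaults to `cfg$seed`).
#' @return A validated gene table `data.frame` (see [read_gene_table()]).
#' @export
simulate_gene_table <- function(cfg = sim_config(), seed = cfg$seed) {
  if (!is.null(seed)) set.seed(seed)
  panel <- cyanidiales_strains()
  terms <- sprintf("GO:%07d", seq_len(cfg$n_go_terms))
  w_native <- rep(1, cfg$n_go_terms)
  w_hgt <- c(rep(6, cfg$n_go_enriched), rep(1, cfg$n_go_terms - cfg$n_go_enriched))
  draw_go <- function(n, w) {
    vapply(seq_len(n), function(i) {
      paste(sample(terms, sample(1:3, 1), prob = w), collapse = ";")
    }, character(1))
  }
  exon_draw <- function(n, p_single, lambda_multi) {
    single <- stats::runif(n) < p_single
    ifelse(single, 1L, 2L + stats::rpois(n, lambda_multi))
  }
  # multi-exon Poisson rates chosen so the HGT-native mean gap equals
  # exon_mean_shift given the two single-exon probabilities
  lam_n <- 1.3
  mean_native <- cfg$single_exon_prob_native +
    (1 - cfg$single_exon_prob_native) * (2 + lam_n)
  mean_hgt <- mean_native + cfg$exon_mean_shift
  lam_h <- max(0, (mean_hgt - cfg$single_exon_prob_hgt) /
                 (1 - cfg$single_exon_prob_hgt) - 2)
  cpm_sdlog <- 1.2
  cpm_mu <- log(cfg$cpm_mean) - cpm_sdlog^2 / 2
  per_species <- lapply(seq_len(nrow(panel)), function(i) {
    lin <- panel$lineage[i]
    nn <- cfg$n_native_genes; nh <- cfg$n_hgt_genes
    gald <- lin == "galdieria"
    gc_mu <- if (gald) cfg$gc_native_galdieria else cfg$gc_native_cyanidioschyzon
    gc_h <- gc_mu + if (gald) cfg$gc_shift_hgt else 0
    exn <- if (gald) exon_draw(nn, cfg$single_exon_prob_native, lam_n)
           else exon_draw(nn, 0.95, 0.05)
    exh <- if (gald) exon_draw(nh, cfg$single_exon_prob_hgt, lam_h)
           else exon_draw(nh, 0.98, 0.02)
    data.frame(
      gene_id = sprintf("%s_g%05d", panel$strain[i], seq_len(nn + nh)),
      species = panel$species[i],
      lineage = lin,
      gc_percent = pmin(100, pmax(0, c(stats::rnorm(nn, gc_mu, cfg$gc_sd),
                                       stats::rnorm(nh, gc_h, cfg$gc_sd)))),
      exon_count = c(exn, exh),
      cpm = stats::rlnorm(nn + nh, cpm_mu, cpm_sdlog),
      is_hgt = rep(c(FALSE, TRUE), c(nn, nh)),
      og_id = c(sprintf("NOG%05d", seq_len(nn)), sprintf("HOG%03d", seq_len(nh))),
      go_terms = c(draw_go(nn, w_native), draw_go(nh, w_hgt)),
      stringsAsFactors = FALSE
    )
  })
  out <- do.call(rbind, per_species)
  rownames(out) <- NULL
  validate_gene_table(out)
  out
}

#' Simulate read alignments for the co-localization screen
#'
#' Genuine HGT genes are placed on long reads alongside native genes;
#' "contaminant" genes sit on reads carrying no native partner. A sprinkle
#' of sub-threshold alignments exercises the e-value/bitscore filters.
#'
#' @param cfg A [sim_config()] (only `seed` is used by default).
#' @param contamination_fraction Fraction of HGT candidates planted as
#'   contaminants, in \[0, 1\].
#' @param n_hgt,n_native Number of HGT candidate and native gene ids.
#' @param seed Seed (defaults to `cfg$seed`).
#' @return List with `alignments` (`data.frame`: `read_id`, `gene_id`,
#'   `bitscore`, `evalue`), `hgt_ids`, `native_ids`, `contaminants`.
#' @export
simulate_read_alignments <- function(cfg = sim_config(),
                                     contamination_fraction = 0,
                                     n_hgt = 641, n_native = 2000,
                                     seed = cfg$seed) {
  if (contamination_fraction < 0 || contamination_fraction > 1) {
    stop("contamination_fraction must lie in [0, 1]")
  }
  if (!is.null(seed)) set.seed(seed)
  hgt_ids <- sprintf("HGT%04d", seq_len(n_hgt))
  native_ids <- sprintf("NAT%05d", seq_len(n_native))
  contaminant <- stats::runif(n_hgt) < contamination_fraction
  bs <- function(n) 75 + stats::rgamma(n, 2, 0.05)
  ev <- function(n) 10^-stats::runif(n, 6, 40)
  rows <- list()
  read_counter <- 0L
  new_read <- function() {
    read_counter <<- read_counter + 1L
    sprintf("read%07d", read_counter)
  }
  for (i in seq_len(n_hgt)) {
    n_reads <- sample(1:3, 1)
    for (r in seq_len(n_reads)) {
      rd <- new_read()
      rows[[length(rows) + 1]] <- data.frame(
        read_id = rd, gene_id = hgt_ids[i], bitscore = bs(1), evalue = ev(1))
      if (!contaminant[i]) {
        partners <- sample(native_ids, sample(1:2, 1))
        rows[[length(rows) + 1]] <- data.frame(
          read_id = rd, gene_id = partners, bitscore = bs(length(partners)),
          evalue = ev(length(partners)))
      }
    }
  }
  # native-only reads and sub-threshold noise
  nat_sample <- sample(native_ids, min(n_native, 500))
  rows[[length(rows) + 1]] <- data.frame(
    read_id = vapply(seq_along(nat_sample), function(i) new_read(), ""),
    gene_id = nat_sample, bitscore = bs(length(nat_sample)),
    evalue = ev(length(nat_sample)))
  noise <- sample(c(hgt_ids, native_ids), 50)
  rows[[length(rows) + 1]] <- data.frame(
    read_id = vapply(seq_along(noise), function(i) new_read(), ""),
    gene_id = noise, bitscore = stats::runif(50, 30, 74),
    evalue = ev(50))
  aln <- do.call(rbind, rows)
  rownames(aln) <- NULL
  list(alignments = aln, hgt_ids = hgt_ids, native_ids = native_ids,
       contaminants = hgt_ids[contaminant])
}

#' Simulate per-orthogroup PID summaries
#'
#' Within-PID and donor-PID are drawn from a Gaussian copula with the
#' configured rank correlation; the HGT class's donor-PID mean exceeds the
#' native class's by the configured gap; orthogroup sizes follow the
#' bimodal erosion mixtures; native orthogroups get the configured
#' negative donor-PID-vs-size slope (centered on the class mean size so
#' the global class means are unchanged) while the HGT class gets none.
#'
#' @param cfg A [sim_config()].
#' @param n_hgt,n_native Orthogroups per class.
#' @param seed Seed (defaults to `cfg$seed`).
#' @return `data.frame` with columns `og_id`, `class`, `category`,
#'   `og_size`, `within_pid`, `donor_pid`, `max_candidate_pid`,
#'   `donor_phyla`.
#' @export
simulate_pid_tables <- function(cfg = sim_config(), n_hgt = 96,
                                n_native = 400, seed = cfg$seed) {
  if (!is.null(seed)) set.seed(seed)
  n <- n_hgt + n_native
  cls <- rep(c("hgt", "native"), c(n_hgt, n_native))
  category <- rep(NA_character_, n)
  category[cls == "hgt"] <- rcat(n_hgt, c(shared = 13, galdieria_only = 60,
                                          cyanidioschyzon_only = 23))
  og_size <- numeric(n)
  for (i in seq_len(n)) {
    og_size[i] <- if (cls[i] == "native") {
      draw_native_galdieria_size()
    } else if (category[i] == "cyanidioschyzon_only") {
      0
    } else {
      draw_galdieria_size(cfg)
    }
  }
  rho <- sin(pi * cfg$pid_rank_correlation / 2)
  z1 <- stats::rnorm(n)
  z2 <- rho * z1 + sqrt(1 - rho^2) * stats::rnorm(n)
  within <- pmin(100, pmax(20, cfg$pid_within_mean + 8 * z1))
  base <- ifelse(cls == "hgt", cfg$donor_pid_hgt, cfg$donor_pid_native)
  nat_center <- mean(og_size[cls == "native"])
  trend <- ifelse(cls == "native",
                  cfg$donor_pid_size_slope_native * (og_size - nat_center), 0)
  donor <- pmin(95, pmax(15, base + trend + 7 * z2))
  weights <- donor_phylum_weights()
  phyla <- vapply(seq_len(n), function(i) {
    paste(sample(names(weights), sample(1:2, 1), prob = weights), collapse = ";")
  }, character(1))
  data.frame(
    og_id = sprintf("POG%05d", seq_len(n)),
    class = cls, category = category, og_size = og_size,
    within_pid = within, donor_pid = donor,
    max_candidate_pid = pmin(99, donor + stats::rexp(n, 1 / 6)),
    donor_phyla = phyla,
    stringsAsFactors = FALSE
  )
}
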