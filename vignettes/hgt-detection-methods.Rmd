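---
title: "Detecting horizontal gene transfer in Cyanidiales genomes: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting horizontal gene transfer in Cyanidiales genomes: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cyanihgt)
```

## The problem

The Cyanidiales are a monophyletic clade of unicellular, polyextremophilic
red algae (the *Galdieria* and *Cyanidioschyzon* lineages) living in hot,
acidic habitats alongside specialized Bacteria and Archaea. A small but
functionally important fraction of their gene inventory — on the order of
1% of orthogroups — appears to derive from horizontal gene transfer (HGT)
from prokaryotic neighbors rather than vertical descent. Detecting such
transfers from genome data is error-prone: assembly contamination,
endosymbiotic gene transfer (EGT) from the plastid and mitochondrial
ancestors, sparse taxon sampling, and weakly supported gene-tree topologies
all masquerade as HGT. `cyanihgt` implements the conservative, multi-layer
detection protocol for this setting:

1. **Taxonomically balanced homolog selection** from similarity-search hit
   tables, so that over-sampled phyla do not dominate the trees.
2. **Rule-based gene-tree classification** of each orthogroup as HGT
   candidate, native, EGT-excluded, or rejected, with the acquisition
   pattern (ancient/shared, lineage-exclusive, replacement, multiple,
   uncertain).
3. **A long-read co-localization screen**: genuine HGT candidates should
   share uncorrected long reads with unambiguously native genes;
   contaminant sequences should not.
4. **Comparative statistics** contrasting HGT candidates with native genes
   (GC content, exon structure, expression, GO enrichment) and
   percent-identity (PID) analyses of cumulative-effect hypotheses.
5. **A synthetic-data generator** that emulates the study design (13 focal
   strains: 11 *Galdieria*, 2 *Cyanidioschyzon*) so that every stage can be
   exercised and validated without external data.

## Gene-tree classification

Each orthogroup tree is a rooted topology with integer ultrafast-bootstrap
supports on internal nodes and leaves bound to a taxonomy (kingdom `A`/`B`/`E`,
phylum, genus, species, focal-lineage flags). The classifier proceeds as an
ordered, total decision cascade, so every tree receives exactly one status:

1. **Singleton.** If the candidate focal clade contains fewer than
   `min_focal_sequences` (default 2) distinct focal strains, the tree is a
   singleton and excluded from calls — one strain's sequence alone cannot be
   distinguished from assembly or annotation artifacts.
2. **Native.** If the clade's nesting context is eukaryotic, the gene is
   vertically inherited.
3. **EGT exclusion.** If the donor neighborhood is dominated (≥ 50% of
   donor leaves) by cyanobacteria or Chlamydiae *and* the cyanobacterium is
   the closest neighbor, or the gene carries a photosynthetic annotation,
   or photosynthetic eukaryotes elsewhere in the tree hold homologs, the
   tree is excluded as endosymbiotic gene transfer.
4. **Donor count.** At least `min_donor_taxa` (default 3) distinct
   non-eukaryotic donor *species* are required; strains of one species
   count once.
5. **Support.** Two or more *consecutive* nodes below `min_support`
   (default 70%) on the path from the focal clade to the donor-neighborhood
   root reject the tree. A single weak node does not: the criterion targets
   weakness "spanning multiple nodes", not isolated uncertainty.
6. **Split structure.** Focal strains scattered over more than two
   prokaryote-nested clades are treated as an inconsistent species
   distribution and rejected. Exactly two prokaryote-nested clades with
   donors from *different* phyla are called HGT with pattern
   `multiple_hgt` — two independent acquisitions of the same function — or
   `uncertain` when the node separating them fails the support floor.
7. **HGT.** Otherwise the tree is an HGT candidate and the pattern is
   assigned: `shared_ancient` when both lineages sit in one
   prokaryote-nested clade (transfer before the *Galdieria*–*Cyanidioschyzon*
   split), `galdieria_exclusive`/`cyanidioschyzon_exclusive` when the other
   lineage is absent, and `replacement_*` when the other lineage is present
   but clusters with eukaryotes (the transfer replaced or complements the
   native gene in one lineage).

```{r example}
tree <- read_newick_with_supports(
  "(((E_gal1,E_gal2)95,((B_s1,B_s2)91,B_s3)90)98,(E_o1,E_o2)97)99;",
  taxon_table(
    leaf_id = c("E_gal1", "E_gal2", "B_s1", "B_s2", "B_s3", "E_o1", "E_o2"),
    kingdom = c("E", "E", "B", "B", "B", "E", "E"),
    is_focal = c(TRUE, TRUE, FALSE, FALSE, FALSE, FALSE, FALSE),
    lineage = c("galdieria", "galdieria", rep("other", 5)),
    strain = c("g1", "g2", rep(NA, 5))))
classify_tree(tree)
```

### Design choices in the cascade

Several rules in this protocol are qualitative in their original
formulation; the package fixes them as follows, and these are deliberate
design decisions rather than derived facts:

* **Donor neighborhood depth.** "Nested among prokaryotes" is judged on
  the sister clade plus one outer clade (`donor_neighborhood_depth = 2`).
  A sister-only mode (`depth = 1`) is available; depth 2 is the default
  because a single sister clade of one or two sequences is too easily
  produced by a misplaced branch.
* **Weak support** is operationalized as ≥ 2 consecutive sub-threshold
  nodes on the focal-to-donor path.
* **Species-distribution inconsistency** is operationalized as focal
  strains split over more than two independently prokaryote-nested clades.
  This is a codification of what was originally a manual inspection step
  and may call differently on borderline topologies.
* **EGT dominance** is fixed at ≥ 50% of donor leaves being
  cyanobacterial/chlamydial.
* **Missing supports pass** the support filters (with a warning): trees
  from the intended pipeline always carry ultrafast-bootstrap values, and
  treating absence as failure would silently reject minimal synthetic
  trees.
* **Rooting.** Trees are used as supplied when rooted and midpoint-rooted
  otherwise (with a message), because the nesting classification depends
  on the root.

## Hit balancing

Database volumes are queried independently; each volume's hits are
truncated to its top 2000 by bitscore and merged, sorted by descending
bitscore, with duplicate subjects collapsed to their best score. A genera
budget (default 180) divided by the number of observed phyla gives the
per-phylum cap — `floor(180 / n_phyla)`, clamped to at least 1; floor
division is our choice, as is admitting *all* hits of an admitted genus
(the cap limits genera, not sequences) and then optionally retaining one
best-scoring representative per subject species for alignment. The
e-value filter retains the boundary (`evalue <= 1e-5`), the conventional
inclusive reading. Bitscore ties break by ascending e-value, then subject
id, so selection is deterministic.

## Read co-localization screen

Protein queries against uncorrected long reads (tblastn-style tabular
alignments) are filtered at *both* an e-value cutoff (1e-5) and a bitscore
floor (75). An HGT candidate is co-localized when at least one retained
read carries the candidate and any native gene; no minimum separation on
the read is imposed. Candidates with no retained alignments at all are
listed separately from contradicted ones, and the summary reports both the
per-candidate fraction and the number of distinct co-localization reads.

## Statistics

* **GC content:** two-sided two-sample t-test per species. Welch's
  unequal-variance form is the default; the pooled Student form is a flag.
  Transcript GC is close enough to normal for this to be the natural test.
* **Single- vs multi-exon:** Fisher's exact test on the 2×2 origin-by-exon
  class table; the two-sided p sums all tables with point probability at
  most the observed one (the standard convention).
* **Exons per gene:** Wilcoxon-Mann-Whitney rank statistic with a
  label-permutation null (default 1000 resamples, seedable); the exact
  rank-sum p is reported alongside. A permutation null is used because the
  original "1000 bootstraps" does not pin down a resampling scheme, and
  label permutation is the exchangeable-null scheme that makes the test
  exact.
* **Expression (CPM):** rank-sum test (CPM is heavy-tailed), class means
  reported.
* **GO enrichment:** per-term Fisher tests of HGT vs native membership
  with Benjamini-Hochberg adjustment across tested terms; terms occurring
  fewer than twice among HGT genes are excluded. The default universe
  pools all species.
* **Kendall trend:** tau-b with tie correction between within-lineage PID
  and donor PID. The two-sided p is an exact full-enumeration permutation
  p for n ≤ 8 and a tie-corrected normal approximation above — exhaustive
  enumeration beyond n = 8 costs factorial time for no practical gain in
  accuracy.
* **Jonckheere–Terpstra:** the ordered-alternative trend statistic
  (cross-pair wins plus half-ties over ordered group pairs). The null is
  enumerated exactly when the number of group-label arrangements is at
  most 1e5 and estimated by seedable random permutation otherwise. For the
  erosion analysis the hypothesized direction is *decreasing* donor-PID
  with increasing orthogroup size; the two-sided p is always reported in
  `$extra`.
* **Seventy-percent rule:** audited per candidate (strictly > 70% to a
  donor), never assumed; exceedances are flagged as potentially
  EGT-attributable when a donor phylum is Cyanobacteria, Chlamydiae or
  Proteobacteria.

Pairwise percent identity is computed from a global Needleman–Wunsch
alignment (BLOSUM62, gap open 10, extension 0.5) as identical residues
over aligned columns where both sequences have a residue; gap columns are
excluded from the denominator. Orthogroup donor-PID uses the mean over
focal–donor pairs, while the seventy-percent rule uses the per-candidate
maximum, because that rule applies to individual candidates.

## The synthetic-data generator

The generator emulates the study conditions, and its defaults are fixed at
those conditions:

* 13 focal strains (11 *Galdieria*, 2 *Cyanidioschyzon*); ~1% of
  orthogroups HGT-derived and 0.5% EGT (our choice for a rarely stated
  quantity; EGT exclusions are rarer than HGT calls but must occur).
* GC: *Galdieria* native 39.5 ± 2%, HGT +1.0 point; *Cyanidioschyzon*
  55.5 ± 2% with no shift (its high native GC makes HGT candidates
  indistinguishable by GC).
* Exon structure: single-exon probability 0.192 (native) vs 0.42 (HGT) in
  *Galdieria*; multi-exon counts are 2 + Poisson with rates chosen in
  closed form so the overall HGT−native mean gap equals −1.2 exons/gene.
  *Cyanidioschyzon* is almost entirely single-exon in both classes.
* Expression: log-normal CPM with mean 154 and no class shift — a planted
  null.
* PID: within-PID mean 72%, donor-PID 45% (HGT) vs 39% (native), coupled
  through a Gaussian copula with Kendall rank correlation 0.4; the native
  class gets a −0.5 point-per-strain size slope (centered, so class means
  are unchanged) and the HGT class none, matching the observed
  trend-in-native / no-trend-in-HGT contrast.
* Orthogroup-size erosion: a three-component mixture — "recent" (1–2
  strains, weight 0.53), "ancient/fixed" (all 11, weight 0.267),
  intermediate (3–10, remainder) — with the retained strain subset drawn
  uniformly. A single per-strain Bernoulli deletion rate cannot produce
  the observed bimodal size distribution (a binomial is unimodal, and a
  U-shaped beta-binomial cannot reach both tail masses once conditioned on
  at least one retained strain), so the mixture weights are set directly to
  the observed fractions. Native orthogroups use their own mixture (0.525
  at 10–11 strains, 0.361 at 1–2).
* Donor phyla are drawn with weights mirroring the observed sister-phylum
  frequencies (Proteobacteria 53 : Firmicutes 28 : Actinobacteria 19 :
  Chloroflexi 12 : Bacteroidetes 10 : Euryarchaeota 6).
* Branch lengths are cosmetic (0.1 implicitly): classification is driven
  by topology and supports only. Supports are drawn in 95–100 unless noisy
  supports are requested.
* A tree eroded to a single focal strain is emitted with truth label
  `singleton`, keeping the planted truth consistent with the emitted tree.

What the generator does **not** emulate: sequence-level evolution (no
substitution models, so PID values are drawn, not computed from simulated
sequences), realistic read error profiles, paralogy and incomplete lineage
sorting, and deep-branching artifacts. Passing recovery tests therefore
demonstrates that the *rules* are implemented correctly and are
recoverable under the stated noise model — not that the protocol is immune
to the real-data failure modes (model misspecification, hidden paralogy)
that motivated its conservative thresholds in the first place.

## Problem sizes and reproducibility

The test suite and the acceptance script run the classifier-recovery
experiment on 500 simulated trees, oracle-equivalence sweeps on 200
randomized trees, effect-size recovery over 50–100 generator seeds at
1000 native + 60 HGT genes per species, and permutation-test calibration
with 199 resamples over 1000 null simulations — sizes chosen so the whole
validation runs in minutes on one CPU while keeping Monte-Carlo error well
inside the asserted tolerances. All stochastic procedures take explicit
seeds; identical configurations produce byte-identical outputs.

## Known limitations

* The inconsistency rule (status `rejected_inconsistent`) codifies a
  manual-inspection criterion; borderline topologies near the root may be
  called differently than a human curator would.
* The per-lineage transfer-rate figure divides a lineage age by an event
  count; the package exposes numerator and denominator explicitly rather
  than committing to any particular event attribution.
* Kendall exact p-values switch to the normal approximation above n = 8.
* The classifier assumes one candidate clade per tree after the split
  rules; heavily paralogous orthogroups should be split upstream of
  classification.
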