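Package: cyanihgt
Title: Phylogenetic Detection and Characterization of Horizontal Gene
    Transfer in Cyanidiales Genomes
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Post-orthology detection of horizontal gene transfer (HGT)
    candidates in the polyextremophilic red algae of the Cyanidiales.
    Provides taxonomically balanced homolog selection from tabular
    similarity-search hits, a rule-based gene-tree classifier that calls
    prokaryote-nested monophyletic orthogroups as HGT while excluding
    endosymbiotic gene transfer and low-support topologies, a long-read
    co-localization screen against assembly contamination, statistical
    comparison of HGT candidates with native genes (GC content, exon
    structure, expression, GO enrichment), percent-identity and
    cumulative-effects analyses (Kendall trend, Jonckheere-Terpstra
    ordered-alternative test, the seventy-percent-rule audit), and a
    synthetic-data generator that emulates a study design of 13 focal
    strains so every stage is testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    ape,
    phangorn,
    Biostrings,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
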