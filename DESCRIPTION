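Package: viromine
Title: Desk-Scale Gut Virome Discovery, Community Ecology and Phage Gene
    Quantification
Version: 0.9.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: A fully testable reimplementation of an in-house gut-virome
    analysis pipeline at desk scale: read cleaning (positional
    deduplication, quality-tail and adapter trimming, length filtering),
    greedy overlap assembly, translated homology triage against a viral
    proteome database with Karlin-Altschul E-values, competitive
    filtering against a non-virus decoy database, profile (PSSM) fallback
    for remote homologs, viral community ecology (Bray-Curtis, UPGMA,
    PCoA, ANOSIM, shared-species sets), hallmark-gene annotation and
    phylogenetics, and phage functional-gene / antibiotic-resistance-gene
    quantification (ppm, FPKM). A seeded synthetic-community simulator
    with ground-truth manifests makes every stage exercisable without
    external data.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    Rcpp,
    Biostrings,
    S4Vectors,
    IRanges,
    ape,
    vegan,
    jsonlite,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    phangorn
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Collate: 
    'utils.R'
    'AllClasses.R'
    'RcppExports.R'
    'triage.R'
    'annotation.R'
    'assembly.R'
    'ecology.R'
    'io.R'
    'phylogenetics.R'
    'quantification.R'
    'read-processing.R'
    'synthetic-data.R'
    'pipeline.R'
    'viromine-package.R'
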