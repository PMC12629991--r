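Package: germkit
Title: Generalized RNA Multivalency (GeRM) Scoring and Multivalent Region Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Computes Generalized RNA Multivalency (GeRM) scores along spliced
    transcripts, calls high-multivalency coding-sequence regions and clusters
    them into multivalency classes, builds synonymous codon-shuffle null
    models and per-position codon-support ratios, normalizes per-base
    conservation at synonymously mutable positions, detects low-complexity
    and arginine-rich mixed-charge domains in the encoded proteins, scores
    RNA-binding-protein binding potential from motif enrichment tables, and
    quantifies crosslink (CLIP) multivalency preference and region
    enrichment. Includes a synthetic transcriptome generator with planted
    ground truth so that every statistic can be exercised end to end without
    external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    Rcpp,
    Biostrings,
    IRanges,
    GenomicRanges,
    S4Vectors,
    rtracklayer,
    jsonlite
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    mclust,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Collate: 
    'AllClasses.R'
    'RcppExports.R'
    'accessors.R'
    'core.R'
    'clusters.R'
    'clip.R'
    'codon.R'
    'conservation.R'
    'germkit-package.R'
    'io.R'
    'lcd.R'
    'regions.R'
    'simulate.R'
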