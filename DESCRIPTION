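Package: mgmlst
Title: Strain-Level Microbiome Composition from Metagenomic Multi-Locus
    Sequence Typing
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Quantifies the relative abundances of strain population groups
    of a bacterial species within a microbiome sample. Per-position
    sequencing coverage over MLST housekeeping genes is converted into
    marker-SNP frequencies, allele relative abundances, and a ploidy-100
    allelic profile, and mixture proportions over predefined population
    groups (e.g. Propionibacterium acnes ribotype groups) are inferred
    with a supervised Bayesian admixture model trained on a labelled
    learning set of reference strains. Includes tools to load and curate
    PubMLST-style schemes, derive allele-distinguishing marker SNPs,
    simulate communities of known composition, and score predictions
    against expected compositions.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    Biostrings,
    Rsamtools,
    GenomicRanges,
    IRanges,
    stats,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
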