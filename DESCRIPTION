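Package: matriline
Title: Matrilineal Phylogeography of mtDNA Control-Region Sequences
Version: 0.9.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for matrilineal phylogeography of mitochondrial
    control-region (D-loop) sequences, built around the diagnostic-motif
    haplogroup nomenclature used for village chickens in Southeast Asia and
    the Pacific. Sequences are anchored to a fixed 1232-bp reference frame,
    substitutions are scored as anc-pos-der motif tokens, and samples are
    assigned to the deepest node of a user-supplied hierarchical motif tree
    (a macrohaplogroup CDV scheme ships as a fixture). Downstream analyses
    cover haplotype collapsing, Nei haplotype and nucleotide diversity with
    sampling variances, Tajima's D and Fu's Fs with significance calibrated
    by an internal neutral infinite-sites coalescent simulator,
    distance-based pairwise Phi-ST with permutation tests, hierarchical
    AMOVA, principal coordinates analysis of the fixation-index matrix, and
    median-joining haplotype networks with mutation-labelled edges and a
    rho-statistic TMRCA utility. A haplogroup-structured synthetic data
    generator with full ground truth makes every stage testable without
    external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    tools,
    Biostrings,
    igraph,
    yaml,
    jsonlite,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
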