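Package: primerblockr
Title: Design and Evaluation of PCR Blocking Primers for Diet DNA
    Metabarcoding
Version: 0.9.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for designing annealing-inhibition blocking primers that
    suppress amplification of a focal predator's marker sequence while
    sparing community (host/prey) species, and for quantifying blocker
    effectiveness from qPCR traces and amplicon read tables. Includes a
    small global/center-star aligner for short marker regions, detection of
    target-discriminative gap windows in reference alignments, candidate
    blocker enumeration with nearest-neighbor melting temperatures and
    per-species specificity scores, cycle-threshold and melt-curve analysis
    with fold-suppression arithmetic, a toy paired-end amplicon pipeline
    (merge, filter, dereplicate, classify, cluster) producing OTU tables,
    paired t-tests with sequential Bonferroni correction, and seeded
    simulators for all three input kinds.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    Rcpp,
    Biostrings,
    S4Vectors,
    IRanges,
    SummarizedExperiment,
    jsonlite
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    yaml
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
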