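#' Published sea lamprey 12S blocker panel
#'
#' The eight annealing-inhibition blocking primers of the motivating sea
#' lamprey evaluation: every combination of length (34/36 bases), 3' end
#' modification (C3 spacer / inverted dT) and purification grade
#' (HPLC / desalted), with the vendor-reported nearest-neighbor melting
#' temperatures. Useful as a worked design target: all eight share the
#' same 5' start — the 3' terminal bases of the universal forward primer —
#' and extend across the predator-specific insertion.
#'
#' @return A data.frame with columns `blocker`, `purification`, `length`,
#'   `modification`, `sequence`, `tm`.
#' @examples
#' head(exampleBlockers())
#' @export
exampleBlockers <- function() {
    read.delim(system.file("extdata", "blockers.tsv",
                           package = "primerblockr"),
               stringsAsFactors = FALSE)
}

#' Lake trout read counts from the sea lamprey blocker evaluation
#'
#' Per-sample lake trout sequence read counts for dietary and
#' mock-community DNA templates amplified without a blocker and with each
#' of the eight blockers. The five dietary samples HP15, HP3, HP5, M1 and
#' M4 are the ones used for host-side paired t-tests (CA14, an adult
#' wild-caught sample with almost no host DNA, is excluded there).
#'
#' @return A data.frame: `sample`, `unblocked`, `blocker1`..`blocker8`.
#' @export
exampleLakeTroutCounts <- function() {
    read.delim(system.file("extdata", "laketrout_read_counts.tsv",
                           package = "primerblockr"),
               stringsAsFactors = FALSE)
}

#' Predator read-count means from the sea lamprey blocker evaluation
#'
#' Mean sea lamprey read counts across the seven dietary samples, without
#' a blocker and with each blocker, plus the paired-test p-values.
#'
#' @return A data.frame: `blocker`, `mean_unblocked`, `mean_blocked`, `p`.
#' @export
examplePredatorMeans <- function() {
    read.delim(system.file("extdata", "predator_read_means.tsv",
                           package = "primerblockr"),
               stringsAsFactors = FALSE)
}
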