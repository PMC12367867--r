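ALIGN_ALPHABET <- c("A", "C", "G", "T", "N", "-")

#' Gapped community reference alignment with a designated target
#'
#' Holds equal-length gapped marker-region sequences for a community plus
#' one designated target (e.g. the predator whose amplification is to be
#' blocked). When a universal primer has been prepended with
#' [appendPrimerToAlignment()], `primerLength()` records how many leading
#' columns belong to the primer track, so that design coordinates cover
#' primer + marker.
#'
#' @slot seqs A gapped [Biostrings::DNAStringSet] (equal widths, unique
#'   non-empty names; alphabet `A,C,G,T,N,-`).
#' @slot targetId Name of the target record.
#' @slot primerLen Number of leading columns occupied by an appended
#'   universal-primer track (0 when none has been appended).
#'
#' @seealso [referenceAlignment()], [centerStarMsa()],
#'   [findDiscriminativeGap()]
#' @export
setClass("ReferenceAlignment",
    representation(seqs = "DNAStringSet", targetId = "character",
                   primerLen = "integer"),
    prototype(primerLen = 0L))

setValidity("ReferenceAlignment", function(object) {
    s <- object@seqs
    msg <- character()
    if (length(s) < 1L)
        msg <- c(msg, "alignment must contain at least one record")
    nm <- names(s)
    if (is.null(nm) || any(!nzchar(nm)))
        msg <- c(msg, "all records must have non-empty ids")
    if (anyDuplicated(nm))
        msg <- c(msg, sprintf("duplicate record ids: %s",
                              paste(unique(nm[duplicated(nm)]), collapse = ", ")))
    if (length(s) && length(unique(Biostrings::width(s))) != 1L)
        msg <- c(msg, "all records must have equal (gapped) length")
    if (length(object@targetId) != 1L || !(object@targetId %in% nm))
        msg <- c(msg, sprintf("targetId '%s' not among record ids",
                              paste(object@targetId, collapse = ",")))
    bad <- .badAlphabet(as.character(s), allow_gap = TRUE)
    if (length(bad))
        msg <- c(msg, sprintf("records with characters outside %s: %s",
                              paste(ALIGN_ALPHABET, collapse = ""),
                              paste(nm[bad], collapse = ", ")))
    if (object@primerLen < 0L || (length(s) &&
                                  object@primerLen > Biostrings::width(s)[1]))
        msg <- c(msg, "primerLen must lie in [0, column count]")
    if (length(msg)) msg else TRUE
})

# indices of sequences containing characters outside the DNA alphabet
.badAlphabet <- function(x, allow_gap = FALSE) {
    pat <- if (allow_gap) "[^ACGTN-]" else "[^ACGTN]"
    which(grepl(pat, x))
}

#' Construct a ReferenceAlignment
#'
#' @param seqs Named character vector or [Biostrings::DNAStringSet] of
#'   equal-length gapped sequences.
#' @param targetId Id of the target record (must be present in `seqs`).
#' @param primerLen Columns of a prepended universal-primer track;
#'   normally left at 0 and set by [appendPrimerToAlignment()].
#' @return A [ReferenceAlignment-class] object.
#' @examples
#' aln <- referenceAlignment(
#'   c(pred = "ACGTACGT", prey = "ACG-ACGT"), targetId = "pred")
#' columnCount(aln)
#' @export
referenceAlignment <- function(seqs, targetId, primerLen = 0L) {
    if (is.character(seqs)) seqs <- Biostrings::DNAStringSet(seqs)
    new("ReferenceAlignment", seqs = seqs, targetId = targetId,
        primerLen = as.integer(primerLen))
}

#' @describeIn referenceAlignment Number of alignment columns.
#' @param x,object A `ReferenceAlignment`.
#' @export
columnCount <- function(x) {
    stopifnot(is(x, "ReferenceAlignment"))
    if (length(x@seqs)) Biostrings::width(x@seqs)[1] else 0L
}

#' @describeIn referenceAlignment The gapped sequences as a `DNAStringSet`.
#' @export
alignedSeqs <- function(x) {
    stopifnot(is(x, "ReferenceAlignment"))
    x@seqs
}

#' @describeIn referenceAlignment Id of the designated target record.
#' @export
targetId <- function(x) {
    stopifnot(is(x, "ReferenceAlignment"))
    x@targetId
}

#' @describeIn referenceAlignment Length of the appended primer track (0 if
#'   none).
#' @export
primerLength <- function(x) {
    stopifnot(is(x, "ReferenceAlignment"))
    x@primerLen
}

#' @export
setMethod("show", "ReferenceAlignment", function(object) {
    cat(sprintf("ReferenceAlignment: %d records x %d columns\n",
                length(object@seqs), columnCount(object)))
    cat(sprintf("  target: %s%s\n", object@targetId,
                if (object@primerLen > 0L)
                    sprintf("  (primer track: %d columns)", object@primerLen)
                else ""))
})

#' Samples-by-taxa read-count container with blocker metadata
#'
#' A thin [SummarizedExperiment::SummarizedExperiment] subclass holding an
#' OTU/read-count matrix (rows = taxa, columns = samples) whose `colData`
#' records, for every sequencing sample, the underlying DNA template
#' (`dnaSampleId`) and which blocking primer was included (`blockerId`,
#' `NA` for unblocked controls). Blocked and unblocked samples that share a
#' `dnaSampleId` form the pairs used by [suppressionMetrics()] and
#' [evaluateBlockers()].
#'
#' @seealso [otuExperiment()], [suppressionMetrics()]
#' @export
setClass("OtuExperiment", contains = "SummarizedExperiment")

setValidity("OtuExperiment", function(object) {
    msg <- character()
    if (!"counts" %in% SummarizedExperiment::assayNames(object))
        msg <- c(msg, "assay 'counts' is required")
    else {
        cts <- SummarizedExperiment::assay(object, "counts")
        if (any(is.na(cts)) || any(cts < 0))
            msg <- c(msg, "counts must be non-negative and non-missing")
    }
    cd <- SummarizedExperiment::colData(object)
    need <- c("dnaSampleId", "blockerId")
    if (!all(need %in% colnames(cd)))
        msg <- c(msg, "colData must contain dnaSampleId and blockerId")
    if (is.null(rownames(object)) || anyDuplicated(rownames(object)))
        msg <- c(msg, "taxa (rownames) must be unique and non-null")
    if (length(msg)) msg else TRUE
})

#' Construct an OtuExperiment
#'
#' @param counts Non-negative integer matrix, rows = taxa (unique
#'   rownames), columns = samples.
#' @param dnaSampleId Character vector, one per sample: the DNA template a
#'   sequencing sample was amplified from.
#' @param blockerId Character vector, one per sample: blocking primer
#'   included in the reaction, or `NA` for unblocked controls.
#' @return An [OtuExperiment-class].
#' @examples
#' cts <- matrix(c(100, 5, 2, 120), 2,
#'               dimnames = list(c("predator", "host"), c("s1", "s2")))
#' oe <- otuExperiment(cts, dnaSampleId = c("M1", "M1"),
#'                     blockerId = c(NA, "B1"))
#' @export
otuExperiment <- function(counts, dnaSampleId, blockerId) {
    counts <- as.matrix(counts)
    se <- SummarizedExperiment::SummarizedExperiment(
        assays = list(counts = counts),
        colData = S4Vectors::DataFrame(
            dnaSampleId = as.character(dnaSampleId),
            blockerId = as.character(blockerId),
            row.names = colnames(counts)))
    as(se, "OtuExperiment")
}

#' @describeIn otuExperiment Read-count matrix accessor.
#' @param x An `OtuExperiment`.
#' @export
otuCounts <- function(x) {
    stopifnot(is(x, "OtuExperiment"))
    SummarizedExperiment::assay(x, "counts")
}
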