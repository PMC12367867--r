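#' Read a FASTA file of DNA sequences
#'
#' Reads marker-region reference sequences. Ids are the first whitespace
#' token of each header and must be unique; lowercase bases are normalized
#' to uppercase. Only `A`, `C`, `G`, `T`, `N` are accepted (plus `-` when
#' `aligned = TRUE`); other IUPAC ambiguity codes are rejected at parse
#' time. Malformed input is reported with the offending line number.
#'
#' @param path Path to a FASTA file.
#' @param aligned Set `TRUE` when the file holds a gapped alignment, so
#'   that `-` is an admissible character.
#' @return A named [Biostrings::DNAStringSet] (empty for an empty file),
#'   with descriptions (header text after the id) in `mcols(x)$description`.
#' @examples
#' tf <- tempfile(fileext = ".fasta")
#' writeLines(c(">a", "ACGT", ">b", "GGCC"), tf)
#' readFasta(tf)
#' @export
readFasta <- function(path, aligned = FALSE) {
    if (!file.exists(path)) stop("file not found: ", path)
    lines <- readLines(path, warn = FALSE)
    nonblank <- which(nzchar(trimws(lines)))
    if (!length(nonblank)) return(Biostrings::DNAStringSet())
    hdr <- grepl("^>", lines)
    if (!hdr[nonblank[1]])
        stop(sprintf("FASTA parse error at line %d: expected a '>' header",
                     nonblank[1]))
    ids <- character(); desc <- character(); seqs <- character()
    cur <- NULL; curline <- NA_integer_
    flush <- function() {
        if (is.null(cur)) return()
        if (!nzchar(cur$seq))
            stop(sprintf("FASTA parse error at line %d: empty sequence for '%s'",
                         curline, cur$id))
        ids <<- c(ids, cur$id); desc <<- c(desc, cur$desc)
        seqs <<- c(seqs, cur$seq)
    }
    for (i in seq_along(lines)) {
        ln <- lines[i]
        if (!nzchar(trimws(ln))) next
        if (grepl("^>", ln)) {
            flush()
            id <- sub("^>\\s*", "", ln)
            d <- sub("^\\S*\\s*", "", id)
            id <- sub("\\s.*$", "", id)
            if (!nzchar(id))
                stop(sprintf("FASTA parse error at line %d: empty header id", i))
            cur <- list(id = id, desc = d, seq = "")
            curline <- i
        } else {
            cur$seq <- paste0(cur$seq, toupper(gsub("\\s", "", ln)))
        }
    }
    flush()
    if (anyDuplicated(ids))
        stop("duplicate FASTA ids: ",
             paste(unique(ids[duplicated(ids)]), collapse = ", "))
    bad <- .badAlphabet(seqs, allow_gap = aligned)
    if (length(bad)) {
        what <- if (aligned) "characters outside ACGTN-"
                else "characters outside ACGTN (is this an aligned file?)"
        stop(sprintf("sequence '%s' contains %s", ids[bad[1]], what))
    }
    out <- Biostrings::DNAStringSet(setNames(seqs, ids))
    S4Vectors::mcols(out)$description <- desc
    out
}

#' Write sequences to FASTA
#'
#' @param seqs Named character vector or [Biostrings::DNAStringSet].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
writeFasta <- function(seqs, path) {
    if (is.character(seqs)) seqs <- Biostrings::DNAStringSet(seqs)
    Biostrings::writeXStringSet(seqs, path)
    invisible(path)
}

#' Load a pre-aligned (gapped) FASTA as a ReferenceAlignment
#'
#' @inheritParams readFasta
#' @param targetId Id of the target record.
#' @return A [ReferenceAlignment-class].
#' @export
loadAlignment <- function(path, targetId) {
    referenceAlignment(readFasta(path, aligned = TRUE), targetId = targetId)
}

.degap <- function(x) gsub("-", "", as.character(x), fixed = TRUE)

.checkUngappedDna <- function(x, what = "sequence") {
    x <- toupper(as.character(x))
    if (!length(x) || any(!nzchar(x)))
        stop(what, " must be non-empty")
    if (any(grepl("-", x, fixed = TRUE)))
        stop(what, " must be ungapped (contains '-'); ",
             "load pre-aligned data with loadAlignment()")
    bad <- .badAlphabet(x, allow_gap = FALSE)
    if (length(bad))
        stop(what, " contains characters outside ACGTN")
    x
}

#' Global pairwise alignment (Needleman-Wunsch, linear gaps)
#'
#' Deterministic global alignment of two short DNA sequences. `N` is
#' scored as a mismatch against every base, including `N`. Traceback ties
#' are broken in a fixed order (diagonal, then a gap in `b`, then a gap in
#' `a`), so the returned alignment is reproducible.
#'
#' @param a,b Ungapped DNA strings (`A,C,G,T,N`).
#' @param match,mismatch,gap Scores per aligned column; defaults `+1`,
#'   `-1`, `-2` suit short rRNA marker fragments.
#' @return A list with `alignedA`, `alignedB` (equal-length gapped
#'   strings) and `score`.
#' @examples
#' needlemanWunsch("ACGT", "AGT")
#' @export
needlemanWunsch <- function(a, b, match = 1L, mismatch = -1L, gap = -2L) {
    a <- .checkUngappedDna(a, "a"); b <- .checkUngappedDna(b, "b")
    r <- nw_align_cpp(a, b, as.integer(match), as.integer(mismatch),
                      as.integer(gap), FALSE)
    list(alignedA = r$aligned_a, alignedB = r$aligned_b, score = r$score)
}

#' Center-star multiple alignment of short marker sequences
#'
#' Builds a small multiple alignment by choosing the center sequence that
#' maximizes its summed pairwise global-alignment score against all others,
#' aligning every other sequence to that center, and merging the pairwise
#' alignments under a once-a-gap-always-a-gap rule. Intended for a few
#' hundred sequences of a couple hundred bases at most — the scale of a
#' curated single-marker reference set — not as a general-purpose MSA.
#'
#' @param seqs Named character vector or [Biostrings::DNAStringSet] of
#'   at least two ungapped sequences.
#' @param targetId Id of the target record in the resulting alignment.
#' @inheritParams needlemanWunsch
#' @return A [ReferenceAlignment-class]; degapping any record recovers its
#'   input sequence.
#' @examples
#' aln <- centerStarMsa(c(t = "ACGTTTTTACG", a = "ACGACG", b = "ACGACG"),
#'                      targetId = "t")
#' @export
centerStarMsa <- function(seqs, targetId, match = 1L, mismatch = -1L,
                          gap = -2L) {
    if (is(seqs, "DNAStringSet")) seqs <- as.character(seqs)
    if (length(seqs) < 2L)
        stop("center-star alignment needs at least 2 sequences")
    if (is.null(names(seqs)) || any(!nzchar(names(seqs))))
        stop("sequences must be named")
    seqs <- vapply(seqs, .checkUngappedDna, "", what = "record")
    n <- length(seqs)
    sc <- nw_score_many_cpp(unname(seqs), as.integer(match),
                            as.integer(mismatch), as.integer(gap))
    center <- which.max(rowSums(sc))
    cseq <- seqs[[center]]
    L <- nchar(cseq)
    others <- setdiff(seq_len(n), center)

    # per-alignment: center-with-gaps decomposed into L+1 insertion slots
    slotGaps <- matrix(0L, nrow = n, ncol = L + 1L)
    insChars <- vector("list", n)   # characters of seq falling in each slot
    coreChars <- vector("list", n)  # characters of seq aligned to center bases
    for (i in others) {
        al <- nw_align_cpp(cseq, seqs[[i]], as.integer(match),
                           as.integer(mismatch), as.integer(gap), FALSE)
        ca <- strsplit(al$aligned_a, "")[[1]]
        sa <- strsplit(al$aligned_b, "")[[1]]
        ins <- vector("list", L + 1L); core <- character(L)
        slot <- 1L; buf <- character()
        for (k in seq_along(ca)) {
            if (ca[k] == "-") {
                buf <- c(buf, sa[k])
            } else {
                ins[[slot]] <- buf; buf <- character()
                core[slot] <- sa[k]
                slot <- slot + 1L
            }
        }
        ins[[slot]] <- buf
        slotGaps[i, ] <- vapply(ins, length, 0L)
        insChars[[i]] <- ins; coreChars[[i]] <- core
    }
    g <- apply(slotGaps, 2, max)  # master insertion width per slot

    buildRow <- function(ins, core) {
        parts <- character(0)
        for (s in seq_len(L + 1L)) {
            block <- if (is.null(ins)) character() else ins[[s]]
            pad <- g[s] - length(block)
            parts <- c(parts, block, rep("-", pad),
                       if (s <= L) core[s] else character())
        }
        paste(parts, collapse = "")
    }
    out <- character(n)
    cchars <- strsplit(cseq, "")[[1]]
    out[center] <- buildRow(NULL, cchars)
    for (i in others) out[i] <- buildRow(insChars[[i]], coreChars[[i]])
    names(out) <- names(seqs)
    referenceAlignment(out, targetId = targetId)
}

#' Prepend a universal primer track to a reference alignment
#'
#' Mirrors the design step of appending the universal forward primer to
#' the 5' end of the alignment so that blocker design coordinates cover
#' primer + marker. The primer binds every community member, so its
#' sequence is prepended to each record; existing columns shift right by
#' `nchar(primer)` and the primer track length is recorded (see
#' [primerLength()]).
#'
#' @param aln A [ReferenceAlignment-class].
#' @param primer Ungapped primer sequence (may be `""`, a no-op).
#' @return The extended [ReferenceAlignment-class].
#' @export
appendPrimerToAlignment <- function(aln, primer) {
    stopifnot(is(aln, "ReferenceAlignment"))
    if (!nzchar(primer)) return(aln)
    primer <- .checkUngappedDna(primer, "primer")
    ext <- paste0(primer, as.character(aln@seqs))
    names(ext) <- names(aln@seqs)
    referenceAlignment(ext, targetId = aln@targetId,
                       primerLen = aln@primerLen + nchar(primer))
}

.alnMatrix <- function(aln) {
    ch <- strsplit(as.character(aln@seqs), "")
    do.call(rbind, ch)  # rows = records, cols = alignment columns
}

#' Find target-discriminative gap windows in an alignment
#'
#' Scans for maximal runs of consecutive columns in which the target
#' carries sequence while (at least a fraction `gapFrac` of) the
#' non-target records are gapped — i.e. a target-specific insertion, the
#' kind of motif a blocking primer is aimed at. The mirrored mode finds
#' windows where the target is gapped and the non-targets carry sequence.
#'
#' @param aln A [ReferenceAlignment-class] with its target set.
#' @param minLen Minimum window length in columns (default 15).
#' @param gapFrac Minimum fraction of non-target records that must be
#'   gapped in every window column (default 0.9, tolerating a few
#'   non-target sequences that share the insertion).
#' @param mode `"target_insert"` (default) or `"nontarget_insert"` (the
#'   mirrored criterion).
#' @return A [S4Vectors::DataFrame] with 0-based half-open `start`, `end`,
#'   `length`, and the mean non-target gap fraction over the window;
#'   windows are non-overlapping and sorted by `start`.
#' @export
findDiscriminativeGap <- function(aln, minLen = 15L, gapFrac = 0.9,
                                  mode = c("target_insert",
                                           "nontarget_insert")) {
    stopifnot(is(aln, "ReferenceAlignment"))
    mode <- match.arg(mode)
    if (!(gapFrac > 0 && gapFrac <= 1))
        stop("gapFrac must lie in (0, 1]")
    m <- .alnMatrix(aln)
    ti <- match(aln@targetId, names(aln@seqs))
    tgt <- m[ti, ]
    nt <- m[-ti, , drop = FALSE]
    empty <- S4Vectors::DataFrame(start = integer(), end = integer(),
                                  length = integer(),
                                  nontargetGapFraction = numeric())
    if (nrow(nt) == 0L) return(empty)
    frac <- colMeans(nt == "-")
    ok <- if (mode == "target_insert") tgt != "-" & frac >= gapFrac
          else tgt == "-" & (1 - frac) >= gapFrac
    r <- rle(ok)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    keep <- r$values & r$lengths >= minLen
    if (!any(keep)) return(empty)
    starts <- starts[keep]; ends <- ends[keep]
    S4Vectors::DataFrame(
        start = starts - 1L, end = ends,
        length = ends - starts + 1L,
        nontargetGapFraction = mapply(function(s, e) mean(frac[s:e]),
                                      starts, ends))
}

#' Per-column alignment summary
#'
#' @param aln A [ReferenceAlignment-class].
#' @return A [S4Vectors::DataFrame] with 0-based `column`, the target's
#'   base, the non-target gap fraction, and the majority-rule consensus
#'   character (ties broken alphabetically, gap sorting last).
#' @export
alignmentSummary <- function(aln) {
    stopifnot(is(aln, "ReferenceAlignment"))
    m <- .alnMatrix(aln)
    ti <- match(aln@targetId, names(aln@seqs))
    nt <- m[-ti, , drop = FALSE]
    cons <- apply(m, 2, function(col) {
        tb <- table(factor(col, levels = c("A", "C", "G", "T", "N", "-")))
        names(tb)[which.max(tb)]
    })
    S4Vectors::DataFrame(
        column = seq_len(ncol(m)) - 1L,
        targetBase = m[ti, ],
        nontargetGapFraction = if (nrow(nt)) colMeans(nt == "-")
                               else rep(NA_real_, ncol(m)),
        consensus = cons)
}

#' @rdname alignmentSummary
#' @param path Output TSV path.
#' @return `writeAlignmentSummary` returns `path` invisibly.
#' @export
writeAlignmentSummary <- function(aln, path) {
    write.table(as.data.frame(alignmentSummary(aln)), path, sep = "\t",
                quote = FALSE, row.names = FALSE)
    invisible(path)
}
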