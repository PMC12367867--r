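#' Design configuration for blocking-primer enumeration
#'
#' Bundles the tunable parameters of candidate enumeration and ranking.
#' Length defaults (34/36) follow the motivating design in which the two
#' blocker lengths were chosen to span a 23-bp target-specific insertion;
#' `lengths` may list discrete lengths (e.g. `c(34, 36)`) and overrides the
#' `lenMin:lenMax` range.
#'
#' @param lenMin,lenMax Candidate length bounds in bases.
#' @param lengths Optional integer vector of exact candidate lengths.
#' @param minOverlap,maxOverlap Bounds on the 3'-end overlap (bases) between
#'   the universal primer footprint and the blocker's 5' end.
#' @param saltmM Monovalent salt concentration (mM) for [nnTm()].
#' @param oligoUm Oligo concentration (uM) for [nnTm()].
#' @param gapFrac,minLen Forwarded to [findDiscriminativeGap()].
#' @param tmBand Two-element numeric; candidates whose Tm falls inside the
#'   band are preferred by [rankCandidates()].
#' @param identityFloor Minimum identity for placing the universal primer
#'   on the target by local alignment when no exact match exists.
#' @return A validated list of class `DesignConfig`.
#' @export
designConfig <- function(lenMin = 34L, lenMax = 36L, lengths = NULL,
                         minOverlap = 6L, maxOverlap = 10L,
                         saltmM = 50, oligoUm = 0.25,
                         gapFrac = 0.9, minLen = 15L,
                         tmBand = c(60, 70), identityFloor = 0.9) {
    lenMin <- as.integer(lenMin); lenMax <- as.integer(lenMax)
    if (lenMin > lenMax) stop("lenMin must be <= lenMax")
    if (!is.null(lengths)) {
        lengths <- sort(unique(as.integer(lengths)))
        if (any(lengths < 1L)) stop("lengths must be positive")
    }
    minOverlap <- as.integer(minOverlap)
    maxOverlap <- as.integer(maxOverlap)
    if (minOverlap < 1L || minOverlap > maxOverlap)
        stop("need 0 < minOverlap <= maxOverlap")
    if (length(tmBand) != 2L || tmBand[1] > tmBand[2])
        stop("tmBand must be c(low, high)")
    structure(list(lenMin = lenMin, lenMax = lenMax, lengths = lengths,
                   minOverlap = minOverlap, maxOverlap = maxOverlap,
                   saltmM = saltmM, oligoUm = oligoUm, gapFrac = gapFrac,
                   minLen = as.integer(minLen), tmBand = tmBand,
                   identityFloor = identityFloor),
              class = "DesignConfig")
}

NN_DH <- c(AA = -7.9, AT = -7.2, TA = -7.2, CA = -8.5, GT = -8.4,
           CT = -7.8, GA = -8.2, CG = -10.6, GC = -9.8, GG = -8.0)
NN_DS <- c(AA = -22.2, AT = -20.4, TA = -21.3, CA = -22.7, GT = -22.4,
           CT = -21.0, GA = -22.2, CG = -27.2, GC = -24.4, GG = -19.9)
.RGAS <- 1.9872  # cal / (mol K)

.canonDinuc <- function(d) {
    comp <- c(A = "T", C = "G", G = "C", T = "A")
    ifelse(d %in% names(NN_DH), d,
           paste0(comp[substr(d, 2, 2)], comp[substr(d, 1, 1)]))
}

#' Nearest-neighbor duplex melting temperature
#'
#' Unified nearest-neighbor stack parameters with entropic monovalent-salt
#' correction (0.368 cal/K per phosphate times ln of the sodium molarity)
#' and the non-self-complementary initiation terms; the duplex is the
#' oligo against its perfect complement, so `nnTm(x)` equals
#' `nnTm(revcomp(x))`. 3' end modifications (C3 spacer, inverted dT) are
#' synthesis annotations and do not enter the calculation.
#'
#' @param seq DNA string(s), `A/C/G/T` only, length >= 8. `N` makes the
#'   duplex thermodynamics undefined and is an error.
#' @param saltmM Monovalent cation concentration in mM (default 50).
#' @param oligoUm Total oligo concentration in uM (default 0.25).
#' @return Melting temperature(s) in degrees Celsius.
#' @examples
#' nnTm("GATACCCCGCTATGCCTGCCATAAATAAACAACC")
#' @export
nnTm <- function(seq, saltmM = 50, oligoUm = 0.25) {
    vapply(seq, function(s) {
        s <- toupper(s)
        if (grepl("[^ACGT]", s))
            stop("Tm undefined: sequence contains non-ACGT characters")
        n <- nchar(s)
        if (n < 8L) stop("Tm requires length >= 8")
        b <- strsplit(s, "")[[1]]
        din <- .canonDinuc(paste0(b[-n], b[-1]))
        dH <- sum(NN_DH[din])
        dS <- sum(NN_DS[din])
        for (endb in b[c(1L, n)]) {
            if (endb %in% c("G", "C")) { dH <- dH + 0.1; dS <- dS - 2.8 }
            else                       { dH <- dH + 2.3; dS <- dS + 4.1 }
        }
        dS <- dS + 0.368 * (n - 1) * log(saltmM / 1000)
        dH * 1000 / (dS + .RGAS * log(oligoUm * 1e-6 / 4)) - 273.15
    }, numeric(1), USE.NAMES = FALSE)
}

# Locate the universal primer footprint on the (degapped) target sense
# strand: exact substring match first, then best local alignment subject to
# an identity floor. Returns the 1-based start.
.locatePrimer <- function(template, primer, identityFloor = 0.9) {
    hit <- regexpr(primer, template, fixed = TRUE)
    if (hit > 0) return(as.integer(hit))
    mat <- Biostrings::nucleotideSubstitutionMatrix(match = 1, mismatch = -1,
                                                    baseOnly = TRUE)
    al <- Biostrings::pairwiseAlignment(pattern = primer, subject = template,
                                        type = "local", substitutionMatrix = mat,
                                        gapOpening = 2, gapExtension = 2)
    ident <- Biostrings::nmatch(al) / nchar(primer)
    if (ident < identityFloor)
        stop(sprintf(paste0("universal primer not locatable on target ",
                            "(best identity %.2f < floor %.2f)"),
                     ident, identityFloor))
    s <- Biostrings::start(Biostrings::subject(al))
    # back up to where the primer's first base would sit
    as.integer(s - (Biostrings::start(Biostrings::pattern(al)) - 1L))
}

#' Enumerate annealing-inhibition blocker candidates
#'
#' Emits every subsequence of the target sense strand whose 5' end lies
#' inside the universal primer's footprint with a 3'-terminal overlap in
#' `[minOverlap, maxOverlap]` bases and whose length is admissible under
#' the configuration. Candidates read in the same strand and direction as
#' the forward universal primer, so each begins with the primer's 3'
#' terminal bases and extends into the target-specific region downstream.
#'
#' @param aln A [ReferenceAlignment-class]; enumerate after
#'   [appendPrimerToAlignment()] so the footprint is present on the target.
#' @param primer Universal forward primer sequence (5'->3', sense strand
#'   of the region it binds; length >= 10).
#' @param cfg A [designConfig()].
#' @return A [S4Vectors::DataFrame], ordered by `start` then `length`, with
#'   the candidate sequence, 0-based `start` on the appended coordinate
#'   system, `length`, `overlapLen` with the primer's 3' terminus, `tmC`
#'   from [nnTm()], and the specificity minima from [specificityScore()].
#'   The per-non-target score matrices are attached as
#'   `metadata(x)$specificity`.
#' @export
enumerateCandidates <- function(aln, primer, cfg = designConfig()) {
    stopifnot(is(aln, "ReferenceAlignment"))
    primer <- .checkUngappedDna(primer, "primer")
    if (nchar(primer) < 10L) stop("universal primer must be >= 10 bases")
    if (cfg$maxOverlap > nchar(primer))
        stop("maxOverlap exceeds primer length")
    template <- .degap(as.character(aln@seqs[[aln@targetId]]))
    lens <- if (!is.null(cfg$lengths)) cfg$lengths else cfg$lenMin:cfg$lenMax
    empty <- S4Vectors::DataFrame(
        id = character(), seq = character(), start = integer(),
        length = integer(), overlapLen = integer(), tmC = numeric(),
        minNontargetMismatches = integer(),
        minNontargetMismatchesWeighted = integer())
    if (nchar(template) < min(lens)) return(empty)
    p <- .locatePrimer(template, primer, cfg$identityFloor)
    fpEnd <- p + nchar(primer)          # 1-based exclusive
    rows <- list()
    for (o in cfg$minOverlap:cfg$maxOverlap) {
        s1 <- fpEnd - o                 # 1-based candidate start
        if (s1 < 1L) next
        for (len in lens) {
            if (s1 + len - 1L > nchar(template)) next
            rows[[length(rows) + 1L]] <-
                list(seq = substr(template, s1, s1 + len - 1L),
                     start = s1 - 1L, length = len, overlapLen = o)
        }
    }
    if (!length(rows)) return(empty)
    df <- S4Vectors::DataFrame(
        seq = vapply(rows, `[[`, "", "seq"),
        start = vapply(rows, `[[`, 0L, "start"),
        length = vapply(rows, `[[`, 0L, "length"),
        overlapLen = vapply(rows, `[[`, 0L, "overlapLen"))
    df <- df[order(df$start, df$length), , drop = FALSE]
    df$tmC <- vapply(df$seq, function(s) {
        if (grepl("N", s)) NA_real_ else nnTm(s, cfg$saltmM, cfg$oligoUm)
    }, numeric(1), USE.NAMES = FALSE)
    spec <- lapply(seq_len(nrow(df)), function(i)
        specificityScore(df[i, , drop = FALSE], aln))
    df$minNontargetMismatches <-
        vapply(spec, function(x) x$min, 0L)
    df$minNontargetMismatchesWeighted <-
        vapply(spec, function(x) x$minWeighted, 0L)
    df <- S4Vectors::DataFrame(id = sprintf("cand_%03d", seq_len(nrow(df))),
                               df)
    S4Vectors::metadata(df)$specificity <- spec
    S4Vectors::metadata(df)$blockerToPrimerRatio <- "10:1"
    df
}

#' Per-non-target specificity of a blocker candidate
#'
#' Counts, for every non-target record, the alignment columns over the
#' candidate footprint at which the non-target mismatches the target or is
#' gapped (a gap counts as a mismatch — a candidate laid across a
#' target-specific insertion therefore scores at least the insertion's
#' width against every species lacking it). A 3'-weighted variant doubles
#' mismatches in the 3'-most `k` columns, where terminal mismatches
#' disrupt annealing most.
#'
#' @param cand A candidate: a one-row [S4Vectors::DataFrame] or list with
#'   0-based `start` and `length` on the target's degapped coordinates.
#' @param aln The [ReferenceAlignment-class] the candidate was designed on.
#' @param k Number of 3'-terminal columns whose mismatches count double.
#' @return A list: `perNontarget` and `perNontargetWeighted` (named
#'   integer vectors), `min`, `minWeighted`.
#' @export
specificityScore <- function(cand, aln, k = 5L) {
    stopifnot(is(aln, "ReferenceAlignment"))
    start <- as.integer(cand$start); len <- as.integer(cand$length)
    m <- .alnMatrix(aln)
    ti <- match(aln@targetId, names(aln@seqs))
    tgt <- m[ti, ]
    colIdx <- which(tgt != "-")  # degapped position -> alignment column
    if (start < 0L || start + len > length(colIdx))
        stop("candidate footprint lies outside the alignment")
    cols <- colIdx[(start + 1L):(start + len)]
    nt <- m[-ti, , drop = FALSE]
    tchars <- tgt[cols]
    w <- rep(1L, len)
    if (k > 0L) w[max(1L, len - k + 1L):len] <- 2L
    per <- apply(nt[, cols, drop = FALSE], 1, function(row) {
        bad <- row == "-" | row == "N" | tchars == "N" | row != tchars
        c(sum(bad), sum(w[bad]))
    })
    plain <- as.integer(per[1, ]); weighted <- as.integer(per[2, ])
    names(plain) <- names(weighted) <- rownames(nt)
    list(perNontarget = plain, perNontargetWeighted = weighted,
         min = if (length(plain)) min(plain) else NA_integer_,
         minWeighted = if (length(weighted)) min(weighted) else NA_integer_)
}

#' Rank blocker candidates
#'
#' Stable deterministic ordering: highest minimum non-target mismatch
#' count first (most discriminative), then candidates whose Tm falls in
#' the configured band, then shorter before longer, then leftmost start.
#'
#' @param cands Candidate table from [enumerateCandidates()].
#' @param cfg A [designConfig()] (supplies `tmBand`).
#' @return The reordered candidate table.
#' @export
rankCandidates <- function(cands, cfg = designConfig()) {
    if (!nrow(cands)) stop("no candidates to rank")
    inBand <- !is.na(cands$tmC) &
        cands$tmC >= cfg$tmBand[1] & cands$tmC <= cfg$tmBand[2]
    o <- order(-cands$minNontargetMismatches, !inBand,
               cands$length, cands$start)
    cands[o, , drop = FALSE]
}

#' Render a vendor-style ordering string for a blocker
#'
#' Appends the synthesis dialect token for the 3' end modification
#' (`"/3SpC3/"` for a C3 spacer, `"/3InvdT/"` for an inverted dT). The
#' purification grade is recorded as metadata only — it does not alter the
#' ordering string.
#'
#' @param seq Blocker sequence (5'->3').
#' @param mod One of `"C3_spacer"`, `"inverted_dT"`, `"none"`.
#' @param purification One of `"HPLC"`, `"desalted"`, `"none"`.
#' @return The ordering string, with the purification grade in
#'   `attr(, "purification")`.
#' @examples
#' annotateModification("GATACCCCGCTATGCCTGCCATAAATAAACAACC", "C3_spacer")
#' @export
annotateModification <- function(seq, mod = c("none", "C3_spacer",
                                              "inverted_dT"),
                                 purification = c("none", "HPLC",
                                                  "desalted")) {
    mod <- match.arg(mod)
    purification <- match.arg(purification)
    suffix <- switch(mod, C3_spacer = "/3SpC3/", inverted_dT = "/3InvdT/",
                     none = "")
    structure(paste0(seq, suffix), purification = purification)
}

#' One-call blocker design
#'
#' Appends the universal primer to the alignment, locates discriminative
#' gap windows, enumerates and ranks candidates, and renders ordering
#' strings. The returned report also carries the standard 10:1
#' blocker-to-primer concentration guidance as metadata.
#'
#' @inheritParams enumerateCandidates
#' @param mod,purification Passed to [annotateModification()].
#' @return A list with `candidates` (ranked table including
#'   `orderingString`), `windows` from [findDiscriminativeGap()], and
#'   `guidance`.
#' @export
designBlockers <- function(aln, primer, cfg = designConfig(),
                           mod = "C3_spacer", purification = "HPLC") {
    aln2 <- appendPrimerToAlignment(aln, primer)
    windows <- findDiscriminativeGap(aln2, minLen = cfg$minLen,
                                     gapFrac = cfg$gapFrac)
    cands <- enumerateCandidates(aln2, primer, cfg)
    if (nrow(cands)) {
        cands <- rankCandidates(cands, cfg)
        cands$orderingString <- vapply(
            cands$seq, function(s)
                as.character(annotateModification(s, mod, purification)),
            "", USE.NAMES = FALSE)
        cands$modification <- mod
        cands$purification <- purification
    }
    list(candidates = cands, windows = windows,
         guidance = list(blockerToPrimerRatio = "10:1",
                         note = paste("use blocking primer at 10x the",
                                      "universal primer concentration")))
}
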