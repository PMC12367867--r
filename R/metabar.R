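.qualToChar <- function(q, len) {
    if (is.null(q)) return(strrep(rawToChar(as.raw(30L + 33L)), len))
    if (is.character(q)) return(q)
    vapply(q, function(v) rawToChar(as.raw(pmin(pmax(v, 0L), 93L) + 33L)),
           "")
}

#' Merge paired-end reads, trimmed to the overlap
#'
#' The reverse mate is reverse-complemented, then the longest
#' suffix/prefix overlap of at least `minOverlap` bases with at most
#' `maxMismatch` mismatches is taken. The merged sequence is the overlap
#' region only (the union is never returned): with short amplicons fully
#' spanned by both mates this recovers exactly the amplicon and discards
#' read-through. At disagreeing positions the higher-quality base wins;
#' quality ties become `N`.
#'
#' @param fwd,rev Character vectors of forward/reverse read sequences.
#' @param fwdQual,revQual Optional qualities, either Phred+33 strings or
#'   lists of integer Phred vectors; `NULL` assumes Q30 throughout.
#' @param maxMismatch Maximum mismatches tolerated in the overlap
#'   (default 2).
#' @param minOverlap Minimum admissible overlap in bases (default 10;
#'   guards against spurious tiny overlaps).
#' @return A [S4Vectors::DataFrame] with `seq`, `qual`, `overlapLen`, and
#'   `status` (`"merged"` or `"no_overlap"`; rejected pairs carry `NA`
#'   sequences).
#' @export
mergePairs <- function(fwd, rev, fwdQual = NULL, revQual = NULL,
                       maxMismatch = 2L, minOverlap = 10L) {
    if (length(fwd) != length(rev))
        stop("fwd and rev must have equal length")
    if (!length(fwd))
        return(S4Vectors::DataFrame(seq = character(), qual = character(),
                                    overlapLen = integer(),
                                    status = character()))
    if (any(!nzchar(fwd)) || any(!nzchar(rev)))
        stop("reads must be non-empty")
    fwd <- toupper(fwd); rev <- toupper(rev)
    revc <- as.character(Biostrings::reverseComplement(
        Biostrings::DNAStringSet(rev)))
    fq <- .qualToChar(fwdQual, 0L)
    rq <- .qualToChar(revQual, 0L)
    if (is.null(fwdQual)) fq <- strrep("?", nchar(fwd))   # '?' = Q30
    if (is.null(revQual)) rq <- strrep("?", nchar(rev))
    if (any(nchar(fq) != nchar(fwd)) || any(nchar(rq) != nchar(rev)))
        stop("sequence and quality lengths must match per mate")
    # reverse the reverse-mate quality string to track the complemented read
    rqr <- vapply(strsplit(rq, ""), function(x)
        paste(rev(x), collapse = ""), "")
    r <- merge_pairs_cpp(fwd, revc, fq, rqr,
                         as.integer(maxMismatch), as.integer(minOverlap))
    S4Vectors::DataFrame(seq = r$seq, qual = r$qual,
                         overlapLen = r$overlap_len, status = r$status)
}

#' Length and homopolymer read filter
#'
#' Keeps a read iff its length does not exceed `maxLen` and its longest
#' single-base run does not exceed `maxHomopolymer`. The defaults (107
#' bases; run of 8) reflect the marker's maximum reference length and a
#' common amplicon-pipeline homopolymer screen.
#'
#' @param seqs Character vector of merged reads.
#' @param maxLen Maximum length in bases (default 107).
#' @param maxHomopolymer Maximum single-base run (default 8).
#' @return A list: `kept` (character vector) and `removed` (a
#'   [S4Vectors::DataFrame] of sequence and reason). Kept and removed
#'   partition the input.
#' @export
filterReads <- function(seqs, maxLen = 107L, maxHomopolymer = 8L) {
    if (!length(seqs))
        return(list(kept = character(),
                    removed = S4Vectors::DataFrame(seq = character(),
                                                   reason = character())))
    tooLong <- nchar(seqs) > maxLen
    runs <- max_run_cpp(seqs)
    tooRunny <- runs > maxHomopolymer
    reason <- ifelse(tooLong, "length",
                     ifelse(tooRunny, "homopolymer", NA))
    drop <- tooLong | tooRunny
    list(kept = seqs[!drop],
         removed = S4Vectors::DataFrame(seq = seqs[drop],
                                        reason = reason[drop]))
}

#' Dereplicate sequences
#'
#' Exact-string deduplication with counts; counts always sum to the input
#' size. Output ordered by count descending, then lexicographically.
#'
#' @param seqs Character vector.
#' @return A [S4Vectors::DataFrame] with `seq` and `count`.
#' @export
dereplicate <- function(seqs) {
    if (!length(seqs))
        return(S4Vectors::DataFrame(seq = character(), count = integer()))
    tb <- table(seqs)
    df <- S4Vectors::DataFrame(seq = names(tb),
                               count = as.integer(tb))
    df[order(-df$count, df$seq), , drop = FALSE]
}

.splitTaxonomy <- function(taxonomy) {
    paths <- strsplit(taxonomy, ";", fixed = TRUE)
    depth <- unique(lengths(paths))
    if (length(depth) != 1L)
        stop("all taxonomy strings must have the same number of ranks")
    do.call(rbind, paths)
}

#' Classify a sequence by bootstrap rank confidence
#'
#' Nearest references by global-alignment identity; the per-rank
#' confidence is the fraction of bootstrap resamples of query positions
#' (with replacement) in which the top hit is unambiguous at that rank and
#' agrees with the full-data call. The assignment is the deepest rank with
#' confidence at or above the cutoff; if none qualifies the sequence is
#' unclassified. When several references tie for the top hit, ranks at
#' which they disagree cannot win, which is what pushes sequences that are
#' one base away from several confamilial references up to family level.
#'
#' This is a deliberately simple identity-ranked stand-in with documented
#' semantics, not a re-implementation of any published classifier.
#'
#' @param seq Query sequence (character).
#' @param refs Named character vector of reference sequences.
#' @param taxonomy Character vector of `;`-separated ranked taxonomy
#'   strings (e.g. `kingdom;...;species`), parallel to `refs`.
#' @param cutoff Confidence cutoff in percent (default 80).
#' @param bootstraps Number of bootstrap resamples (default 100).
#' @param seed Optional integer seed for the resampling.
#' @return A list: `taxon` (label at the assigned rank, or
#'   `"unclassified"`), `rank` (1-based rank index, `NA` if unclassified),
#'   `confidence` (percent at the assigned rank), and `confidences`
#'   (per-rank vector).
#' @export
classifySeq <- function(seq, refs, taxonomy, cutoff = 80, bootstraps = 100L,
                        seed = NULL) {
    if (!length(refs)) stop("refs must be non-empty")
    if (length(refs) != length(taxonomy))
        stop("refs and taxonomy must be parallel")
    if (!is.null(seed)) set.seed(seed)
    tax <- .splitTaxonomy(taxonomy)
    nRanks <- ncol(tax)
    prof <- mismatch_profile_cpp(toupper(seq), toupper(unname(refs)),
                                 1L, -1L, -2L)
    n <- nrow(prof)
    mmFull <- colSums(prof)
    topFull <- which(mmFull == min(mmFull))
    # consensus path: truncate at the deepest rank where all top hits agree
    consensus <- rep(NA_character_, nRanks)
    for (r in seq_len(nRanks)) {
        u <- unique(tax[topFull, r])
        if (length(u) == 1L) consensus[r] <- u else break
    }
    wins <- numeric(nRanks)
    for (b in seq_len(bootstraps)) {
        idx <- sample.int(n, n, replace = TRUE)
        mm <- colSums(prof[idx, , drop = FALSE])
        top <- which(mm == min(mm))
        for (r in seq_len(nRanks)) {
            if (is.na(consensus[r])) break
            u <- unique(tax[top, r])
            if (length(u) == 1L && u == consensus[r])
                wins[r] <- wins[r] + 1
            else break
        }
    }
    conf <- 100 * wins / bootstraps
    ok <- which(conf >= cutoff & !is.na(consensus))
    if (!length(ok))
        return(list(taxon = "unclassified", rank = NA_integer_,
                    confidence = NA_real_, confidences = conf))
    r <- max(ok)
    list(taxon = consensus[r], rank = r, confidence = conf[r],
         confidences = conf)
}

#' Cluster unique sequences into OTUs (single linkage)
#'
#' Pairwise distances are alignment-based mismatch fractions (mismatching
#' plus gapped columns over alignment length, from the deterministic
#' global aligner); clusters are single-linkage components cut at the
#' distance cutoff. The default 0.03 corresponds to a 97% similarity
#' threshold. Each OTU is represented by its most abundant member (ties
#' broken lexicographically) and carries the summed counts.
#'
#' @param seqs Character vector of unique sequences.
#' @param counts Integer counts parallel to `seqs`.
#' @param cutoff Distance cutoff (default 0.03).
#' @return A [S4Vectors::DataFrame] with `representative`, `count`, and a
#'   `members` CharacterList-like list column.
#' @export
clusterOtus <- function(seqs, counts, cutoff = 0.03) {
    if (!length(seqs))
        return(S4Vectors::DataFrame(representative = character(),
                                    count = integer()))
    if (length(seqs) != length(counts))
        stop("seqs and counts must be parallel")
    if (length(seqs) == 1L) {
        cl <- 1L
    } else {
        d <- nw_dist_cpp(seqs, 1L, -1L, -2L)
        hc <- stats::hclust(stats::as.dist(d), method = "single")
        cl <- stats::cutree(hc, h = cutoff)
    }
    out <- lapply(split(seq_along(seqs), cl), function(ix) {
        o <- ix[order(-counts[ix], seqs[ix])]
        list(representative = seqs[o[1]], count = sum(counts[ix]),
             members = seqs[o])
    })
    df <- S4Vectors::DataFrame(
        representative = unname(vapply(out, `[[`, "", "representative")),
        count = unname(vapply(out, function(x) as.integer(x$count), 0L)))
    df$members <- unname(lapply(out, `[[`, "members"))
    df[order(-df$count, df$representative), , drop = FALSE]
}

#' Toy amplicon pipeline: paired reads to per-taxon counts
#'
#' Runs merge, length/homopolymer filtering, dereplication (optionally
#' dropping low-count uniques as a pseudo-denoising step), bootstrap
#' classification of unique representatives, and single-linkage OTU
#' clustering; OTU counts are aggregated by assigned taxon label. Chimera
#' removal is recorded as an explicit no-op stage for provenance parity
#' with full-scale pipelines.
#'
#' @inheritParams mergePairs
#' @inheritParams filterReads
#' @param refs,taxonomy Reference sequences and taxonomy strings for
#'   [classifySeq()].
#' @param otuDist OTU distance cutoff (default 0.03; 0.01 for a 99%
#'   similarity threshold).
#' @param confidence,bootstraps Passed to [classifySeq()].
#' @param minCount Drop uniques with fewer reads before classification and
#'   clustering (default 1 = keep everything; 2 drops singletons).
#' @param seed Optional seed for the classification bootstrap.
#' @return A list: `counts` (named per-taxon read counts), `otus` (the OTU
#'   table with taxon assignments), `stats` (reads surviving each stage),
#'   `stages` (provenance markers).
#' @export
processReads <- function(fwd, rev, fwdQual = NULL, revQual = NULL,
                         refs, taxonomy,
                         maxMismatch = 2L, minOverlap = 10L,
                         maxLen = 107L, maxHomopolymer = 8L,
                         otuDist = 0.03, confidence = 80,
                         bootstraps = 100L, minCount = 1L, seed = NULL) {
    merged <- mergePairs(fwd, rev, fwdQual, revQual, maxMismatch, minOverlap)
    seqsM <- merged$seq[merged$status == "merged"]
    filt <- filterReads(seqsM, maxLen, maxHomopolymer)
    uni <- dereplicate(filt$kept)
    uni <- uni[uni$count >= minCount, , drop = FALSE]
    stages <- c("merge_pairs", "screen_length_homopolymer", "dereplicate",
                if (minCount > 1L) sprintf("drop_uniques_below_%d", minCount),
                "chimera_removal: no-op (out of scope)",
                "classify", "cluster_otus")
    if (!nrow(uni))
        return(list(counts = integer(0),
                    otus = S4Vectors::DataFrame(), stages = stages,
                    stats = c(input = length(fwd), merged = length(seqsM),
                              kept = length(filt$kept), uniques = 0L)))
    cls <- lapply(uni$seq, classifySeq, refs = refs, taxonomy = taxonomy,
                  cutoff = confidence, bootstraps = bootstraps, seed = seed)
    taxLabel <- vapply(cls, `[[`, "", "taxon")
    otus <- clusterOtus(uni$seq, uni$count, otuDist)
    otus$taxon <- taxLabel[match(otus$representative, uni$seq)]
    counts <- vapply(split(otus$count, otus$taxon), sum, 0L)
    list(counts = counts, otus = otus, stages = stages,
         stats = c(input = length(fwd), merged = length(seqsM),
                   kept = length(filt$kept), uniques = nrow(uni)))
}

#' Assemble per-sample taxon counts into an OtuExperiment
#'
#' @param countsList Named list of per-taxon named count vectors (one per
#'   sequencing sample).
#' @param dnaSampleId,blockerId Per-sample metadata vectors, parallel to
#'   `countsList` (`blockerId` `NA` = unblocked control).
#' @return An [OtuExperiment-class].
#' @export
buildOtuExperiment <- function(countsList, dnaSampleId, blockerId) {
    taxa <- sort(unique(unlist(lapply(countsList, names))))
    m <- vapply(countsList, function(x) {
        v <- setNames(integer(length(taxa)), taxa)
        v[names(x)] <- as.integer(x)
        v
    }, integer(length(taxa)))
    m <- matrix(m, nrow = length(taxa),
                dimnames = list(taxa, names(countsList)))
    otuExperiment(m, dnaSampleId, blockerId)
}

# blocked/unblocked column pairing for one blocker: returns a data.frame of
# dnaSampleId plus blocked and unblocked column indices
.pairColumns <- function(x, blocker) {
    cd <- SummarizedExperiment::colData(x)
    ub <- which(is.na(cd$blockerId))
    bl <- which(!is.na(cd$blockerId) & cd$blockerId == blocker)
    shared <- intersect(cd$dnaSampleId[bl], cd$dnaSampleId[ub])
    shared <- sort(shared)
    data.frame(dnaSampleId = shared,
               blocked = bl[match(shared, cd$dnaSampleId[bl])],
               unblocked = ub[match(shared, cd$dnaSampleId[ub])])
}

#' Per-blocker suppression metrics from an OTU table
#'
#' For each blocker, pairs every blocked sequencing sample with the
#' unblocked control of the same DNA template and reports the predator
#' read reduction `100 * (1 - mean(blocked) / mean(unblocked))` together
#' with the per-host-taxon fold change `mean(blocked) / mean(unblocked)`.
#'
#' @param x An [OtuExperiment-class].
#' @param predatorTaxon Row name of the predator taxon.
#' @return A [S4Vectors::DataFrame] with one row per blocker
#'   (`blockerId`, `nPairs`, `meanUnblocked`, `meanBlocked`,
#'   `predatorReductionPct`, `status`); per-taxon host fold changes are in
#'   `metadata(x)$hostChange` (taxa x blockers matrix).
#' @export
suppressionMetrics <- function(x, predatorTaxon) {
    stopifnot(is(x, "OtuExperiment"))
    cts <- otuCounts(x)
    if (!predatorTaxon %in% rownames(cts))
        stop("predator taxon '", predatorTaxon, "' not in table")
    cd <- SummarizedExperiment::colData(x)
    blockers <- sort(unique(cd$blockerId[!is.na(cd$blockerId)]))
    hosts <- setdiff(rownames(cts), predatorTaxon)
    hostChange <- matrix(NA_real_, length(hosts), length(blockers),
                         dimnames = list(hosts, blockers))
    rows <- lapply(blockers, function(b) {
        pr <- .pairColumns(x, b)
        if (!nrow(pr))
            return(data.frame(blockerId = b, nPairs = 0L,
                              meanUnblocked = NA_real_, meanBlocked = NA_real_,
                              predatorReductionPct = NA_real_,
                              status = "no_pairs"))
        mu <- mean(cts[predatorTaxon, pr$unblocked])
        mb <- mean(cts[predatorTaxon, pr$blocked])
        for (h in hosts) {
            hu <- mean(cts[h, pr$unblocked])
            if (hu > 0)
                hostChange[h, b] <<- mean(cts[h, pr$blocked]) / hu
        }
        if (mu == 0)
            return(data.frame(blockerId = b, nPairs = nrow(pr),
                              meanUnblocked = mu, meanBlocked = mb,
                              predatorReductionPct = NA_real_,
                              status = "zero_unblocked_predator"))
        data.frame(blockerId = b, nPairs = nrow(pr), meanUnblocked = mu,
                   meanBlocked = mb,
                   predatorReductionPct = 100 * (1 - mb / mu),
                   status = "ok")
    })
    out <- S4Vectors::DataFrame(do.call(rbind, rows))
    S4Vectors::metadata(out)$hostChange <- hostChange
    out
}

#' Paired t-test on read counts
#'
#' Differences are taken as `unblocked - blocked`, so suppression of the
#' taxon yields a positive statistic and enhancement (host rescue) a
#' negative one. Zero-variance differences are flagged, not an error.
#'
#' @param unblocked,blocked Equal-length (n >= 2) count vectors, paired by
#'   sample.
#' @return A list: `t`, `df`, `p` (two-sided), `meanUnblocked`,
#'   `meanBlocked`, `status` (`"ok"` or `"zero_variance"`).
#' @export
pairedT <- function(unblocked, blocked) {
    n <- length(unblocked)
    if (n < 2L || length(blocked) != n)
        stop("need equal-length vectors with n >= 2")
    d <- unblocked - blocked
    if (stats::sd(d) == 0)
        return(list(t = NA_real_, df = n - 1L, p = NA_real_,
                    meanUnblocked = mean(unblocked),
                    meanBlocked = mean(blocked), status = "zero_variance"))
    tt <- stats::t.test(unblocked, blocked, paired = TRUE)
    list(t = unname(tt$statistic), df = unname(tt$parameter),
         p = tt$p.value, meanUnblocked = mean(unblocked),
         meanBlocked = mean(blocked), status = "ok")
}

#' Sequential Bonferroni (Holm) correction
#'
#' Step-down Holm correction: adjusted p-values are running maxima of
#' `(m - i + 1) * p_(i)` capped at 1, and a test is significant when its
#' adjusted p-value is at or below `alpha`. Never more permissive than
#' plain Bonferroni, never less permissive than no correction.
#'
#' @param pvals Numeric p-values in (0, 1].
#' @param alpha Family-wise error level (default 0.05).
#' @return A [S4Vectors::DataFrame] with `p`, `pAdjusted`, `significant`,
#'   in the input order.
#' @export
holmCorrection <- function(pvals, alpha = 0.05) {
    if (any(is.na(pvals)) || any(pvals <= 0 | pvals > 1))
        stop("p-values must lie in (0, 1]")
    adj <- stats::p.adjust(pvals, method = "holm")
    S4Vectors::DataFrame(p = pvals, pAdjusted = adj,
                         significant = adj <= alpha)
}

#' Effectiveness verdict for one blocker
#'
#' A blocker is effective iff it significantly reduced the predator's
#' reads and no host taxon shows a significant reduction; significant host
#' *increases* (negative paired-t statistics) do not disqualify.
#'
#' @param predatorTest A list with `t` and `significant` for the predator
#'   comparison (Holm-corrected decision).
#' @param hostTests List of such lists for the host taxa.
#' @return A list: `effective` (logical) and `reasons` (character).
#' @export
effectivenessVerdict <- function(predatorTest, hostTests = list()) {
    reasons <- character()
    predOk <- isTRUE(predatorTest$significant) &&
        !is.na(predatorTest$t) && predatorTest$t > 0
    if (!predOk)
        reasons <- c(reasons, "predator reduction not significant")
    hostBad <- vapply(hostTests, function(h)
        isTRUE(h$significant) && !is.na(h$t) && h$t > 0, TRUE)
    if (any(hostBad))
        reasons <- c(reasons, paste("significant host reduction:",
                                    paste(names(hostTests)[hostBad],
                                          collapse = ", ")))
    list(effective = predOk && !any(hostBad), reasons = reasons)
}

#' Blocker-effectiveness statistics over an OTU table
#'
#' Runs [pairedT()] per blocker for the predator taxon and each host
#' taxon, applies [holmCorrection()] within each taxon's family of tests
#' (all blockers), and issues an [effectivenessVerdict()] per blocker.
#'
#' @param x An [OtuExperiment-class].
#' @param predatorTaxon Predator row name.
#' @param hostTaxa Host row names (default: every other taxon).
#' @param alpha Family-wise error level.
#' @return A list: `tests` (a [S4Vectors::DataFrame] with one row per
#'   blocker x taxon) and `verdicts` (named list per blocker).
#' @export
evaluateBlockers <- function(x, predatorTaxon, hostTaxa = NULL,
                             alpha = 0.05) {
    stopifnot(is(x, "OtuExperiment"))
    cts <- otuCounts(x)
    if (is.null(hostTaxa))
        hostTaxa <- setdiff(rownames(cts), predatorTaxon)
    cd <- SummarizedExperiment::colData(x)
    blockers <- sort(unique(cd$blockerId[!is.na(cd$blockerId)]))
    taxa <- c(predatorTaxon, hostTaxa)
    rows <- list()
    for (tx in taxa) {
        for (b in blockers) {
            pr <- .pairColumns(x, b)
            if (nrow(pr) < 2L) next
            r <- pairedT(cts[tx, pr$unblocked], cts[tx, pr$blocked])
            rows[[length(rows) + 1L]] <- data.frame(
                blockerId = b, taxon = tx, nPairs = nrow(pr),
                meanUnblocked = r$meanUnblocked,
                meanBlocked = r$meanBlocked, t = r$t, df = r$df, p = r$p,
                status = r$status, stringsAsFactors = FALSE)
        }
    }
    tests <- do.call(rbind, rows)
    tests$pAdjusted <- NA_real_
    tests$holmSignificant <- NA
    for (tx in taxa) {
        ix <- which(tests$taxon == tx & tests$status == "ok")
        if (!length(ix)) next
        hc <- holmCorrection(tests$p[ix], alpha)
        tests$pAdjusted[ix] <- hc$pAdjusted
        tests$holmSignificant[ix] <- hc$significant
    }
    verdicts <- lapply(blockers, function(b) {
        pRow <- tests[tests$blockerId == b & tests$taxon == predatorTaxon, ]
        hRows <- tests[tests$blockerId == b & tests$taxon %in% hostTaxa, ]
        hostTests <- setNames(lapply(seq_len(nrow(hRows)), function(i)
            list(t = hRows$t[i], significant = hRows$holmSignificant[i])),
            hRows$taxon)
        pt <- if (nrow(pRow))
            list(t = pRow$t[1], significant = pRow$holmSignificant[1])
        else list(t = NA_real_, significant = FALSE)
        effectivenessVerdict(pt, hostTests)
    })
    names(verdicts) <- blockers
    list(tests = S4Vectors::DataFrame(tests), verdicts = verdicts)
}
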