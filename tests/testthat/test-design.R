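test_that("enumeration reproduces the published 34/36-mer pair", {
    aln <- appendPrimerToAlignment(makeFixtureAlignment(), PRIMER_12SV5F)
    cfg <- designConfig(lengths = c(34L, 36L), minOverlap = 8L,
                        maxOverlap = 8L)
    cands <- enumerateCandidates(aln, PRIMER_12SV5F, cfg)
    expect_equal(unname(cands$seq), c(BLOCKER_34, BLOCKER_36))
    expect_equal(cands$overlapLen, c(8L, 8L))
    expect_equal(cands$length, c(34L, 36L))
    # same 0-based start: the primer's 3' terminus minus the overlap
    expect_equal(unique(cands$start), nchar(PRIMER_12SV5F) - 8L)
})

test_that("enumeration degenerate and counting behavior", {
    short <- referenceAlignment(c(t = "ACGTACGTACGTACG",
                                  a = "ACGTACGTACGTACG"), targetId = "t")
    short <- appendPrimerToAlignment(short, PRIMER_12SV5F)
    # degapped target (18 + 15 = 33) shorter than the minimum length 34
    expect_equal(nrow(enumerateCandidates(short, PRIMER_12SV5F,
                                          designConfig())), 0L)

    # candidate count equals the brute-force (overlap, length) enumeration
    aln <- appendPrimerToAlignment(makeFixtureAlignment(), PRIMER_12SV5F)
    tlen <- nchar(gsub("-", "",
                       as.character(alignedSeqs(aln))[["SeaLamprey"]]))
    cfg <- designConfig(lenMin = 30L, lenMax = 32L, minOverlap = 6L,
                        maxOverlap = 8L)
    cands <- enumerateCandidates(aln, PRIMER_12SV5F, cfg)
    fpEnd <- nchar(PRIMER_12SV5F)  # primer sits at position 0 after append
    expected <- 0L
    for (o in 6:8) for (len in 30:32) {
        s <- fpEnd - o
        if (s >= 0L && s + len <= tlen) expected <- expected + 1L
    }
    expect_equal(nrow(cands), expected)
    # deterministic order: by start, then length
    expect_false(is.unsorted(cands$start))
})

test_that("primer placement needs an identity floor", {
    aln <- appendPrimerToAlignment(makeFixtureAlignment(), PRIMER_12SV5F)
    expect_error(enumerateCandidates(aln, "TTTTTTTTTTTTTTTTTT",
                                     designConfig()),
                 "identity")
    # a primer with one mismatch is still placed via local alignment
    near <- paste0("ACTGGGATTAGATACCCA")  # last base altered
    cands <- enumerateCandidates(aln, near,
                                 designConfig(lengths = c(34L, 36L),
                                              minOverlap = 8L,
                                              maxOverlap = 8L))
    expect_equal(nrow(cands), 2L)
})

test_that("nearest-neighbor Tm reproduces the published panel values", {
    tm34 <- nnTm(BLOCKER_34)
    tm36 <- nnTm(BLOCKER_36)
    expect_lt(abs(tm34 - 63.8), 1.5)
    expect_lt(abs(tm36 - 65.8), 1.5)
    expect_gt(tm36, tm34)
})

test_that("Tm is duplex-symmetric and grows when extended by G/C", {
    rc <- function(s) as.character(
        Biostrings::reverseComplement(Biostrings::DNAString(s)))
    set.seed(9)
    deltas <- numeric(0)
    for (case in 1:20) {
        s <- randomDna(sample(10:40, 1))
        expect_equal(nnTm(s), nnTm(rc(s)), tolerance = 1e-12)
        d <- nnTm(paste0(s, sample(c("G", "C"), 1))) - nnTm(s)
        # monotone up to a trace: the terminal-penalty/entropy swap can
        # shave a few hundredths of a degree on GC-rich oligos
        expect_gte(d, -0.05)
        deltas <- c(deltas, d)
    }
    expect_gt(median(deltas), 0)
    expect_error(nnTm("ACGTNACGTACG"), "non-ACGT")
    expect_error(nnTm("ACGT"), "length")
})

test_that("specificity counts mismatches and gaps over the footprint", {
    aln <- appendPrimerToAlignment(makeFixtureAlignment(), PRIMER_12SV5F)
    cand <- list(start = nchar(PRIMER_12SV5F) - 8L, length = 34L)
    sc <- specificityScore(cand, aln)
    # hosts are gapped across the 23-column insertion inside the footprint
    expect_true(all(sc$perNontarget >= 23L))
    expect_gte(sc$min, 23L)

    # a non-target identical to the target over the footprint scores 0
    twin <- referenceAlignment(
        c(t = paste0(PRIMER_12SV5F, FIXTURE_INSERT, FIXTURE_SHARED),
          u = paste0(PRIMER_12SV5F, FIXTURE_INSERT, FIXTURE_SHARED)),
        targetId = "t")
    expect_equal(specificityScore(cand, twin)$min, 0L)

    expect_error(specificityScore(list(start = 0L, length = 10000L), aln),
                 "outside")
})

test_that("specificity equals hand counts on a constructed panel", {
    # footprint = columns 0..9 of the target; mismatches placed by hand
    recs <- c(t  = "ACGTACGTAC",
              m0 = "ACGTACGTAC",     # 0 differences
              m2 = "TCGTACGTAT",     # 2 substitutions (cols 0 and 9)
              g3 = "ACG---GTAC",     # gap columns 4-6; column 6 is 3'-weighted
              mx = "TTTTTCGTAC",     # substitutions at columns 1,2,3,5
              m3p = "ACGTACGTTT")    # 2 substitutions in the 3'-most 5
    aln <- referenceAlignment(recs, targetId = "t")
    sc <- specificityScore(list(start = 0L, length = 10L), aln, k = 5L)
    expect_equal(unname(sc$perNontarget[c("m0", "m2", "g3", "mx", "m3p")]),
                 c(0L, 2L, 3L, 4L, 2L))
    # 3'-weighting doubles columns 6..10 (1-based)
    expect_equal(unname(sc$perNontargetWeighted[c("m0", "m2", "g3", "mx",
                                                  "m3p")]),
                 c(0L, 3L, 4L, 4L, 4L))
    expect_equal(sc$min, 0L)
})

test_that("ranking is deterministic and honors the tie rules", {
    df <- S4Vectors::DataFrame(
        id = c("a", "b", "c"),
        seq = c("x", "y", "z"),
        start = c(5L, 10L, 10L),
        length = c(36L, 34L, 36L),
        overlapLen = c(8L, 8L, 8L),
        tmC = c(65, 64, 64),
        minNontargetMismatches = c(3L, 25L, 25L),
        minNontargetMismatchesWeighted = c(3L, 30L, 30L))
    r <- rankCandidates(df, designConfig())
    expect_equal(r$id, c("b", "c", "a"))   # 25 beats 3; 34 beats 36
    set.seed(2)
    for (case in 1:5) {
        perm <- sample(3)
        expect_equal(rankCandidates(df[perm, ], designConfig())$id,
                     c("b", "c", "a"))
    }
    expect_error(rankCandidates(df[0, ], designConfig()), "no candidates")
})

test_that("ordering strings use the vendor dialect byte-for-byte", {
    expect_identical(
        as.character(annotateModification(BLOCKER_34, "C3_spacer", "HPLC")),
        "GATACCCCGCTATGCCTGCCATAAATAAACAACC/3SpC3/")
    expect_identical(
        as.character(annotateModification(BLOCKER_36, "inverted_dT", "HPLC")),
        "GATACCCCGCTATGCCTGCCATAAATAAACAACCGT/3InvdT/")
    plain <- annotateModification("ACGTACGT", "none", "desalted")
    expect_identical(as.character(plain), "ACGTACGT")
    expect_identical(attr(plain, "purification"), "desalted")
    expect_error(annotateModification("ACGT", "phosphorothioate"),
                 "should be one of")
})

test_that("candidates are substrings of the degapped target sense strand", {
    aln <- appendPrimerToAlignment(makeFixtureAlignment(), PRIMER_12SV5F)
    tpl <- gsub("-", "", as.character(alignedSeqs(aln))[["SeaLamprey"]])
    cands <- enumerateCandidates(aln, PRIMER_12SV5F,
                                 designConfig(lenMin = 30L, lenMax = 36L))
    for (i in seq_len(nrow(cands)))
        expect_identical(substr(tpl, cands$start[i] + 1L,
                                cands$start[i] + cands$length[i]),
                         cands$seq[i])
})

test_that("designBlockers produces a ranked annotated report", {
    res <- designBlockers(makeFixtureAlignment(), PRIMER_12SV5F,
                          designConfig(lengths = c(34L, 36L),
                                       minOverlap = 8L, maxOverlap = 8L),
                          mod = "C3_spacer", purification = "HPLC")
    expect_equal(res$windows$length, 23L)
    expect_setequal(unname(res$candidates$seq), c(BLOCKER_34, BLOCKER_36))
    expect_true(all(grepl("/3SpC3/$", res$candidates$orderingString)))
    expect_equal(res$guidance$blockerToPrimerRatio, "10:1")
})
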