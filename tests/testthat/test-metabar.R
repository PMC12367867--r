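revcomp <- function(s) as.character(
    Biostrings::reverseComplement(Biostrings::DNAString(s)))

test_that("mergePairs keeps only the overlap and resolves by quality", {
    set.seed(31)
    amp <- randomDna(100)
    # both mates span the whole amplicon: perfect 100-base overlap
    r <- mergePairs(amp, revcomp(amp))
    expect_equal(r$status, "merged")
    expect_equal(nchar(r$seq), 100L)
    expect_identical(r$seq, amp)

    # three overlap mismatches exceed the two-mismatch allowance
    mut <- amp
    for (p in c(10, 50, 90))
        substr(mut, p, p) <- setdiff(c("A", "C", "G", "T"),
                                     substr(amp, p, p))[1]
    r <- mergePairs(amp, revcomp(mut), minOverlap = 90L)
    expect_equal(r$status, "no_overlap")

    # one mismatch in a 50-base overlap: the q40 base wins
    a <- randomDna(50)
    b <- a
    substr(b, 25, 25) <- setdiff(c("A", "C", "G", "T"),
                                 substr(a, 25, 25))[1]
    qa <- strrep("I", 50)  # Q40
    qb <- strrep("+", 50)  # Q10
    r <- mergePairs(a, revcomp(b), qa, qb)
    expect_equal(nchar(r$seq), 50L)
    expect_identical(r$seq, a)
    # swap the qualities and the other base wins
    r2 <- mergePairs(a, revcomp(b), qb, qa)
    expect_identical(r2$seq, b)
    # equal qualities give N at the disputed position
    r3 <- mergePairs(a, revcomp(b), qa, qa)
    expect_equal(substr(r3$seq, 25, 25), "N")
})

test_that("merged length equals the overlap, never the union", {
    set.seed(32)
    for (case in 1:10) {
        L <- sample(60:120, 1)
        amp <- randomDna(L)
        rl <- sample(40:80, 1)
        fwd <- substr(amp, 1, min(rl, L))
        rev <- revcomp(substr(amp, max(1, L - rl + 1), L))
        r <- mergePairs(fwd, rev)
        ov <- max(0, 2 * min(rl, L) - L)
        if (ov >= 10) {
            expect_equal(r$status, "merged")
            expect_equal(nchar(r$seq), ov)
            expect_equal(r$overlapLen, ov)
        } else {
            expect_equal(r$status, "no_overlap")
        }
    }
})

test_that("read filter enforces length and homopolymer boundaries", {
    seqs <- c(strrep("ACGT", 27),                 # 108 bases -> length
              paste0(strrep("ACGT", 25), "ACGTACG"),  # 107, run 1 -> kept
              paste0(randomDna(20), strrep("A", 9), randomDna(20)),  # run 9
              paste0(randomDna(20), strrep("A", 8), randomDna(20)))  # run 8
    r <- filterReads(seqs)
    expect_equal(length(r$kept) + nrow(r$removed), length(seqs))
    expect_equal(r$removed$reason, c("length", "homopolymer"))
    expect_true(seqs[2] %in% r$kept)
    expect_true(seqs[4] %in% r$kept)
})

test_that("dereplication counts and orders uniques", {
    r <- dereplicate(c("A", "A", "C"))
    expect_equal(as.character(r$seq), c("A", "C"))
    expect_equal(r$count, c(2L, 1L))
    expect_equal(nrow(dereplicate(character())), 0L)
    # simulated reads from 3 templates, error-free
    set.seed(33)
    tpl <- vapply(1:3, function(i) randomDna(60), "")
    n <- c(500, 300, 200)
    reads <- rep(tpl, n)
    r <- dereplicate(reads)
    expect_equal(nrow(r), 3L)
    expect_equal(sum(r$count), 1000L)
    expect_equal(sort(r$count, decreasing = TRUE), c(500L, 300L, 200L))
})

test_that("classification: exact hit, congeneric tie, confamilial ambiguity", {
    set.seed(34)
    base <- randomDna(100)
    mutAt <- function(s, p) {
        substr(s, p, p) <- setdiff(c("A", "C", "G", "T"),
                                   substr(s, p, p))[1]
        s
    }
    far <- vapply(1:3, function(i) randomDna(100), "")
    # exact hit on one reference, all others distant -> species, conf 100
    refs <- c(sp1 = base, o1 = far[1], o2 = far[2])
    tax <- c("An;Ch;Cl;Or;FamA;GenA;sp1",
             "An;Ch;Cl;Or;FamB;GenB;sp2",
             "An;Ch;Cl;Or;FamC;GenC;sp3")
    r <- classifySeq(base, refs, tax, seed = 1)
    expect_equal(r$taxon, "sp1")
    expect_equal(r$rank, 7L)
    expect_equal(r$confidence, 100)

    # equidistant from two congeners -> never species level
    refs2 <- c(a = mutAt(base, 10), b = mutAt(base, 60), o = far[1])
    tax2 <- c("An;Ch;Cl;Or;FamA;GenA;spA",
              "An;Ch;Cl;Or;FamA;GenA;spB",
              "An;Ch;Cl;Or;FamB;GenB;spO")
    r2 <- classifySeq(base, refs2, tax2, seed = 1)
    expect_true(r2$rank <= 6L)
    expect_false(r2$taxon %in% c("spA", "spB"))

    # matches one reference that differs from three confamilial references
    # by a single base each -> family level at the default cutoff
    refs3 <- c(sl = base, x1 = mutAt(base, 5), x2 = mutAt(base, 45),
               x3 = mutAt(base, 85))
    tax3 <- c("An;Ch;Cl;Or;Petromyzontidae;Petromyzon;sl",
              "An;Ch;Cl;Or;Petromyzontidae;Lethenteron;x1",
              "An;Ch;Cl;Or;Petromyzontidae;Ichthyomyzon;x2",
              "An;Ch;Cl;Or;Petromyzontidae;Ichthyomyzon;x3")
    r3 <- classifySeq(base, refs3, tax3, seed = 1)
    expect_equal(r3$rank, 5L)
    expect_equal(r3$taxon, "Petromyzontidae")
})

test_that("OTU clustering is single linkage at the distance cutoff", {
    set.seed(35)
    base <- randomDna(100)
    mutN <- function(s, k) {
        for (p in sample(nchar(s), k))
            substr(s, p, p) <- setdiff(c("A", "C", "G", "T"),
                                       substr(s, p, p))[1]
        s
    }
    # 1 difference in 100 -> one OTU; 10 differences -> two
    r1 <- clusterOtus(c(base, mutN(base, 1)), c(10L, 5L))
    expect_equal(nrow(r1), 1L)
    expect_equal(r1$count, 15L)
    expect_equal(r1$representative, base)  # most abundant member
    r2 <- clusterOtus(c(base, mutN(base, 10)), c(10L, 5L))
    expect_equal(nrow(r2), 2L)

    # chain A-B 0.02, B-C 0.02, A-C 0.04: one OTU under single linkage
    A <- base
    B <- mutN(A, 2)
    C <- B
    for (p in which(strsplit(A, "")[[1]] == strsplit(B, "")[[1]])[1:2])
        substr(C, p, p) <- setdiff(c("A", "C", "G", "T"),
                                   substr(C, p, p))[1]
    r3 <- clusterOtus(c(A, B, C), c(5L, 3L, 2L))
    expect_equal(nrow(r3), 1L)
    expect_equal(r3$count, 10L)
})

test_that("suppression metrics follow the mean-ratio definition", {
    # single pair carrying the published per-blocker predator means
    cts <- matrix(c(19387.29, 100, 35.57, 30000), nrow = 2,
                  dimnames = list(c("Petromyzontidae", "LakeTrout"),
                                  c("u", "b")))
    oe <- otuExperiment(cts, dnaSampleId = c("d", "d"),
                        blockerId = c(NA, "Blocker 1"))
    m <- suppressionMetrics(oe, "Petromyzontidae")
    expect_equal(m$predatorReductionPct, 99.82, tolerance = 5e-5)
    expect_equal(S4Vectors::metadata(m)$hostChange["LakeTrout", "Blocker 1"],
                 300)

    # blocked == unblocked: 0% reduction, host change 1
    cts2 <- matrix(c(50, 80, 50, 80), nrow = 2,
                   dimnames = list(c("P", "H"), c("u", "b")))
    oe2 <- otuExperiment(cts2, c("d", "d"), c(NA, "B"))
    m2 <- suppressionMetrics(oe2, "P")
    expect_equal(m2$predatorReductionPct, 0)
    expect_equal(unname(S4Vectors::metadata(m2)$hostChange["H", "B"]), 1)

    # zero unblocked predator reads are flagged
    cts3 <- matrix(c(0, 10, 5, 10), nrow = 2,
                   dimnames = list(c("P", "H"), c("u", "b")))
    m3 <- suppressionMetrics(otuExperiment(cts3, c("d", "d"), c(NA, "B")),
                             "P")
    expect_true(is.na(m3$predatorReductionPct))
    expect_equal(m3$status, "zero_unblocked_predator")
})

test_that("paired t matches the published counts and the textbook oracle", {
    lt <- exampleLakeTroutCounts()
    lt5 <- lt[lt$sample %in% c("HP15", "HP3", "HP5", "M1", "M4"), ]
    r <- pairedT(lt5$unblocked, lt5$blocker1)
    expect_equal(r$df, 4L)
    expect_equal(r$t, -4.41, tolerance = 5e-3)
    o <- handPairedT(lt5$unblocked, lt5$blocker1)
    expect_equal(r$t, o$t, tolerance = 1e-10)
    expect_equal(r$p, o$p, tolerance = 1e-10)

    # hand case: d = (1, 2, 3)
    r2 <- pairedT(c(11, 22, 33), c(10, 20, 30))
    expect_equal(r2$t, 2 * sqrt(3), tolerance = 1e-12)
    expect_equal(r2$df, 2L)

    # zero variance flags, does not throw
    r3 <- pairedT(c(5, 6, 7), c(4, 5, 6))
    expect_equal(r3$status, "zero_variance")
    expect_true(is.na(r3$t))

    # random battery against the oracle
    set.seed(36)
    for (case in 1:20) {
        n <- sample(3:8, 1)
        u <- rpois(n, 1000); b <- rpois(n, 100)
        if (sd(u - b) == 0) next
        r <- pairedT(u, b); o <- handPairedT(u, b)
        expect_equal(r$t, o$t, tolerance = 1e-10)
        expect_equal(r$p, o$p, tolerance = 1e-10)
    }
})

test_that("Holm correction walks the hand cases and is bracketed", {
    r <- holmCorrection(0.01)
    expect_true(r$significant)
    expect_equal(r$pAdjusted, 0.01)

    r2 <- holmCorrection(c(0.01, 0.02, 0.04))
    expect_true(all(r2$significant))
    expect_equal(r2$pAdjusted, c(0.03, 0.04, 0.04))

    r3 <- holmCorrection(c(0.04, 0.04, 0.04))
    expect_false(any(r3$significant))
    expect_equal(r3$pAdjusted, c(0.12, 0.12, 0.12))

    expect_error(holmCorrection(c(0.01, 0)), "\\(0, 1]")
    expect_error(holmCorrection(c(0.01, 1.2)), "\\(0, 1]")

    # never more permissive than Bonferroni, never stricter than raw
    set.seed(37)
    for (case in 1:20) {
        p <- runif(sample(2:10, 1))
        h <- holmCorrection(p, 0.05)$significant
        bonf <- p.adjust(p, "bonferroni") <= 0.05
        raw <- p <= 0.05
        expect_true(all(h[bonf]))       # Bonferroni-significant => Holm too
        expect_true(all(raw[h]))        # Holm-significant => raw-significant
    }
})

test_that("effectiveness verdict applies the stated rule", {
    # significant predator reduction + significant host increase: effective
    v <- effectivenessVerdict(list(t = 6.5, significant = TRUE),
                              list(LakeTrout = list(t = -4.4,
                                                    significant = TRUE)))
    expect_true(v$effective)
    # predator not significant: ineffective
    v2 <- effectivenessVerdict(list(t = 2.0, significant = FALSE))
    expect_false(v2$effective)
    # significant host reduction disqualifies
    v3 <- effectivenessVerdict(list(t = 6.5, significant = TRUE),
                               list(H = list(t = 3.1, significant = TRUE)))
    expect_false(v3$effective)
    expect_match(v3$reasons, "host")
})

test_that("evaluateBlockers corrects within taxa and issues verdicts", {
    lt <- exampleLakeTroutCounts()
    lt5 <- lt[lt$sample %in% c("HP15", "HP3", "HP5", "M1", "M4"), ]
    blockers <- paste0("blocker", 1:8)
    # lake trout counts as measured; predator counts built with strong,
    # consistent suppression so the predator side is clearly significant
    set.seed(38)
    pred_u <- c(19000, 21000, 18500, 20500, 18000)
    samples <- c(lt5$sample, as.vector(outer(lt5$sample, blockers,
                                             paste, sep = "_")))
    counts <- matrix(0L, nrow = 2, ncol = length(samples),
                     dimnames = list(c("Petromyzontidae", "LakeTrout"),
                                     samples))
    counts["LakeTrout", seq_len(5)] <- lt5$unblocked
    counts["Petromyzontidae", seq_len(5)] <- pred_u
    for (j in seq_along(blockers)) {
        cols <- 5 + (j - 1) * 5 + seq_len(5)
        counts["LakeTrout", cols] <- lt5[[blockers[j]]]
        counts["Petromyzontidae", cols] <- round(pred_u / 500) + j
    }
    oe <- otuExperiment(counts,
                        dnaSampleId = rep(lt5$sample, times = 9),
                        blockerId = rep(c(NA, blockers), each = 5))
    ev <- evaluateBlockers(oe, "Petromyzontidae")
    ltRows <- ev$tests[ev$tests$taxon == "LakeTrout", ]
    expect_equal(nrow(ltRows), 8L)
    expect_true(all(ltRows$t < -4.0))
    pRows <- ev$tests[ev$tests$taxon == "Petromyzontidae", ]
    expect_true(all(pRows$t > 6.0))
    expect_true(all(pRows$holmSignificant))
    expect_true(all(vapply(ev$verdicts, `[[`, TRUE, "effective")))
})
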