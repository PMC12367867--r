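# Shared fixtures: the published blocker panel's sequences, the universal
# forward primer whose 3' terminus they start with, and a small alignment
# reverse-engineered so that enumeration reproduces the panel.

PRIMER_12SV5F <- "ACTGGGATTAGATACCCC"
BLOCKER_34 <- "GATACCCCGCTATGCCTGCCATAAATAAACAACC"
BLOCKER_36 <- "GATACCCCGCTATGCCTGCCATAAATAAACAACCGT"

# target carries a 23-base insertion absent from the hosts; the marker then
# continues with a shared region, so the 34/36-mer blockers run from the
# primer's last 8 bases across the insertion into the shared tail
FIXTURE_INSERT <- "GCTATGCCTGCCATAAATAAACA"     # 23 bases
FIXTURE_SHARED <- "ACCGTCTGAACTCAGATCACGTAGG"   # 25 bases

makeFixtureAlignment <- function(nHosts = 10L) {
    stopifnot(nchar(FIXTURE_INSERT) == 23L)
    gapBlock <- strrep("-", nchar(FIXTURE_INSERT))
    recs <- c(SeaLamprey = paste0(FIXTURE_INSERT, FIXTURE_SHARED),
              setNames(rep(paste0(gapBlock, FIXTURE_SHARED), nHosts),
                       paste0("host", seq_len(nHosts))))
    referenceAlignment(recs, targetId = "SeaLamprey")
}

# Exhaustive-recursion alignment oracle: the optimum over all global
# alignments, straight from the definition (no DP table reuse).
bruteForceNwScore <- function(a, b, match = 1L, mismatch = -1L, gap = -2L) {
    sub <- function(x, y) {
        if (x == "N" || y == "N") return(mismatch)
        if (x == y) match else mismatch
    }
    rec <- function(i, j) {
        if (i == 0L && j == 0L) return(0L)
        best <- -Inf
        if (i > 0L && j > 0L)
            best <- max(best, rec(i - 1L, j - 1L) +
                              sub(substr(a, i, i), substr(b, j, j)))
        if (i > 0L) best <- max(best, rec(i - 1L, j) + gap)
        if (j > 0L) best <- max(best, rec(i, j - 1L) + gap)
        best
    }
    rec(nchar(a), nchar(b))
}

randomDna <- function(n) paste(sample(c("A", "C", "G", "T"), n,
                                      replace = TRUE), collapse = "")

# textbook paired-t oracle, independent of stats::t.test
handPairedT <- function(u, b) {
    d <- u - b
    n <- length(d)
    t <- mean(d) / (sd(d) / sqrt(n))
    list(t = t, df = n - 1L, p = 2 * pt(-abs(t), n - 1L))
}
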