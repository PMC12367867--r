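HOST_POOL <- data.frame(
    species = c("Salvelinus_namaycush", "Catostomus_commersonii",
                "Sander_vitreus", "Coregonus_clupeaformis", "Esox_lucius",
                "Lota_lota", "Perca_flavescens", "Micropterus_dolomieu",
                "Salmo_trutta", "Oncorhynchus_mykiss",
                "Ameiurus_nebulosus", "Moxostoma_anisurum",
                "Notropis_hudsonius", "Alosa_pseudoharengus",
                "Osmerus_mordax"),
    genus = c("Salvelinus", "Catostomus", "Sander", "Coregonus", "Esox",
              "Lota", "Perca", "Micropterus", "Salmo", "Oncorhynchus",
              "Ameiurus", "Moxostoma", "Notropis", "Alosa", "Osmerus"),
    family = c("Salmonidae", "Catostomidae", "Percidae", "Salmonidae",
               "Esocidae", "Lotidae", "Percidae", "Centrarchidae",
               "Salmonidae", "Salmonidae", "Ictaluridae", "Catostomidae",
               "Leuciscidae", "Clupeidae", "Osmeridae"),
    stringsAsFactors = FALSE)

#' Simulation configuration
#'
#' Defaults emulate the motivating study's scales: a short 12S-like marker
#' (84-base shared region plus a 23-base target-specific insertion, so the
#' target amplicon is 107 bases — the longest the pipeline's length filter
#' admits), 2 x 150 paired-end reads, a community of 12 species at a
#' typical interspecific 12S divergence, and mock mixtures such as 90:10
#' predator:host.
#'
#' @param seed Mandatory integer seed; every generator is reproducible
#'   under it.
#' @param nSpecies Community size including the target (default 12).
#' @param regionLen Shared marker length in bases (default 84).
#' @param insertLen Target-specific insertion length (default 23).
#' @param substitutionRate Per-base divergence of each species from the
#'   common ancestor (default 0.08).
#' @param readLen Read length in bases (default 150).
#' @param errorRate Per-base sequencing substitution error (default
#'   0.001).
#' @param suppressionFold Factor dividing the predator's template
#'   proportion before amplification (default 1 = no blocker).
#' @param mixture Named template proportions (subset of community
#'   species), summing to 1. Default: 90:10 predator:first host.
#' @param nReads Total read pairs per simulated library (default 50000).
#' @return A validated list of class `SimConfig`.
#' @export
simConfig <- function(seed, nSpecies = 12L, regionLen = 84L,
                      insertLen = 23L, substitutionRate = 0.08,
                      readLen = 150L, errorRate = 0.001,
                      suppressionFold = 1, mixture = NULL,
                      nReads = 50000L) {
    if (missing(seed) || is.null(seed)) stop("seed is mandatory")
    rates <- c(substitutionRate, errorRate)
    if (any(rates < 0 | rates > 1)) stop("rates must lie in [0, 1]")
    if (insertLen >= regionLen)
        stop("insertLen must be smaller than regionLen")
    if (!is.null(mixture)) {
        if (abs(sum(mixture) - 1) > 1e-8)
            stop("mixture proportions must sum to 1")
        if (is.null(names(mixture))) stop("mixture must be named")
    }
    if (suppressionFold < 1) stop("suppressionFold must be >= 1")
    structure(list(seed = as.integer(seed), nSpecies = as.integer(nSpecies),
                   regionLen = as.integer(regionLen),
                   insertLen = as.integer(insertLen),
                   substitutionRate = substitutionRate,
                   readLen = as.integer(readLen), errorRate = errorRate,
                   suppressionFold = suppressionFold, mixture = mixture,
                   nReads = as.integer(nReads)),
              class = "SimConfig")
}

.randDna <- function(n) paste(sample(c("A", "C", "G", "T"), n,
                                     replace = TRUE), collapse = "")

.mutateSeq <- function(seq, rate) {
    if (rate <= 0) return(seq)
    b <- strsplit(seq, "")[[1]]
    hit <- which(runif(length(b)) < rate)
    for (i in hit)
        b[i] <- sample(setdiff(c("A", "C", "G", "T"), b[i]), 1L)
    paste(b, collapse = "")
}

#' Simulate a marker-region community with a target-specific insertion
#'
#' An ancestral marker sequence is mutated independently per species at
#' the configured substitution rate; the target (predator) additionally
#' receives a unique insertion near the 5' end — the discriminative motif
#' a blocking primer targets. The true gapped alignment is recorded, so
#' [findDiscriminativeGap()] on it recovers the insertion by
#' construction.
#'
#' @param cfg A [simConfig()].
#' @return A list: `seqs` (ungapped named character vector), `alignment`
#'   (the true [ReferenceAlignment-class]), `taxonomy` (named
#'   `kingdom;...;species` strings), `targetId`, `insertStart` (0-based
#'   alignment column) and `insertLen`.
#' @export
simulateCommunity <- function(cfg) {
    stopifnot(inherits(cfg, "SimConfig"))
    set.seed(cfg$seed)
    nHost <- cfg$nSpecies - 1L
    if (nHost < 1L) stop("need at least 2 species")
    hosts <- HOST_POOL[rep_len(seq_len(nrow(HOST_POOL)), nHost), ]
    dup <- duplicated(hosts$species)
    hosts$species[dup] <- paste0(hosts$species[dup], "_",
                                 cumsum(dup)[dup] + 1L)
    targetId <- "Petromyzon_marinus"
    ancestor <- .randDna(cfg$regionLen)
    insert <- .randDna(cfg$insertLen)
    insAfter <- 8L   # bases of shared region 5' of the insertion
    species <- c(targetId, hosts$species)
    ungapped <- character(length(species))
    gapped <- character(length(species))
    gapBlock <- strrep("-", cfg$insertLen)
    for (i in seq_along(species)) {
        s <- .mutateSeq(ancestor, cfg$substitutionRate)
        if (i == 1L) {
            ungapped[i] <- paste0(substr(s, 1, insAfter), insert,
                                  substr(s, insAfter + 1L, nchar(s)))
            gapped[i] <- ungapped[i]
        } else {
            ungapped[i] <- s
            gapped[i] <- paste0(substr(s, 1, insAfter), gapBlock,
                                substr(s, insAfter + 1L, nchar(s)))
        }
    }
    names(ungapped) <- names(gapped) <- species
    taxonomy <- c(
        paste("Animalia;Chordata;Hyperoartia;Petromyzontiformes",
              "Petromyzontidae;Petromyzon;Petromyzon_marinus", sep = ";"),
        sprintf("Animalia;Chordata;Actinopteri;Teleostei;%s;%s;%s",
                hosts$family, hosts$genus, hosts$species))
    names(taxonomy) <- species
    list(seqs = ungapped,
         alignment = referenceAlignment(gapped, targetId = targetId),
         taxonomy = taxonomy, targetId = targetId,
         insertStart = insAfter, insertLen = cfg$insertLen)
}

#' Simulate a qPCR amplification curve with known true Ct
#'
#' Generates a logistic delta-Rn trace whose noise-free threshold crossing
#' (as measured by [computeCt()], i.e. with linear interpolation between
#' cycles) equals `trueCt`; the logistic midpoint is placed analytically
#' from the amplification efficiency and then refined against the
#' package's own Ct definition, so the round trip is exact up to noise.
#'
#' @param trueCt Target cycle threshold (must lie within the cycle range).
#' @param efficiency Per-cycle gain fraction in (0, 1]; 1 = perfect
#'   doubling.
#' @param plateau Plateau delta-Rn (must exceed the threshold).
#' @param noiseSd Gaussian noise standard deviation (delta-Rn units).
#' @param cycles Number of cycles (default 40).
#' @param threshold Threshold the curve is calibrated against (default
#'   0.063).
#' @param seed Optional seed for the noise.
#' @return A data.frame with `cycle` and `drn`.
#' @export
simulateQpcr <- function(trueCt, efficiency = 0.95, plateau = 2,
                         noiseSd = 0, cycles = 40L, threshold = 0.063,
                         seed = NULL) {
    if (efficiency <= 0 || efficiency > 1)
        stop("efficiency must lie in (0, 1]")
    if (plateau <= threshold) stop("plateau must exceed the threshold")
    if (trueCt < 1 || trueCt > cycles)
        stop("trueCt outside the cycle range")
    if (!is.null(seed)) set.seed(seed)
    k <- log(1 + efficiency)
    c0 <- trueCt + log(plateau / threshold - 1) / k
    cyc <- seq_len(cycles)
    for (it in 1:3) {
        drn0 <- plateau / (1 + exp(-k * (cyc - c0)))
        ct <- computeCt(cyc, drn0, threshold)$ct
        if (is.na(ct)) break
        c0 <- c0 + (trueCt - ct)
    }
    drn <- plateau / (1 + exp(-k * (cyc - c0)))
    if (noiseSd > 0) drn <- drn + rnorm(cycles, 0, noiseSd)
    data.frame(cycle = cyc, drn = drn)
}

#' Simulate a melt curve with a known peak
#'
#' Fluorescence is a sigmoid drop centered at `peakC`; [meltPeak()]
#' recovers the peak within one grid step at zero noise.
#'
#' @param peakC Melting temperature peak (deg C).
#' @param widthC Transition width (deg C, > 0).
#' @param gridStep Temperature grid spacing (deg C).
#' @param noiseSd Gaussian noise standard deviation.
#' @param seed Optional seed for the noise.
#' @return A data.frame with `temperature` and `fluorescence`.
#' @export
simulateMelt <- function(peakC = 81.77, widthC = 0.8, gridStep = 0.2,
                         noiseSd = 0, seed = NULL) {
    if (widthC <= 0) stop("widthC must be > 0")
    if (!is.null(seed)) set.seed(seed)
    temperature <- seq(peakC - 5 * widthC, peakC + 5 * widthC,
                       by = gridStep)
    fl <- 1 / (1 + exp((temperature - peakC) / widthC))
    if (noiseSd > 0) fl <- fl + rnorm(length(fl), 0, noiseSd)
    data.frame(temperature = temperature, fluorescence = fl)
}

.mutateReads <- function(reads, rate) {
    if (rate <= 0) return(reads)
    bases <- c("A", "C", "G", "T")
    vapply(reads, function(r) {
        n <- nchar(r)
        hit <- which(runif(n) < rate)
        if (!length(hit)) return(r)
        b <- strsplit(r, "")[[1]]
        for (i in hit) b[i] <- sample(setdiff(bases, b[i]), 1L)
        paste(b, collapse = "")
    }, "", USE.NAMES = FALSE)
}

.randQual <- function(lens) {
    vapply(lens, function(L)
        rawToChar(as.raw(33L + sample(30:40, L, replace = TRUE))), "")
}

#' Simulate blocker-suppressed paired-end amplicon reads
#'
#' Template proportions follow `cfg$mixture`; the predator's proportion is
#' divided by `cfg$suppressionFold` and the mixture renormalized — the
#' single-effective-factor model matching the \eqn{2^{\Delta C_t}}
#' interpretation of annealing inhibition. Read-pair counts are drawn
#' multinomially; each mate covers the amplicon from its end (up to the
#' read length) and receives uniform substitution errors. Sequencing
#' errors are substitutions only (no indels), which keeps merge and
#' filter behavior analyzable.
#'
#' @param community Output of [simulateCommunity()].
#' @param cfg A [simConfig()]; `mixture` defaults to 90:10
#'   predator:first-host.
#' @return A list: `fwd`, `rev`, `fwdQual`, `revQual` (parallel character
#'   vectors; qualities Phred+33), `truth` (data.frame of species,
#'   template proportion before and after suppression, and true read
#'   counts).
#' @export
simulateReads <- function(community, cfg) {
    stopifnot(inherits(cfg, "SimConfig"))
    set.seed(cfg$seed + 1L)
    mixture <- cfg$mixture
    if (is.null(mixture)) {
        host <- setdiff(names(community$seqs), community$targetId)[1]
        mixture <- setNames(c(0.9, 0.1), c(community$targetId, host))
    }
    if (!all(names(mixture) %in% names(community$seqs)))
        stop("mixture names must be community species")
    w <- mixture
    isTgt <- names(w) == community$targetId
    w[isTgt] <- w[isTgt] / cfg$suppressionFold
    w <- w / sum(w)
    counts <- as.integer(stats::rmultinom(1, cfg$nReads, w))
    names(counts) <- names(w)
    fwd <- rev <- character(0)
    spLab <- character(0)
    for (sp in names(w)) {
        if (counts[[sp]] == 0L) next
        amp <- community$seqs[[sp]]
        L <- nchar(amp)
        f1 <- substr(amp, 1L, min(cfg$readLen, L))
        r1 <- as.character(Biostrings::reverseComplement(
            Biostrings::DNAString(substr(amp, max(1L, L - cfg$readLen + 1L),
                                         L))))
        fwd <- c(fwd, rep(f1, counts[[sp]]))
        rev <- c(rev, rep(r1, counts[[sp]]))
        spLab <- c(spLab, rep(sp, counts[[sp]]))
    }
    fwd <- .mutateReads(fwd, cfg$errorRate)
    rev <- .mutateReads(rev, cfg$errorRate)
    truth <- data.frame(species = names(w),
                        mixtureProportion = as.numeric(mixture[names(w)]),
                        templateProportion = as.numeric(w),
                        reads = counts, row.names = NULL)
    list(fwd = fwd, rev = rev,
         fwdQual = .randQual(nchar(fwd)), revQual = .randQual(nchar(rev)),
         species = spLab, truth = truth)
}

#' Write simulated reads as paired FASTQ plus a truth table
#'
#' @param sim Output of [simulateReads()].
#' @param dir Output directory (created if needed).
#' @param prefix File name prefix.
#' @return Paths of the files written, invisibly.
#' @export
writeSimulatedFastq <- function(sim, dir, prefix = "sim") {
    dir.create(dir, showWarnings = FALSE, recursive = TRUE)
    ids <- sprintf("read_%06d", seq_along(sim$fwd))
    r1 <- file.path(dir, paste0(prefix, "_R1.fastq"))
    r2 <- file.path(dir, paste0(prefix, "_R2.fastq"))
    writeLines(as.vector(rbind(paste0("@", ids), sim$fwd, "+",
                               sim$fwdQual)), r1)
    writeLines(as.vector(rbind(paste0("@", ids), sim$rev, "+",
                               sim$revQual)), r2)
    tj <- file.path(dir, paste0(prefix, "_truth.json"))
    jsonlite::write_json(sim$truth, tj, dataframe = "rows",
                         auto_unbox = TRUE, digits = NA)
    invisible(c(r1, r2, tj))
}
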