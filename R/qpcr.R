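#' Read qPCR amplification curves (long CSV)
#'
#' Expects columns `sample_id, blocker_id, cycle, drn`: baseline-normalized
#' reporter fluorescence (delta-Rn) per cycle per sample. `blocker_id` may
#' be empty/NA for unblocked reactions.
#'
#' @param path CSV path.
#' @return A data.frame with one row per (sample, cycle).
#' @export
readAmpCurves <- function(path) {
    df <- read.csv(path, stringsAsFactors = FALSE)
    need <- c("sample_id", "cycle", "drn")
    if (!all(need %in% names(df)))
        stop("amplification CSV needs columns sample_id, cycle, drn")
    if (!"blocker_id" %in% names(df)) df$blocker_id <- NA_character_
    df$blocker_id[!nzchar(trimws(as.character(df$blocker_id)))] <- NA
    df
}

#' Read melt curves (long CSV)
#'
#' Expects columns `sample_id, temperature, fluorescence`.
#'
#' @param path CSV path.
#' @return A data.frame.
#' @export
readMeltCurves <- function(path) {
    df <- read.csv(path, stringsAsFactors = FALSE)
    need <- c("sample_id", "temperature", "fluorescence")
    if (!all(need %in% names(df)))
        stop("melt CSV needs columns sample_id, temperature, fluorescence")
    df
}

#' Cycle threshold of an amplification curve
#'
#' The fractional cycle at which delta-Rn first reaches a fixed threshold,
#' linearly interpolated between the bracketing cycles. The default
#' threshold (0.063 delta-Rn units) is the instrument setting used in the
#' motivating evaluation; input is assumed already baseline-normalized.
#' A curve that never crosses is flagged, not an error: `ct` is `NA` with
#' `status = "no_crossing"` — downstream this is reported as suppression
#' beyond quantification.
#'
#' @param cycles Strictly increasing integer cycle index.
#' @param drn Normalized fluorescence, same length as `cycles`.
#' @param threshold Positive threshold in delta-Rn units (default 0.063).
#' @return A list: `ct` (fractional cycles or `NA`), `threshold`,
#'   `status` (`"ok"` or `"no_crossing"`).
#' @examples
#' computeCt(1:12, c(rep(0, 9), 0, 0.063, 0.126))
#' @export
computeCt <- function(cycles, drn, threshold = 0.063) {
    if (threshold <= 0) stop("threshold must be > 0")
    if (length(cycles) != length(drn))
        stop("cycles and drn must have equal length")
    if (any(diff(cycles) <= 0)) stop("cycle index must be strictly increasing")
    if (any(!is.finite(drn))) stop("drn values must be finite")
    above <- drn >= threshold
    if (!any(above))
        return(list(ct = NA_real_, threshold = threshold,
                    status = "no_crossing"))
    i <- which(above)[1]
    if (i == 1L)
        return(list(ct = as.numeric(cycles[1]), threshold = threshold,
                    status = "ok"))
    c0 <- cycles[i - 1L]; c1 <- cycles[i]
    v0 <- drn[i - 1L]; v1 <- drn[i]
    ct <- c0 + (threshold - v0) / (v1 - v0) * (c1 - c0)
    list(ct = ct, threshold = threshold, status = "ok")
}

#' Fold suppression from a cycle-threshold difference
#'
#' Assuming perfect doubling of product per cycle, a blocked reaction that
#' reaches threshold `dCt` cycles later than its unblocked control was
#' suppressed `2^dCt`-fold: `foldSuppression(ctBlocked, ctUnblocked) =
#' 2^(ctBlocked - ctUnblocked)`. Values below 1 mean the blocked reaction
#' amplified earlier.
#'
#' @param ctBlocked,ctUnblocked Cycle thresholds; `NA` propagates with a
#'   reason.
#' @return A list: `fold`, `deltaCt`, `status` (`"ok"` or
#'   `"undefined_ct"`).
#' @examples
#' foldSuppression(31.12, 17.4)$fold   # ~ 2^13.72
#' @export
foldSuppression <- function(ctBlocked, ctUnblocked) {
    if (is.na(ctBlocked) || is.na(ctUnblocked))
        return(list(fold = NA_real_, deltaCt = NA_real_,
                    status = "undefined_ct"))
    d <- ctBlocked - ctUnblocked
    list(fold = 2^d, deltaCt = d, status = "ok")
}

#' Melting-temperature peak of a melt curve
#'
#' The temperature at which the negative derivative of fluorescence with
#' respect to temperature is largest, after moving-average smoothing;
#' derivative by central differences, ties broken to the lowest
#' temperature. Monotonically non-decreasing fluorescence (nothing melts)
#' yields a flagged no-peak result.
#'
#' @param temperature Strictly increasing temperatures (deg C), >= 5 points.
#' @param fluorescence Same length as `temperature`.
#' @param smoothWindow Moving-average window in points (default 3).
#' @return A list: `peakC` (deg C or `NA`), `status` (`"ok"` or
#'   `"no_peak"`).
#' @export
meltPeak <- function(temperature, fluorescence, smoothWindow = 3L) {
    n <- length(temperature)
    if (n < 5L) stop("melt curve needs at least 5 points")
    if (length(fluorescence) != n)
        stop("temperature and fluorescence must have equal length")
    if (any(diff(temperature) <= 0))
        stop("temperatures must be strictly increasing")
    if (all(diff(fluorescence) >= 0))
        return(list(peakC = NA_real_, status = "no_peak"))
    f <- as.numeric(stats::filter(fluorescence,
                                  rep(1 / smoothWindow, smoothWindow),
                                  sides = 2))
    f[is.na(f)] <- fluorescence[is.na(f)]
    idx <- 2:(n - 1L)
    deriv <- -(f[idx + 1L] - f[idx - 1L]) /
        (temperature[idx + 1L] - temperature[idx - 1L])
    if (max(deriv) <= 0)
        return(list(peakC = NA_real_, status = "no_peak"))
    best <- idx[which.max(deriv)]  # which.max takes the first = lowest T
    list(peakC = temperature[best], status = "ok")
}

#' Classify a melt peak against predator and host baselines
#'
#' A blocked mixed-template reaction whose product melt peak sits near the
#' host baseline (rather than the predator's) indicates that host DNA,
#' not predator DNA, was amplified. The nearest baseline wins when the
#' difference between the two distances exceeds `margin`; otherwise the
#' call is ambiguous.
#'
#' @param samplePeak Observed melt peak (deg C).
#' @param predatorBaseline,hostBaseline Baseline peaks (deg C), distinct.
#' @param margin Decision margin (deg C, default 0.5).
#' @return `"predator_like"`, `"host_like"`, or `"ambiguous"`.
#' @export
classifyShift <- function(samplePeak, predatorBaseline, hostBaseline,
                          margin = 0.5) {
    if (predatorBaseline == hostBaseline)
        stop("predator and host baselines must be distinct")
    dp <- abs(samplePeak - predatorBaseline)
    dh <- abs(samplePeak - hostBaseline)
    if (abs(dp - dh) <= margin) return("ambiguous")
    if (dp < dh) "predator_like" else "host_like"
}

#' Evaluate blocker qPCR runs: Ct, fold suppression, melt shifts
#'
#' @param amp Long-format amplification data ([readAmpCurves()] layout).
#' @param pairs data.frame with columns `blocked`, `unblocked` mapping
#'   blocked sample ids to their unblocked controls.
#' @param melt Optional long-format melt data ([readMeltCurves()] layout).
#' @param predatorBaseline,hostBaseline Optional baselines for
#'   [classifyShift()] (both required for shift calls).
#' @param threshold Ct threshold in delta-Rn units.
#' @param margin Passed to [classifyShift()].
#' @return A list: `ct` (per-sample table), `suppression` (per pair:
#'   delta-Ct, fold, status — pairs whose blocked curve never crosses get
#'   `status = "suppressed_beyond_quantification"` and the fold is the
#'   lower bound `2^(maxCycle - ctUnblocked)`), and `melt` (per-sample
#'   peak and optional shift label).
#' @export
qpcrEvaluate <- function(amp, pairs, melt = NULL,
                         predatorBaseline = NULL, hostBaseline = NULL,
                         threshold = 0.063, margin = 0.5) {
    stopifnot(all(c("blocked", "unblocked") %in% names(pairs)))
    sp <- split(amp, amp$sample_id)
    ctTab <- do.call(rbind, lapply(names(sp), function(id) {
        d <- sp[[id]][order(sp[[id]]$cycle), ]
        r <- computeCt(d$cycle, d$drn, threshold)
        data.frame(sample_id = id,
                   blocker_id = d$blocker_id[1],
                   ct = r$ct, status = r$status,
                   max_cycle = max(d$cycle),
                   stringsAsFactors = FALSE)
    }))
    sup <- do.call(rbind, lapply(seq_len(nrow(pairs)), function(i) {
        b <- ctTab[ctTab$sample_id == pairs$blocked[i], ]
        u <- ctTab[ctTab$sample_id == pairs$unblocked[i], ]
        if (!nrow(b) || !nrow(u))
            stop("pair references unknown sample id: ",
                 pairs$blocked[i], " / ", pairs$unblocked[i])
        fs <- foldSuppression(b$ct, u$ct)
        status <- fs$status
        if (is.na(b$ct) && !is.na(u$ct)) {
            # never crossed: report the quantification lower bound
            fs$deltaCt <- b$max_cycle - u$ct
            fs$fold <- 2^fs$deltaCt
            status <- "suppressed_beyond_quantification"
        }
        data.frame(blocked = pairs$blocked[i], unblocked = pairs$unblocked[i],
                   blocker_id = b$blocker_id, deltaCt = fs$deltaCt,
                   fold = fs$fold, status = status,
                   stringsAsFactors = FALSE)
    }))
    meltTab <- NULL
    if (!is.null(melt)) {
        sm <- split(melt, melt$sample_id)
        meltTab <- do.call(rbind, lapply(names(sm), function(id) {
            d <- sm[[id]][order(sm[[id]]$temperature), ]
            r <- meltPeak(d$temperature, d$fluorescence)
            lab <- NA_character_
            if (!is.null(predatorBaseline) && !is.null(hostBaseline) &&
                r$status == "ok")
                lab <- classifyShift(r$peakC, predatorBaseline,
                                     hostBaseline, margin)
            data.frame(sample_id = id, peakC = r$peakC, status = r$status,
                       shift = lab, stringsAsFactors = FALSE)
        }))
    }
    list(ct = ctTab, suppression = sup, melt = meltTab)
}
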