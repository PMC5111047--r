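#' @importFrom stats pt var
#' @importFrom utils combn
NULL

allBalancedSplits <- function(samples) {
    ## unordered 4-vs-4 splits of 8 samples, each represented by the side
    ## containing the first sample: C(8,4)/2 = 35 including the identity
    stopifnot(length(samples) == 8L)
    cols <- combn(samples, length(samples) / 2L, simplify = FALSE)
    Filter(function(s) samples[1] %in% s, cols)
}

#' Balanced replicate-shuffling schemes
#'
#' Enumerates the unordered balanced 4-vs-4 relabelings of the 8 samples of
#' a comparison, excludes the true labeling (whose mirror is the same
#' unordered split), and returns `nPerms` distinct schemes drawn under the
#' seed.
#'
#' @param design sample design data.frame.
#' @param comparison `"caste"` or `"sex"` (defines the true labeling).
#' @param nPerms number of schemes wanted.
#' @param seed RNG seed.
#' @return list of schemes, each a list with integer sample indices `A`
#'   and `B`.
#' @export
shuffleReplicates <- function(design, comparison, nPerms, seed) {
    sides <- comparisonSides(design, comparison)
    if (length(sides$A) + length(sides$B) != 8L)
        stop("replicate shuffling expects 8 samples, 4 per side")
    samples <- seq_len(nrow(design))
    splits <- allBalancedSplits(samples)
    isIdentity <- vapply(splits, function(s)
        setequal(s, sides$A) || setequal(s, sides$B), logical(1))
    splits <- splits[!isIdentity]
    if (nPerms > length(splits))
        stop("nPerms exceeds the ", length(splits),
             " available distinct balanced relabelings")
    withSeed(seed, {
        pick <- sample(seq_along(splits), nPerms)
    })
    lapply(splits[pick], function(s)
        list(A = s, B = setdiff(samples, s)))
}

## shared significance-counting path used by both the observed run and the
## shuffled runs: identical filtering, test and thresholds
countSignificantWindows <- function(wc, called, design, sideA, sideB,
                                    test = c("ttest", "betabin"),
                                    alpha = 0.05, minDiff = 0.15,
                                    minCov = 5L, minSamples = 3L,
                                    requireMethylated = TRUE,
                                    windows = NULL) {
    test <- match.arg(test)
    sides <- list(A = sideA, B = sideB)
    cov <- wc$M + wc$U
    okA <- rowSums(cov[, sideA, drop = FALSE] >= minCov) >= minSamples
    okB <- rowSums(cov[, sideB, drop = FALSE] >= minCov) >= minSamples
    testable <- okA & okB
    if (requireMethylated && !is.null(called)) {
        half <- ceiling(ncol(called) / 2)
        siteMeth <- rowSums(assay(called, "status") == "methylated") >= half
        winHasMeth <- rep(FALSE, nrow(cov))
        keep <- !is.na(wc$siteWindow) & siteMeth
        winHasMeth[unique(wc$siteWindow[keep])] <- TRUE
        testable <- testable & winHasMeth
    }
    idx <- which(testable)
    if (!length(idx)) return(0L)
    if (test == "ttest") {
        frac <- wc$M / cov
        frac[cov < minCov] <- NA    # fractions only from covered replicates
        fa <- frac[idx, sideA, drop = FALSE]
        fb <- frac[idx, sideB, drop = FALSE]
        na <- rowSums(!is.na(fa)); nb <- rowSums(!is.na(fb))
        usable <- na >= 2 & nb >= 2
        ma <- rowMeans(fa, na.rm = TRUE); mb <- rowMeans(fb, na.rm = TRUE)
        va <- apply(fa, 1, var, na.rm = TRUE)
        vb <- apply(fb, 1, var, na.rm = TRUE)
        se2 <- va / na + vb / nb
        tstat <- (ma - mb) / sqrt(se2)
        df <- se2^2 / ((va / na)^2 / (na - 1) + (vb / nb)^2 / (nb - 1))
        p <- 2 * pt(abs(tstat), df, lower.tail = FALSE)
        zeroVar <- is.finite(se2) & se2 == 0
        p[zeroVar & abs(ma - mb) == 0] <- 1   # identical replicates
        p[zeroVar & abs(ma - mb) > 0] <- 0
        p[!usable] <- NA
        q <- bhAdjust(p)
        sum(q < alpha & abs(ma - mb) > minDiff, na.rm = TRUE)
    } else {
        theta <- localDispersionAll(wc, windows, sides, idx)
        nsig <- 0L
        ps <- diffs <- numeric(length(idx))
        for (k in seq_along(idx)) {
            i <- idx[k]
            fit <- betaBinomFit(wc$M[i, sideA], wc$U[i, sideA],
                                wc$M[i, sideB], wc$U[i, sideB], theta[k])
            ps[k] <- pchisq(fit$lrt, 1, lower.tail = FALSE)
            diffs[k] <- fit$piA - fit$piB
        }
        q <- bhAdjust(ps)
        sum(q < alpha & abs(diffs) > minDiff)
    }
}

#' Null distribution of significant-window counts under replicate shuffling
#'
#' Re-runs the identical filtering and testing path used for the observed
#' comparison under shuffled replicate labels, and returns the observed
#' count next to the null distribution. The `"ttest"` procedure (Welch
#' two-sample t on per-replicate window fractions, BH-corrected, same
#' significance filters) supports any number of iterations by sampling the
#' 34 distinct balanced relabelings with replacement (`replace = TRUE`,
#' the default when `nPerms` exceeds 34); the `"betabin"` procedure reuses
#' the window likelihood-ratio test.
#'
#' @param called A [BSCounts] after [callMethylation()].
#' @param windows window `GRanges`.
#' @param comparison `"caste"` or `"sex"`.
#' @param nPerms number of shuffled runs (e.g. 100).
#' @param seed RNG seed.
#' @param test `"ttest"` or `"betabin"`.
#' @param replace sample schemes with replacement; default `nPerms > 34`.
#' @param alpha,minDiff,minCov,minSamples,requireMethylated thresholds as in
#'   [testWindows()].
#' @return list with `observed` (count), `null` (integer vector of length
#'   `nPerms`) and `summary` from [empiricalExcess()].
#' @export
permutedDmrCounts <- function(called, windows, comparison, nPerms, seed,
                              test = c("ttest", "betabin"),
                              replace = NULL,
                              alpha = 0.05, minDiff = 0.15,
                              minCov = 5L, minSamples = 3L,
                              requireMethylated = TRUE) {
    test <- match.arg(test)
    design <- sampleDesign(called)
    sides <- comparisonSides(design, comparison)
    wc <- windowCounts(called, windows)
    run <- function(A, B) countSignificantWindows(
        wc, called, design, A, B, test = test, alpha = alpha,
        minDiff = minDiff, minCov = minCov, minSamples = minSamples,
        requireMethylated = requireMethylated, windows = windows)
    observed <- run(sides$A, sides$B)
    splits <- allBalancedSplits(seq_len(nrow(design)))
    splits <- splits[!vapply(splits, function(s)
        setequal(s, sides$A) || setequal(s, sides$B), logical(1))]
    if (is.null(replace)) replace <- nPerms > length(splits)
    if (!replace && nPerms > length(splits))
        stop("nPerms exceeds the ", length(splits),
             " available distinct balanced relabelings; use replace = TRUE")
    withSeed(seed, {
        pick <- sample(seq_along(splits), nPerms, replace = replace)
    })
    null <- vapply(pick, function(j) {
        A <- splits[[j]]
        as.integer(run(A, setdiff(seq_len(nrow(design)), A)))
    }, integer(1))
    list(observed = observed, null = null,
         summary = empiricalExcess(observed, null))
}

#' Empirical excess of the observed count over the shuffled null
#'
#' Empirical p = (1 + #\{null >= observed\}) / (1 + nPerms); fold =
#' observed / mean(null), with the null mean floored at 1.
#'
#' @param observed observed significant-window count.
#' @param nullCounts vector of counts from shuffled runs.
#' @return data.frame observed, nullMean, nullMax, empiricalP, fold.
#' @export
empiricalExcess <- function(observed, nullCounts) {
    if (!length(nullCounts)) stop("empty null distribution")
    data.frame(observed = observed,
               nullMean = mean(nullCounts),
               nullMax = max(nullCounts),
               empiricalP = (1 + sum(nullCounts >= observed)) /
                            (1 + length(nullCounts)),
               fold = observed / max(mean(nullCounts), 1))
}
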