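#' @importFrom stats pbinom p.adjust setNames
NULL

#' Estimate the bisulfite conversion error from an unmethylated control
#'
#' The conversion (deamination) error is the fraction of truly unmethylated
#' cytosines that are read as methylated, i.e. unconverted reads over total
#' read cytosines in the unmethylated lambda spike-in. When counts from
#' non-genic non-CpG genomic cytosines are also supplied, their rate is
#' returned alongside for a concordance check, and a warning is emitted when
#' the two estimates differ by more than two-fold.
#'
#' @param unconverted,total unconverted and total read cytosines in the
#'   spike-in control.
#' @param nonCpGUnconverted,nonCpGTotal optional counts at non-genic
#'   non-CpG genomic cytosines.
#' @param floor minimum returned rate (default 1e-6), so a perfectly
#'   converted control still yields a usable binomial success probability.
#' @return list with `rate`, and `nonCpGRate` when supplied.
#' @examples
#' estimateConversionError(100, 10000)$rate  # 0.01
#' @export
estimateConversionError <- function(unconverted, total,
                                    nonCpGUnconverted = NULL,
                                    nonCpGTotal = NULL, floor = 1e-6) {
    if (total <= 0) stop("total read cytosines must be positive")
    if (unconverted > total) stop("unconverted exceeds total")
    rate <- max(unconverted / total, floor)
    out <- list(rate = rate)
    if (!is.null(nonCpGUnconverted) && !is.null(nonCpGTotal)) {
        nr <- max(nonCpGUnconverted / nonCpGTotal, floor)
        out$nonCpGRate <- nr
        if (max(rate, nr) / min(rate, nr) > 2)
            warning(sprintf(
                "spike-in (%.2e) and non-CpG (%.2e) conversion-error estimates differ by >2x",
                rate, nr))
    }
    out
}

#' Upper-tail binomial p-value for methylated read counts
#'
#' The probability of observing at least `m` unconverted reads out of `cov`
#' when every read is unmethylated and unconverted reads arise only through
#' the conversion error `err`: `P(X >= m | n = cov, p = err)`. Vectorised
#' over `m` and `cov`; `binomialTailP(0, n) = 1` by convention.
#'
#' @param m methylated (unconverted) read count(s).
#' @param cov total coverage(s).
#' @param err conversion error rate in `[0,1]`.
#' @return p-value vector.
#' @examples
#' binomialTailP(3, 10, 0.05)  # 0.01150
#' @export
binomialTailP <- function(m, cov, err) {
    if (err < 0 || err > 1) stop("err must lie in [0,1]")
    if (any(m < 0 | m > cov)) stop("need 0 <= m <= cov")
    ifelse(m <= 0, 1, pbinom(m - 1, cov, err, lower.tail = FALSE))
}

#' Benjamini-Hochberg adjusted p-values
#'
#' Step-up BH adjustment, `q_(i) = min_(j>=i) p_(j) * m / j` capped at 1,
#' returned in the original order. A thin wrapper over
#' `stats::p.adjust(method = "BH")`.
#'
#' @param p p-value vector (NAs propagate).
#' @return q-value vector of the same length.
#' @export
bhAdjust <- function(p) {
    if (!length(p)) return(numeric(0))
    p.adjust(p, method = "BH")
}

#' Call per-CpG methylation status per sample
#'
#' For each sample, sites with coverage of at least `minCov` reads are
#' tested with the spike-in-calibrated binomial test; p-values are BH
#' adjusted within the sample over its testable sites; a site is called
#' methylated when its adjusted p falls below `alpha`. Sites below the
#' coverage threshold are `untestable`. The per-site methylated fraction is
#' `m/(m+u)` wherever coverage is positive.
#'
#' @param bs A [BSCounts].
#' @param err conversion error rate from [estimateConversionError()].
#' @param alpha FDR threshold for the methylated call (default 0.01).
#' @param minCov minimum coverage to test; the default 4 encodes
#'   "more than three reads".
#' @return The input [BSCounts] with added assays `p`, `q`,
#'   `status` (character: methylated/unmethylated/untestable) and `fraction`.
#' @export
callMethylation <- function(bs, err, alpha = 0.01, minCov = 4L) {
    M <- assay(bs, "M"); U <- assay(bs, "U")
    cov <- M + U
    p <- matrix(NA_real_, nrow(M), ncol(M), dimnames = dimnames(M))
    q <- p
    status <- matrix("untestable", nrow(M), ncol(M), dimnames = dimnames(M))
    for (j in seq_len(ncol(M))) {
        testable <- cov[, j] >= minCov
        if (any(testable)) {
            pj <- binomialTailP(M[testable, j], cov[testable, j], err)
            p[testable, j] <- pj
            q[testable, j] <- bhAdjust(pj)
            status[testable, j] <-
                ifelse(q[testable, j] < alpha, "methylated", "unmethylated")
        }
    }
    frac <- M / cov
    frac[cov == 0] <- NA_real_
    assay(bs, "p", withDimnames = FALSE) <- p
    assay(bs, "q", withDimnames = FALSE) <- q
    assay(bs, "status", withDimnames = FALSE) <- status
    assay(bs, "fraction", withDimnames = FALSE) <- frac
    metadata(bs)$call <- list(err = err, alpha = alpha, minCov = minCov)
    bs
}

#' Pooled calls and cross-sample consensus status
#'
#' Pools raw counts across all samples (summing, not averaging fractions)
#' and calls the pooled data with the same procedure; additionally counts,
#' per site, in how many individual samples the site was called methylated,
#' and classifies genes as methylated when at least one of their exon (or
#' exon+intron) CpGs is methylated in the pooled calls.
#'
#' @param called A [BSCounts] that has been through [callMethylation()].
#' @param annotation A [GeneAnnotation] (optional; gene-level output needs it).
#' @param kMin site-level consensus threshold: a site is consensus-methylated
#'   when methylated in at least `kMin` samples (default 2).
#' @param geneMode `"exons"` or `"exons+introns"`: which feature CpGs decide
#'   gene-level status.
#' @return list with `pooled` (single-sample [BSCounts] of the summed
#'   counts, called), `siteSupport` (integer per site: samples methylated),
#'   `consensusMethylated` (logical per site), and when annotation is given
#'   `geneStatus` (data.frame gene_id, nMethSites, status; genes with no
#'   covered CpGs get status `NA`).
#' @export
pooledConsensus <- function(called, annotation = NULL, kMin = 2L,
                            geneMode = c("exons", "exons+introns")) {
    geneMode <- match.arg(geneMode)
    if (kMin > ncol(called))
        stop("kMin exceeds the number of samples")
    prm <- metadata(called)$call
    if (is.null(prm)) stop("run callMethylation() first")
    M <- rowSums(assay(called, "M"))
    U <- rowSums(assay(called, "U"))
    pooled <- BSCounts(rowRanges(called),
                       M = matrix(M, ncol = 1), U = matrix(U, ncol = 1),
                       design = data.frame(sample = "pooled", caste = "all",
                                           sex = "all", replicate = 0L))
    pooled <- callMethylation(pooled, prm$err, prm$alpha, prm$minCov)
    support <- rowSums(assay(called, "status") == "methylated")
    out <- list(pooled = pooled, siteSupport = support,
                consensusMethylated = support >= kMin)
    if (!is.null(annotation)) {
        feat <- exonsBy(annotation)
        if (geneMode == "exons+introns")
            feat <- mergeGRLs(feat, intronsBy(annotation))
        pooledMeth <- assay(pooled, "status")[, 1] == "methylated"
        covered <- rowSums(methCoverage(called)) > 0
        gs <- vapply(seq_along(feat), function(i) {
            hits <- queryHits(findOverlaps(rowRanges(called), feat[[i]]))
            if (!length(hits) || !any(covered[hits])) return(NA_integer_)
            sum(pooledMeth[hits])
        }, integer(1))
        out$geneStatus <- data.frame(
            gene_id = names(feat), nMethSites = gs,
            status = ifelse(is.na(gs), NA_character_,
                            ifelse(gs > 0, "methylated", "unmethylated")),
            stringsAsFactors = FALSE)
    }
    out
}

mergeGRLs <- function(a, b) {
    stopifnot(identical(names(a), names(b)))
    endoapply(S4Vectors::mendoapply(c, a, b), GenomicRanges::sort)
}

#' Counts of sites/genes methylated in at least k samples
#'
#' @param called A [BSCounts] through [callMethylation()].
#' @param ks integer vector of thresholds.
#' @return data.frame k, nSites.
#' @export
consensusCounts <- function(called, ks = seq_len(ncol(called))) {
    if (any(ks > ncol(called))) stop("k exceeds the number of samples")
    support <- rowSums(assay(called, "status") == "methylated")
    data.frame(k = ks, nSites = vapply(ks, function(k) sum(support >= k),
                                       integer(1)))
}

#' Per-feature fractional methylation
#'
#' The weighted per-feature fraction is the summed methylated reads over
#' summed total reads across the feature's CpGs; the unweighted mean of
#' per-site fractions is emitted alongside for comparison. Features with no
#' covered CpGs get `NA`, never 0.
#'
#' @param bs A [BSCounts] (pooled single-sample or per-sample; counts are
#'   summed across columns).
#' @param features `GRanges` or `GRangesList`; names (or a `gene_id`/`name`
#'   column) label the output.
#' @return data.frame feature, nSites, weighted, unweighted.
#' @export
featureMethylation <- function(bs, features) {
    if (is(features, "GRangesList")) {
        nm <- names(features)
        flat <- unlist(features, use.names = FALSE)
        grp <- rep(seq_along(features), lengths(features))
    } else {
        nm <- mcols(features)$gene_id
        if (is.null(nm)) nm <- mcols(features)$name
        if (is.null(nm)) nm <- as.character(seq_along(features))
        flat <- features
        grp <- seq_along(features)
    }
    M <- rowSums(assay(bs, "M")); U <- rowSums(assay(bs, "U"))
    hits <- findOverlaps(rowRanges(bs), flat)
    fi <- grp[subjectHits(hits)]
    si <- queryHits(hits)
    covered <- (M + U)[si] > 0
    fi <- fi[covered]; si <- si[covered]
    n <- length(nm)
    sm <- rowsum(M[si], fi); su <- rowsum(U[si], fi)
    frac <- M[si] / (M + U)[si]
    mn <- rowsum(frac, fi) / rowsum(rep(1, length(fi)), fi)
    idx <- as.integer(rownames(sm))
    out <- data.frame(feature = nm, nSites = 0L,
                      weighted = NA_real_, unweighted = NA_real_,
                      stringsAsFactors = FALSE)
    out$nSites[idx] <- as.integer(table(factor(fi, levels = idx)))
    out$weighted[idx] <- sm / (sm + su)
    out$unweighted[idx] <- mn
    out
}
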