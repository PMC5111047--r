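#' @importFrom stats sd cor.test fisher.test wilcox.test lm complete.cases
NULL

#' FPKM from counts, transcript lengths and library sizes
#'
#' `FPKM = count * 1e9 / (length_bp * library_total)`.
#'
#' @param counts genes x libraries count matrix.
#' @param lengths transcript length in bp per gene.
#' @param librarySizes total mapped fragments per library; defaults to the
#'   column sums of `counts`.
#' @return FPKM matrix of the same shape.
#' @examples
#' fpkm(matrix(10), lengths = 1000, librarySizes = 1e6)  # 10
#' @export
fpkm <- function(counts, lengths, librarySizes = colSums(counts)) {
    counts <- as.matrix(counts)
    if (any(lengths <= 0)) stop("transcript lengths must be positive")
    sweep(counts * 1e9 / lengths, 2, librarySizes, "/")
}

#' Expression specificity (tau index)
#'
#' `tau = sum(1 - x_i / max(x)) / (n - 1)` on per-condition means: 0 for
#' uniform expression, 1 for condition-exclusive expression.
#'
#' @param x per-condition mean expression (non-negative).
#' @return tau in `[0, 1]`, `NA` when all zero.
#' @export
tauIndex <- function(x) {
    if (all(x == 0) || any(is.na(x))) return(NA_real_)
    sum(1 - x / max(x)) / (length(x) - 1)
}

#' Per-gene expression summaries across morphs
#'
#' Within-morph replicate coefficient of variation (sd/mean of FPKM,
#' averaged over morphs; missing when a morph mean is 0), between-morph
#' absolute difference (max - min of morph means on log2(FPKM+1)), tau
#' specificity on linear morph means, and overall level (mean of morph
#' means).
#'
#' @param fpkmMat genes x libraries FPKM matrix.
#' @param design library design data.frame with columns `library`, `caste`,
#'   `sex` (row order = columns).
#' @return data.frame gene, level, logLevel, cv, absDiff, tau and one
#'   `mean_<morph>` column per morph.
#' @export
expressionSummaries <- function(fpkmMat, design) {
    morph <- paste(design$caste, design$sex, sep = "_")
    morphs <- unique(morph)
    nG <- nrow(fpkmMat)
    asMat <- function(x) matrix(x, nrow = nG,
                                dimnames = list(rownames(fpkmMat), morphs))
    mm <- asMat(vapply(morphs, function(g)
        rowMeans(fpkmMat[, morph == g, drop = FALSE]), numeric(nG)))
    lm2 <- asMat(vapply(morphs, function(g)
        rowMeans(log2(fpkmMat[, morph == g, drop = FALSE] + 1)),
        numeric(nG)))
    cvm <- asMat(vapply(morphs, function(g) {
        sub <- fpkmMat[, morph == g, drop = FALSE]
        if (ncol(sub) < 2) return(rep(NA_real_, nG))
        mu <- rowMeans(sub)
        s <- apply(sub, 1, sd)
        ifelse(mu > 0, s / mu, NA_real_)
    }, numeric(nG)))
    out <- data.frame(
        gene = rownames(fpkmMat),
        level = rowMeans(mm),
        logLevel = rowMeans(log2(mm + 1)),
        cv = rowMeans(cvm),
        absDiff = apply(lm2, 1, max) - apply(lm2, 1, min),
        tau = apply(mm, 1, tauIndex),
        stringsAsFactors = FALSE)
    colnames(mm) <- paste0("mean_", morphs)
    cbind(out, as.data.frame(mm))
}

#' Antisense transcription flags and continuous metric
#'
#' Within each library, every included locus (genes overlapping more than
#' half of another gene are excluded) is tested with an upper-tail binomial
#' test of its antisense count against the library-wide antisense
#' proportion over included loci; p-values are BH-adjusted within the
#' library and a locus-library pair is significant below `alpha`. A gene is
#' flagged antisense-expressed when significant in more than a third of
#' libraries. The continuous metric is, per sample type, the mean antisense
#' read proportion across its replicates.
#'
#' @param sense,antisense genes x libraries count matrices.
#' @param design library design (columns `library`, `caste`, `sex`).
#' @param excluded logical per gene: overlaps >50% of another gene.
#' @param alpha per-library FDR threshold (default 0.05).
#' @return list: `flags` (logical per included gene), `nSignificant`
#'   (libraries significant per gene), `globalRate` (per library),
#'   `metric` (genes x sample types mean antisense proportion), `perGene`
#'   (data.frame).
#' @export
antisenseFlags <- function(sense, antisense, design,
                           excluded = rep(FALSE, nrow(sense)),
                           alpha = 0.05) {
    stopifnot(identical(dim(sense), dim(antisense)))
    inc <- !excluded
    tot <- sense + antisense
    nLib <- ncol(sense)
    sig <- matrix(FALSE, nrow(sense), nLib, dimnames = dimnames(sense))
    globalRate <- numeric(nLib)
    for (j in seq_len(nLib)) {
        globalRate[j] <- sum(antisense[inc, j]) / max(sum(tot[inc, j]), 1)
        use <- inc & tot[, j] > 0
        p <- rep(NA_real_, nrow(sense))
        p[use] <- binomialTailP(antisense[use, j], tot[use, j], globalRate[j])
        q <- rep(NA_real_, nrow(sense))
        q[use] <- bhAdjust(p[use])
        sig[, j] <- !is.na(q) & q < alpha
    }
    nSig <- rowSums(sig)
    flags <- inc & nSig > nLib / 3
    morph <- paste(design$caste, design$sex, sep = "_")
    morphs <- unique(morph)
    prop <- antisense / tot
    metric <- matrix(vapply(morphs, function(g)
        rowMeans(prop[, morph == g, drop = FALSE], na.rm = TRUE),
        numeric(nrow(sense))), nrow = nrow(sense),
        dimnames = list(rownames(sense), morphs))
    list(flags = flags, nSignificant = nSig, globalRate = globalRate,
         metric = metric,
         perGene = data.frame(gene = rownames(sense), included = inc,
                              nSignificant = nSig, antisenseFlag = flags,
                              meanAntisenseProp = rowMeans(prop, na.rm = TRUE),
                              stringsAsFactors = FALSE))
}

#' Rank correlations and a standardized joint model of methylation
#'
#' Per predictor: Spearman rho, the R-squared of a single-predictor fit on
#' ranks, and the correlation-test p. Jointly: ordinary least squares of
#' rank-transformed methylation on standardized rank-transformed
#' predictors; zero-variance predictors are dropped with a warning, and of
#' a perfectly collinear pair the second is dropped with a warning.
#'
#' @param df data.frame containing `methylation` and the predictor columns.
#' @param predictors predictor column names (default: every other numeric
#'   column).
#' @return list: `marginal` (data.frame predictor, rho, r2, p),
#'   `coefficients` (standardized joint coefficients, sign and magnitude
#'   rank), `model` (the `lm` fit).
#' @export
methylationExpressionModel <- function(df, predictors = NULL) {
    if (is.null(predictors))
        predictors <- setdiff(colnames(df)[vapply(df, is.numeric, logical(1))],
                              "methylation")
    df <- df[complete.cases(df[, c("methylation", predictors)]), ]
    keep <- predictors[vapply(predictors, function(p) {
        v <- var(df[[p]])
        if (is.na(v) || v == 0) {
            warning("dropping zero-variance predictor ", p)
            FALSE
        } else TRUE
    }, logical(1))]
    marg <- do.call(rbind, lapply(keep, function(p) {
        ct <- suppressWarnings(
            cor.test(df$methylation, df[[p]], method = "spearman"))
        data.frame(predictor = p, rho = unname(ct$estimate),
                   r2 = unname(ct$estimate)^2, p = ct$p.value,
                   stringsAsFactors = FALSE)
    }))
    ranks <- as.data.frame(lapply(df[keep], rank))
    ## drop later members of perfectly collinear pairs
    if (length(keep) > 1) {
        cm <- abs(cor(ranks))
        drop <- character(0)
        for (i in seq_along(keep)[-1])
            for (j in seq_len(i - 1))
                if (!(keep[j] %in% drop) && cm[i, j] > 1 - 1e-12)
                    drop <- c(drop, keep[i])
        if (length(drop)) {
            warning("dropping collinear predictor(s): ",
                    paste(unique(drop), collapse = ", "))
            keep <- setdiff(keep, unique(drop))
            ranks <- ranks[keep]
        }
    }
    z <- as.data.frame(scale(ranks))
    z$.y <- scale(rank(df$methylation))[, 1]
    fit <- lm(.y ~ ., data = z)
    cf <- stats::coef(fit)[-1]
    coefs <- data.frame(predictor = names(cf), beta = unname(cf),
                        sign = sign(unname(cf)),
                        magnitudeRank = rank(-abs(unname(cf))),
                        stringsAsFactors = FALSE)
    list(marginal = marg, coefficients = coefs, model = fit)
}

#' Gene-family conservation and duplication metrics
#'
#' Per family: the proportion of species with at least one member
#' (large-scale conservation), the mean copy number across species
#' (ancestral duplication rate), and the focal-species copy number over the
#' cross-species mean. Genes of families with focal copy number > 1 are
#' labelled duplicated; [methylationExpressionModel()] can then be run per
#' stratum and the slope contrast reported.
#'
#' @param orthologs data.frame with columns `family`, `species`, `copies`.
#' @param focalSpecies name of the focal species (default "Znev").
#' @return data.frame family, nSpecies, propSpecies, meanCopies,
#'   focalCopies, focalRatio, duplicated. Families absent from the focal
#'   species get `NA` ratio.
#' @export
familyMetrics <- function(orthologs, focalSpecies = "Znev") {
    allSpecies <- unique(orthologs$species)
    sp <- split(orthologs, orthologs$family)
    out <- do.call(rbind, lapply(names(sp), function(f) {
        x <- sp[[f]]
        present <- x$species[x$copies > 0]
        fc <- x$copies[x$species == focalSpecies]
        fc <- if (length(fc)) fc[1] else NA_integer_
        data.frame(family = f,
                   nSpecies = length(unique(present)),
                   propSpecies = length(unique(present)) / length(allSpecies),
                   meanCopies = mean(x$copies),
                   focalCopies = fc,
                   focalRatio = if (!is.na(fc)) fc / mean(x$copies) else NA_real_,
                   duplicated = !is.na(fc) && fc > 1,
                   stringsAsFactors = FALSE)
    }))
    rownames(out) <- NULL
    out
}

#' Duplicated-vs-single methylation-expression slope contrast
#'
#' @param df gene table with `methylation`, predictor columns and a logical
#'   `duplicated` column.
#' @param predictor which predictor's slope to contrast (default
#'   "logLevel").
#' @return data.frame stratum, beta, rho, n.
#' @export
duplicationContrast <- function(df, predictor = "logLevel") {
    strata <- list(duplicated = df[df$duplicated %in% TRUE, ],
                   single = df[!(df$duplicated %in% TRUE), ])
    do.call(rbind, lapply(names(strata), function(s) {
        x <- strata[[s]]
        fitres <- methylationExpressionModel(x, predictors = predictor)
        data.frame(stratum = s,
                   beta = fitres$coefficients$beta[1],
                   rho = fitres$marginal$rho[1],
                   n = nrow(x), stringsAsFactors = FALSE)
    }))
}

#' DMG-vs-non-DMG expression and splicing contrasts
#'
#' Rank-sum tests of within-morph CV and between-morph absolute difference
#' between DMR-containing genes and others; Fisher exact tests of the
#' DMG x alternatively-spliced 2x2 table; and, per DMG, the distance from
#' each DMR midpoint to the nearest differentially-spliced exon against the
#' distances from non-significant windows, with a rank-sum p. Differential
#' expression/exon calls are consumed as input tables.
#'
#' @param dmgGenes character vector of DMG ids.
#' @param summaries result of [expressionSummaries()].
#' @param splicedGenes character vector of genes with a differential
#'   splicing event (external calls).
#' @param dmrs DMR `GRanges` (optional, for the distance contrast).
#' @param nonDmrWindows non-significant window `GRanges` (optional).
#' @param splicedExons differentially-spliced exon `GRanges` (optional).
#' @return list with `expression` (data.frame metric, pRankSum, medianDmg,
#'   medianOther), `splicing` (data.frame with Fisher p and sample odds
#'   ratio), `distance` (data.frame or NULL).
#' @export
dmgExpressionContrasts <- function(dmgGenes, summaries, splicedGenes,
                                   dmrs = NULL, nonDmrWindows = NULL,
                                   splicedExons = NULL) {
    isDmg <- summaries$gene %in% dmgGenes
    exprTab <- do.call(rbind, lapply(c("cv", "absDiff"), function(metric) {
        a <- summaries[[metric]][isDmg]; b <- summaries[[metric]][!isDmg]
        a <- a[is.finite(a)]; b <- b[is.finite(b)]
        p <- if (length(a) >= 2 && length(b) >= 2)
            suppressWarnings(wilcox.test(a, b)$p.value) else NA_real_
        data.frame(metric = metric, pRankSum = p,
                   medianDmg = stats::median(a), medianOther = stats::median(b),
                   stringsAsFactors = FALSE)
    }))
    spl <- summaries$gene %in% splicedGenes
    tab <- table(factor(isDmg, c(TRUE, FALSE)), factor(spl, c(TRUE, FALSE)))
    ft <- if (all(rowSums(tab) > 0) && all(colSums(tab) > 0))
        fisher.test(tab) else list(p.value = 1, estimate = NA)
    sampleOR <- (tab[1, 1] * tab[2, 2]) / max(tab[1, 2] * tab[2, 1], 1)
    splicing <- data.frame(pFisher = ft$p.value,
                           oddsRatio = sampleOR,
                           dmgSpliced = tab[1, 1], dmgNot = tab[1, 2],
                           otherSpliced = tab[2, 1], otherNot = tab[2, 2])
    distance <- NULL
    if (!is.null(dmrs) && !is.null(nonDmrWindows) && !is.null(splicedExons) &&
        length(dmrs) && length(splicedExons)) {
        mid <- function(gr) GRanges(seqnames(gr),
                                    IRanges(floor((start(gr) + end(gr)) / 2),
                                            width = 1L))
        dist1 <- GenomicRanges::distanceToNearest(mid(dmrs), splicedExons)
        dist0 <- GenomicRanges::distanceToNearest(mid(nonDmrWindows),
                                                  splicedExons)
        dd <- mcols(dist1)$distance; d0 <- mcols(dist0)$distance
        p <- if (length(dd) >= 2 && length(d0) >= 2)
            suppressWarnings(wilcox.test(dd, d0)$p.value) else NA_real_
        distance <- data.frame(medianDmr = stats::median(dd),
                               medianNonDmr = stats::median(d0),
                               pRankSum = p)
    }
    list(expression = exprTab, splicing = splicing, distance = distance)
}
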