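#' @importFrom stats optimize pchisq lbeta
#' @importFrom GenomicRanges tileGenome reduce
NULL

## ---- tiling ----------------------------------------------------------------

#' Tile a genome into fixed-width windows
#'
#' Half-open 200-bp tiles in spirit; returned as the usual 1-based closed
#' `GRanges`, with the terminal partial window retained.
#'
#' @param genome `DNAStringSet` or named integer vector of scaffold lengths.
#' @param width tile width in bp (default 200).
#' @return `GRanges` of windows in (scaffold, start) order.
#' @export
tileWindows <- function(genome, width = 200L) {
    if (width < 1L) stop("width must be >= 1")
    lens <- if (is.numeric(genome)) genome else genomeLengths(genome)
    lens <- lens[lens > 0L]
    if (!length(lens)) return(GRanges())
    tileGenome(lens, tilewidth = width, cut.last.tile.in.chrom = TRUE)
}

#' Sum site counts into windows per sample
#'
#' @param bs A [BSCounts].
#' @param windows `GRanges` tiling.
#' @return list with matrices `M`, `U` (windows x samples), `nCpG` (sites
#'   per window), and `siteWindow` (window index per site, NA outside).
#' @export
windowCounts <- function(bs, windows) {
    hits <- findOverlaps(rowRanges(bs), windows)
    sw <- rep(NA_integer_, nrow(bs))
    sw[queryHits(hits)] <- subjectHits(hits)
    nW <- length(windows)
    M <- U <- matrix(0L, nW, ncol(bs), dimnames = list(NULL, colnames(bs)))
    keep <- !is.na(sw)
    f <- factor(sw[keep], levels = seq_len(nW))
    for (j in seq_len(ncol(bs))) {
        M[, j] <- as.integer(rowsum(assay(bs, "M")[keep, j], f))
        U[, j] <- as.integer(rowsum(assay(bs, "U")[keep, j], f))
    }
    nCpG <- as.integer(table(f))
    list(M = M, U = U, nCpG = nCpG, siteWindow = sw)
}

comparisonSides <- function(design, comparison = c("caste", "sex")) {
    comparison <- match.arg(comparison)
    if (comparison == "caste")
        list(A = which(design$caste == "alate"),
             B = which(design$caste == "worker"),
             labels = c("hyper-alate", "hyper-worker"))
    else
        list(A = which(design$sex == "female"),
             B = which(design$sex == "male"),
             labels = c("hyper-female", "hyper-male"))
}

#' Testability filter for windows
#'
#' A window is testable when, on each side of the comparison, at least
#' `minSamples` of the pooled samples have window-summed coverage of at
#' least `minCov` reads (">4 reads"), and the window contains at least one
#' CpG called methylated in at least half of all samples.
#'
#' @param wc result of [windowCounts()].
#' @param design sample design data.frame (row order = columns of wc).
#' @param comparison `"caste"` or `"sex"`.
#' @param called the [BSCounts] after [callMethylation()] (for the
#'   methylated-in-half criterion); `NULL` skips that criterion.
#' @param minCov per-sample window coverage threshold (default 5).
#' @param minSamples samples per side that must reach it (default 3).
#' @return logical vector over windows.
#' @export
filterTestable <- function(wc, design, comparison, called = NULL,
                           minCov = 5L, minSamples = 3L) {
    sides <- comparisonSides(design, comparison)
    if (length(sides$A) < 3L || length(sides$B) < 3L)
        stop("comparison needs at least 3 samples per side")
    cov <- wc$M + wc$U
    okA <- rowSums(cov[, sides$A, drop = FALSE] >= minCov) >= minSamples
    okB <- rowSums(cov[, sides$B, drop = FALSE] >= minCov) >= minSamples
    ok <- okA & okB
    if (!is.null(called)) {
        half <- ceiling(ncol(called) / 2)
        siteMeth <- rowSums(assay(called, "status") == "methylated") >= half
        winHasMeth <- rep(FALSE, nrow(cov))
        keep <- !is.na(wc$siteWindow) & siteMeth
        winHasMeth[unique(wc$siteWindow[keep])] <- TRUE
        ok <- ok & winHasMeth
    }
    ok
}

## ---- beta-binomial likelihood ----------------------------------------------

## log-likelihood of replicate counts under BetaBin(n, pi, theta) with the
## mean/precision parameterisation alpha = pi*theta, beta = (1-pi)*theta
betaBinLogLik <- function(m, u, pi, theta) {
    a <- pi * theta; b <- (1 - pi) * theta
    sum(lchoose(m + u, m) + lbeta(m + a, u + b) - lbeta(a, b))
}

fitPi <- function(m, u, theta, tol = 1e-7) {
    if (!length(m) || sum(m + u) == 0) return(NA_real_)
    opt <- optimize(function(pi) betaBinLogLik(m, u, pi, theta),
                    c(1e-6, 1 - 1e-6), maximum = TRUE, tol = tol)
    opt$maximum
}

#' Beta-binomial likelihood-ratio fit for one window
#'
#' Maximum-likelihood group methylation proportions under a beta-binomial
#' with common precision `theta`, for the two groups separately
#' (alternative) and pooled (null).
#'
#' @param mA,uA,mB,uB per-replicate methylated/unmethylated window counts.
#' @param theta beta-binomial precision (alpha + beta).
#' @return list piA, piB, piNull, llAlt, llNull, lrt (non-negative).
#' @export
betaBinomFit <- function(mA, uA, mB, uB, theta) {
    piA <- fitPi(mA, uA, theta)
    piB <- fitPi(mB, uB, theta)
    piN <- fitPi(c(mA, mB), c(uA, uB), theta)
    llAlt <- betaBinLogLik(mA, uA, piA, theta) +
             betaBinLogLik(mB, uB, piB, theta)
    llNull <- betaBinLogLik(c(mA, mB), c(uA, uB), piN, theta)
    if (!is.finite(llAlt) || !is.finite(llNull))
        stop("non-finite beta-binomial likelihood")
    list(piA = piA, piB = piB, piNull = piN,
         llAlt = llAlt, llNull = llNull,
         lrt = max(0, 2 * (llAlt - llNull)))
}

#' Method-of-moments beta-binomial precision from replicate fractions
#'
#' For each cell (a group of replicates sharing a true proportion), the
#' intra-class correlation rho = 1/(theta+1) is estimated from the
#' standardized squared deviations of replicate fractions around the
#' coverage-weighted cell mean, with a finite-replicate correction; theta is
#' the average across cells, clamped to `[1, 1e6]`.
#'
#' @param m,u observation vectors (one entry per replicate x cell).
#' @param cell factor assigning observations to cells.
#' @return theta estimate (scalar).
#' @export
thetaMoM <- function(m, u, cell) {
    n <- m + u
    keep <- n >= 2
    m <- m[keep]; u <- u[keep]; n <- n[keep]
    cell <- factor(cell[keep])
    if (!length(m)) return(1e6)
    sm <- tapply(m, cell, sum); sn <- tapply(n, cell, sum)
    R <- tapply(rep(1, length(m)), cell, sum)
    pihat <- (sm / sn)[cell]
    Rc <- R[cell]
    ok <- pihat > 0 & pihat < 1 & Rc >= 2
    if (!any(ok)) return(1e6)
    p <- m[ok] / n[ok]
    r <- (p - pihat[ok])^2 / (pihat[ok] * (1 - pihat[ok])) *
         (Rc[ok] / (Rc[ok] - 1))
    rho <- (r - 1 / n[ok]) * n[ok] / (n[ok] - 1)
    mr <- mean(rho)
    if (mr <= 0) return(1e6)
    min(max(1 / mr - 1, 1), 1e6)
}

#' Locally pooled dispersion for a window
#'
#' Pools replicate fractions over the window plus its immediate flanking
#' windows (200 bp each side in the default tiling) and estimates the
#' beta-binomial precision by method of moments; with no flanking data the
#' estimate falls back to the window alone.
#'
#' @param wc result of [windowCounts()].
#' @param windows the window `GRanges`.
#' @param i window index.
#' @param sides result of `comparisonSides()` (groups define the cells).
#' @return theta estimate.
#' @export
localDispersion <- function(wc, windows, i, sides) {
    sc <- as.character(seqnames(windows))
    idx <- c(i - 1L, i, i + 1L)
    idx <- idx[idx >= 1L & idx <= length(windows)]
    idx <- idx[sc[idx] == sc[i]]
    gather <- function(ii) {
        grp <- rep(c("A", "B"), c(length(sides$A), length(sides$B)))
        cols <- c(sides$A, sides$B)
        list(m = as.vector(t(wc$M[ii, cols, drop = FALSE])),
             u = as.vector(t(wc$U[ii, cols, drop = FALSE])),
             cell = paste(rep(grp, length(ii)),
                          rep(ii, each = length(cols))))
    }
    g <- gather(idx)
    th <- thetaMoM(g$m, g$u, g$cell)
    if (length(idx) == 1L) return(th)
    th
}

## vectorised theta for all testable windows: MoM over window +- 1 tile
localDispersionAll <- function(wc, windows, sides, which) {
    sc <- as.character(seqnames(windows))
    vapply(which, function(i) localDispersion(wc, windows, i, sides),
           numeric(1))
}

#' Window (or single-CpG) differential methylation test
#'
#' For each testable window the beta-binomial likelihood-ratio statistic
#' with locally pooled dispersion is referred to chi-square(1); p-values are
#' BH-adjusted over the tested windows of the comparison. Significance
#' combines the FDR threshold with an absolute methylation-difference
#' filter (defaults q < 0.05 and |diff| > 0.15; use `alpha = 0.01,
#' minDiff = 0.20` for the confident single-CpG set).
#'
#' @param called A [BSCounts] after [callMethylation()].
#' @param windows window `GRanges` from [tileWindows()] (or width-1 CpG
#'   ranges for site-level tests).
#' @param comparison `"caste"` or `"sex"`.
#' @param alpha FDR threshold (default 0.05).
#' @param minDiff absolute group-difference threshold (default 0.15).
#' @param minCov,minSamples testability thresholds, see [filterTestable()].
#' @param requireMethylated apply the methylated-in-half-of-samples
#'   criterion (default TRUE).
#' @return the window `GRanges` with result columns: `tested`, `nCpG`,
#'   `piA`, `piB`, `diff`, `theta`, `lrt`, `p`, `q`, `direction`,
#'   `significant`.
#' @export
testWindows <- function(called, windows, comparison = c("caste", "sex"),
                        alpha = 0.05, minDiff = 0.15,
                        minCov = 5L, minSamples = 3L,
                        requireMethylated = TRUE) {
    comparison <- match.arg(comparison)
    design <- sampleDesign(called)
    sides <- comparisonSides(design, comparison)
    wc <- windowCounts(called, windows)
    testable <- filterTestable(wc, design, comparison,
                               called = if (requireMethylated) called else NULL,
                               minCov = minCov, minSamples = minSamples)
    nW <- length(windows)
    res <- DataFrame(tested = testable, nCpG = wc$nCpG,
                     piA = NA_real_, piB = NA_real_, diff = NA_real_,
                     theta = NA_real_, lrt = NA_real_,
                     p = NA_real_, q = NA_real_,
                     direction = NA_character_, significant = FALSE)
    idx <- which(testable)
    if (length(idx)) {
        theta <- localDispersionAll(wc, windows, sides, idx)
        fits <- lapply(seq_along(idx), function(k) {
            i <- idx[k]
            betaBinomFit(wc$M[i, sides$A], wc$U[i, sides$A],
                         wc$M[i, sides$B], wc$U[i, sides$B], theta[k])
        })
        res$piA[idx] <- vapply(fits, `[[`, numeric(1), "piA")
        res$piB[idx] <- vapply(fits, `[[`, numeric(1), "piB")
        res$diff[idx] <- res$piA[idx] - res$piB[idx]
        res$theta[idx] <- theta
        res$lrt[idx] <- vapply(fits, `[[`, numeric(1), "lrt")
        res$p[idx] <- pchisq(res$lrt[idx], df = 1, lower.tail = FALSE)
        res$q[idx] <- bhAdjust(res$p[idx])
        res$direction[idx] <- ifelse(res$diff[idx] >= 0,
                                     sides$labels[1], sides$labels[2])
        res$significant[idx] <- res$q[idx] < alpha &
                                abs(res$diff[idx]) > minDiff
    }
    out <- windows
    mcols(out) <- res
    metadata(out) <- list(comparison = comparison, alpha = alpha,
                          minDiff = minDiff, sides = sides)
    out
}

## ---- merging and gene assignment -------------------------------------------

featureTerritories <- function(annotation, downstreamLen = 2000L) {
    ex <- unlist(exonsBy(annotation), use.names = FALSE)
    inx <- unlist(intronsBy(annotation), use.names = FALSE)
    g <- genes(annotation)
    plus <- as.logical(strand(g) != "-")
    dn <- GRanges(seqnames(g),
                  IRanges(ifelse(plus, end(g) + 1L,
                                 pmax(start(g) - downstreamLen, 1L)),
                          ifelse(plus, end(g) + downstreamLen,
                                 pmax(start(g) - 1L, 1L))))
    mcols(dn)$gene_id <- mcols(g)$gene_id
    list(exon = ex, promoter = promoterRanges(annotation), intron = inx,
         downstream = dn)
}

overlapBp <- function(query, subject) {
    hits <- findOverlaps(query, subject)
    ov <- pmin(end(query)[queryHits(hits)], end(subject)[subjectHits(hits)]) -
          pmax(start(query)[queryHits(hits)], start(subject)[subjectHits(hits)]) + 1L
    out <- numeric(length(query))
    if (length(hits)) {
        agg <- rowsum(ov, queryHits(hits))
        out[as.integer(rownames(agg))] <- agg
    }
    out
}

#' Merge significant windows into DMRs and assign genes/features
#'
#' Adjacent (bookended) significant windows sharing a direction are merged;
#' each DMR is assigned the genic feature type it overlaps most, with ties
#' broken exon > promoter > intron > downstream > intergenic, and the gene
#' whose territory (body + promoter + 2 kb downstream) it overlaps most.
#' The gene-level table counts caste-/sex-DMRs per direction.
#'
#' @param dmRes result of [testWindows()].
#' @param annotation A [GeneAnnotation].
#' @return list with `dmrs` (`GRanges` with nWindows, direction, feature,
#'   gene_id) and `dmgs` (data.frame gene_id, comparison, nDmr, nHyperA,
#'   nHyperB, direction).
#' @export
mergeAndAssign <- function(dmRes, annotation) {
    comparison <- metadata(dmRes)$comparison
    sig <- dmRes[mcols(dmRes)$significant %in% TRUE]
    dirs <- unique(mcols(sig)$direction)
    merged <- GRanges()
    for (d in dirs) {
        r <- reduce(granges(sig[mcols(sig)$direction == d]), min.gapwidth = 1L)
        if (length(r)) {
            mcols(r)$direction <- d
            merged <- c(merged, r)
        }
    }
    merged <- GenomicRanges::sort(merged)
    if (length(merged)) {
        mcols(merged)$nWindows <- GenomicRanges::countOverlaps(
            merged, sig, minoverlap = 1L)
        terr <- featureTerritories(annotation)
        prio <- c("exon", "promoter", "intron", "downstream")
        bp <- vapply(prio, function(f) overlapBp(merged, terr[[f]]),
                     numeric(length(merged)))
        bp <- matrix(bp, nrow = length(merged),
                     dimnames = list(NULL, prio))
        best <- apply(bp, 1L, function(v)
            if (all(v == 0)) "intergenic" else prio[which.max(v)])
        mcols(merged)$feature <- best
        ## gene territory = body + promoter + downstream
        g <- genes(annotation)
        terrAll <- c(granges(g), granges(promoterRanges(annotation)),
                     granges(terr$downstream))
        terrGene <- c(mcols(g)$gene_id, mcols(promoterRanges(annotation))$gene_id,
                      mcols(terr$downstream)$gene_id)
        hits <- findOverlaps(merged, terrAll)
        geneBp <- data.frame(
            dmr = queryHits(hits), gene = terrGene[subjectHits(hits)],
            bp = pmin(end(merged)[queryHits(hits)], end(terrAll)[subjectHits(hits)]) -
                 pmax(start(merged)[queryHits(hits)], start(terrAll)[subjectHits(hits)]) + 1L)
        assigned <- rep(NA_character_, length(merged))
        if (nrow(geneBp)) {
            agg <- stats::aggregate(bp ~ dmr + gene, geneBp, sum)
            agg <- agg[order(agg$dmr, -agg$bp, agg$gene), ]
            first <- agg[!duplicated(agg$dmr), ]
            assigned[first$dmr] <- first$gene
        }
        mcols(merged)$gene_id <- assigned
    }
    dmgs <- data.frame(gene_id = character(), comparison = character(),
                       nDmr = integer(), nHyperA = integer(),
                       nHyperB = integer(), direction = character(),
                       stringsAsFactors = FALSE)
    if (length(merged)) {
        df <- as.data.frame(mcols(merged))
        df <- df[!is.na(df$gene_id), ]
        if (nrow(df)) {
            labs <- metadata(dmRes)$sides$labels
            sp <- split(df, df$gene_id)
            dmgs <- do.call(rbind, lapply(names(sp), function(gid) {
                x <- sp[[gid]]
                nA <- sum(x$direction == labs[1])
                nB <- sum(x$direction == labs[2])
                data.frame(gene_id = gid, comparison = comparison,
                           nDmr = nrow(x), nHyperA = nA, nHyperB = nB,
                           direction = if (nA > nB) labs[1]
                                       else if (nB > nA) labs[2]
                                       else "mixed",
                           stringsAsFactors = FALSE)
            }))
            rownames(dmgs) <- NULL
        }
    }
    list(dmrs = merged, dmgs = dmgs)
}

#' Conservative DMG set from two paired comparisons
#'
#' Genes significant in both constituent pairwise comparisons with a
#' consistent direction (e.g. alate-vs-worker within females and within
#' males).
#'
#' @param dmgA,dmgB gene-level tables from [mergeAndAssign()].
#' @return data.frame of the intersected genes with their shared direction.
#' @export
pairedIntersection <- function(dmgA, dmgB) {
    common <- intersect(dmgA$gene_id, dmgB$gene_id)
    a <- dmgA[match(common, dmgA$gene_id), ]
    b <- dmgB[match(common, dmgB$gene_id), ]
    keep <- a$direction == b$direction & a$direction != "mixed"
    data.frame(gene_id = common[keep],
               direction = a$direction[keep],
               stringsAsFactors = FALSE)
}
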