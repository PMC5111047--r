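#' @importFrom stats median qnorm
NULL

pooledSiteFractions <- function(bs) {
    M <- rowSums(assay(bs, "M")); U <- rowSums(assay(bs, "U"))
    f <- M / (M + U)
    f[(M + U) == 0] <- NA_real_
    f
}

pooledSiteMethylated <- function(called) {
    ## methylated status of the pooled (count-summed) data
    if ("status" %in% assayNames(called) && ncol(called) == 1L)
        return(assay(called, "status")[, 1] == "methylated")
    prm <- metadata(called)$call
    if (is.null(prm)) stop("run callMethylation() first")
    pooled <- pooledConsensus(called)$pooled
    assay(pooled, "status")[, 1] == "methylated"
}

#' Metagene methylation profile
#'
#' Per-gene CpG fractions are assigned to length-normalised gene-body bins
#' plus fixed-bp flank bins, strand-flipped so bins run 5'->3'; the profile
#' is the across-gene mean per bin. The absolute mode profiles the first
#' and last `absoluteBp` of gene bodies in fixed-width bins instead.
#'
#' @param bs A [BSCounts] (fractions are computed from pooled counts).
#' @param annotation A [GeneAnnotation].
#' @param nBins gene-body bins (default 40).
#' @param flankBins flank bins per side (default 20).
#' @param flankBp flank span in bp (default 2000).
#' @param mode `"proportional"` or `"absolute"` (first/last `absoluteBp`).
#' @param absoluteBp span of the absolute mode (default 4000).
#' @param multiexonOnly restrict to multi-exon genes (default TRUE).
#' @return data.frame bin, region, mean, nGenes, ci (95% half-width).
#' @export
metageneProfile <- function(bs, annotation, nBins = 40L, flankBins = 20L,
                            flankBp = 2000L,
                            mode = c("proportional", "absolute"),
                            absoluteBp = 4000L, multiexonOnly = TRUE) {
    mode <- match.arg(mode)
    if (nBins < 1L) stop("nBins must be >= 1")
    g <- genes(annotation)
    if (multiexonOnly) g <- g[lengths(exonsBy(annotation)[mcols(g)$gene_id]) > 1L]
    frac <- pooledSiteFractions(bs)
    sites <- rowRanges(bs)
    pos <- start(sites); sc <- as.character(seqnames(sites))
    acc <- list()
    for (i in seq_along(g)) {
        gs <- start(g)[i]; ge <- end(g)[i]
        minus <- as.character(strand(g))[i] == "-"
        onScaf <- sc == as.character(seqnames(g))[i]
        if (mode == "proportional") {
            lo <- gs - flankBp; hi <- ge + flankBp
            sel <- which(onScaf & pos >= lo & pos <= hi & !is.na(frac))
            if (!length(sel)) next
            p <- pos[sel]
            bin <- integer(length(p))
            inBody <- p >= gs & p <= ge
            rel <- (p[inBody] - gs + 1) / (ge - gs + 1)
            if (minus) rel <- 1 - rel + 1 / (ge - gs + 1)
            bin[inBody] <- flankBins + pmin(pmax(ceiling(rel * nBins), 1L), nBins)
            up <- p < gs
            relU <- (gs - p[up]) / flankBp        # (0,1], 5' flank distance
            dn <- p > ge
            relD <- (p[dn] - ge) / flankBp
            if (!minus) {
                bin[up] <- flankBins - pmin(ceiling(relU * flankBins), flankBins) + 1L
                bin[dn] <- flankBins + nBins + pmin(ceiling(relD * flankBins), flankBins)
            } else {
                bin[dn] <- flankBins - pmin(ceiling(relD * flankBins), flankBins) + 1L
                bin[up] <- flankBins + nBins + pmin(ceiling(relU * flankBins), flankBins)
            }
            acc[[length(acc) + 1L]] <- rowsumMean(bin, frac[sel],
                                                  nBinsTotal = nBins + 2L * flankBins)
        } else {
            sel <- which(onScaf & pos >= gs & pos <= ge & !is.na(frac))
            if (!length(sel)) next
            p <- pos[sel]
            from5 <- if (minus) ge - p else p - gs     # 0-based distance from TSS
            from3 <- if (minus) p - gs else ge - p
            binW <- absoluteBp / nBins
            b5 <- ifelse(from5 < absoluteBp, pmin(floor(from5 / binW) + 1L, nBins), NA)
            b3 <- ifelse(from3 < absoluteBp, pmin(floor(from3 / binW) + 1L, nBins), NA)
            v <- c(b5[!is.na(b5)], nBins + (nBins - b3[!is.na(b3)] + 1L))
            f <- c(frac[sel][!is.na(b5)], frac[sel][!is.na(b3)])
            acc[[length(acc) + 1L]] <- rowsumMean(v, f, nBinsTotal = 2L * nBins)
        }
    }
    if (!length(acc)) stop("no genes with covered CpGs")
    perGene <- do.call(rbind, acc)          # genes x bins, NA where absent
    means <- colMeans(perGene, na.rm = TRUE)
    nG <- colSums(!is.na(perGene))
    sds <- apply(perGene, 2, sd, na.rm = TRUE)
    nTot <- ncol(perGene)
    region <- if (mode == "proportional")
        rep(c("upstream", "body", "downstream"),
            c(flankBins, nBins, flankBins))
    else rep(c("first", "last"), each = nBins)
    data.frame(bin = seq_len(nTot), region = region, mean = means,
               nGenes = nG, ci = qnorm(0.975) * sds / sqrt(pmax(nG, 1)))
}

rowsumMean <- function(bin, val, nBinsTotal) {
    out <- rep(NA_real_, nBinsTotal)
    s <- rowsum(val, bin); n <- rowsum(rep(1, length(bin)), bin)
    out[as.integer(rownames(s))] <- s / n
    out
}

#' Methylation profile around internal exon-intron junctions
#'
#' For every internal junction (first exon starts and last exon ends are
#' excluded) the mean CpG fraction is accumulated per bp offset in
#' transcription orientation: negative offsets on the exon side, positive
#' on the intron side. Profiles are produced for all exons and for
#' methylated exons (those containing a methylated CpG in the pooled
#' calls).
#'
#' @param called A [BSCounts] after [callMethylation()].
#' @param annotation A [GeneAnnotation].
#' @param spanBp bp on each side (default 200); offsets beyond a feature's
#'   length are truncated, never padded.
#' @return data.frame offset, set ("all"/"methylated"), mean, n.
#' @export
junctionProfile <- function(called, annotation, spanBp = 200L) {
    frac <- pooledSiteFractions(called)
    methSite <- pooledSiteMethylated(called)
    sites <- rowRanges(called)
    exl <- exonsBy(annotation)
    g <- genes(annotation)
    offAll <- offMeth <- list()
    ## offset convention: exon-side bp adjacent to the junction = -1,
    ## intron-side adjacent bp = +1; strand-independent, since the two
    ## sides are defined by the features themselves
    addJunction <- function(sel, off, exonIsMeth) {
        d <- data.frame(offset = off, frac = frac[sel])
        offAll[[length(offAll) + 1L]] <<- d
        if (exonIsMeth) offMeth[[length(offMeth) + 1L]] <<- d
    }
    for (i in seq_along(g)) {
        ex <- exl[[i]]
        if (length(ex) < 2L) next
        exMeth <- GenomicRanges::countOverlaps(
            ex, sites[methSite & !is.na(frac)]) > 0
        onScaf <- as.character(seqnames(sites)) == as.character(seqnames(g))[i]
        for (k in seq_len(length(ex) - 1L)) {
            inLen <- start(ex)[k + 1L] - end(ex)[k] - 1L
            ## boundary after exon k (exon left, intron right)
            bnd <- end(ex)[k]
            lo <- bnd - min(spanBp, BiocGenerics::width(ex)[k]) + 1L
            hi <- bnd + min(spanBp, inLen)
            sel <- which(onScaf & start(sites) >= lo & start(sites) <= hi &
                         !is.na(frac))
            if (length(sel)) {
                o <- start(sites)[sel] - bnd
                addJunction(sel, ifelse(o <= 0L, o - 1L, o), exMeth[k])
            }
            ## boundary before exon k+1 (intron left, exon right)
            bnd2 <- start(ex)[k + 1L]
            lo2 <- bnd2 - min(spanBp, inLen)
            hi2 <- bnd2 + min(spanBp, BiocGenerics::width(ex)[k + 1L]) - 1L
            sel2 <- which(onScaf & start(sites) >= lo2 & start(sites) <= hi2 &
                          !is.na(frac))
            if (length(sel2)) {
                o <- start(sites)[sel2] - bnd2
                addJunction(sel2, ifelse(o >= 0L, -(o + 1L), -o),
                            exMeth[k + 1L])
            }
        }
    }
    summarise <- function(lst, set) {
        if (!length(lst))
            return(data.frame(offset = integer(0), set = character(0),
                              mean = numeric(0), n = integer(0)))
        df <- do.call(rbind, lst)
        s <- rowsum(df$frac, df$offset); n <- rowsum(rep(1, nrow(df)), df$offset)
        data.frame(offset = as.integer(rownames(s)), set = set,
                   mean = as.numeric(s / n), n = as.integer(n))
    }
    rbind(summarise(offAll, "all"), summarise(offMeth, "methylated"))
}

#' CpG observed/expected ratio
#'
#' `o/e = N_CG * L / (N_C * N_G)` with `N_CG` the count of CG dinucleotides
#' on the given strand and `L` the sequence length; `NA` when the sequence
#' has no C or no G.
#'
#' @param seq character string, `DNAString`, or `DNAStringSet` (vectorised).
#' @return numeric ratio(s).
#' @examples
#' cpgObsExp("CGCG")  # 2
#' @export
cpgObsExp <- function(seq) {
    if (is.character(seq)) seq <- DNAStringSet(seq)
    if (is(seq, "DNAString")) seq <- DNAStringSet(seq)
    L <- Biostrings::width(seq)
    nCG <- vcountPattern("CG", seq)
    lf <- letterFrequency(seq, c("C", "G"))
    oe <- nCG * L / (lf[, "C"] * lf[, "G"])
    oe[lf[, "C"] * lf[, "G"] == 0] <- NA_real_
    unname(oe)
}

#' Methylation deciles for methylated genes
#'
#' Methylated genes are ranked by fraction (ties broken by stable gene-id
#' order) and split into 10 equal-size deciles (sizes differ by at most 1);
#' unmethylated genes are labelled "Un".
#'
#' @param fraction per-gene methylation fraction.
#' @param methylated logical per gene.
#' @param gene gene ids (tie-break order).
#' @return character vector: "1".."10" or "Un".
#' @export
methylationDeciles <- function(fraction, methylated, gene) {
    out <- rep("Un", length(fraction))
    idx <- which(methylated)
    n <- length(idx)
    if (n < 10L) stop("need at least 10 methylated genes to form deciles")
    o <- idx[order(fraction[idx], gene[idx])]
    dec <- ceiling(seq_len(n) * 10 / n)
    out[o] <- as.character(dec)
    out
}

#' Distance to the nearest adjacent gene
#'
#' Minimum gap in bp to the nearest other gene on the same scaffold
#' (0 when genes overlap or abut); `NA` for genes alone on their scaffold.
#'
#' @param annotation A [GeneAnnotation].
#' @return named numeric vector per gene.
#' @export
nearestGeneDistance <- function(annotation) {
    g <- genes(annotation)
    d <- rep(NA_real_, length(g))
    hits <- GenomicRanges::distanceToNearest(g, ignore.strand = TRUE)
    d[queryHits(hits)] <- mcols(hits)$distance
    stats::setNames(d, mcols(g)$gene_id)
}

#' Profile of methylation, CpG o/e and GC% around unmethylated promoters
#'
#' Considers genes whose body contains a methylated CpG while the promoter
#' contains none; profiles mean fractional methylation, CpG o/e and GC
#' content in fixed-width bins across the promoter extended by `spanBp`
#' each side, oriented 5'->3'.
#'
#' @param called A [BSCounts] after [callMethylation()].
#' @param annotation A [GeneAnnotation].
#' @param genome `DNAStringSet`.
#' @param spanBp extension each side of the promoter (default 2000).
#' @param binBp bin width (default 200).
#' @return data.frame bin, offsetBp (bin start relative to promoter start),
#'   fraction, cpgOE, gc, nGenes; empty (with a warning) when no promoter
#'   qualifies.
#' @export
promoterIslandProfile <- function(called, annotation, genome,
                                  spanBp = 2000L, binBp = 200L) {
    frac <- pooledSiteFractions(called)
    methSite <- pooledSiteMethylated(called)
    sites <- rowRanges(called)
    g <- genes(annotation)
    pr <- promoterRanges(annotation)
    methGr <- sites[methSite]
    bodyMeth <- GenomicRanges::countOverlaps(g, methGr) > 0
    promMeth <- GenomicRanges::countOverlaps(pr, methGr) > 0
    qual <- which(bodyMeth & !promMeth)
    if (!length(qual)) {
        warning("no gene with methylated body and unmethylated promoter")
        return(data.frame(bin = integer(0), offsetBp = integer(0),
                          fraction = numeric(0), cpgOE = numeric(0),
                          gc = numeric(0), nGenes = integer(0)))
    }
    lens <- genomeLengths(genome)
    nBins <- as.integer(ceiling((2L * spanBp +
                                 max(BiocGenerics::width(pr))) / binBp))
    fracM <- oeM <- gcM <- matrix(NA_real_, length(qual), nBins)
    for (k in seq_along(qual)) {
        i <- qual[k]
        minus <- as.character(strand(pr))[i] == "-"
        lo <- start(pr)[i] - spanBp; hi <- end(pr)[i] + spanBp
        lo <- max(lo, 1L); hi <- min(hi, lens[as.character(seqnames(pr))[i]])
        edges <- seq(lo, hi, by = binBp)
        for (b in seq_len(length(edges) - 1L)) {
            b0 <- edges[b]; b1 <- min(edges[b + 1L] - 1L, hi)
            bin <- if (minus) length(edges) - b else b
            if (bin > nBins) next
            sel <- which(as.character(seqnames(sites)) ==
                         as.character(seqnames(pr))[i] &
                         start(sites) >= b0 & start(sites) <= b1 &
                         !is.na(frac))
            if (length(sel)) fracM[k, bin] <- mean(frac[sel])
            sq <- subseq(genome[[as.character(seqnames(pr))[i]]], b0, b1)
            oeM[k, bin] <- cpgObsExp(as.character(sq))
            gcM[k, bin] <- sum(letterFrequency(sq, c("G", "C"))) / (b1 - b0 + 1L)
        }
    }
    data.frame(bin = seq_len(nBins),
               offsetBp = (seq_len(nBins) - 1L) * binBp - spanBp,
               fraction = colMeans(fracM, na.rm = TRUE),
               cpgOE = colMeans(oeM, na.rm = TRUE),
               gc = colMeans(gcM, na.rm = TRUE),
               nGenes = colSums(!is.na(fracM)))
}

#' Repeat vs genomic-context methylation
#'
#' Repeats with at least 3 covered CpGs are classified as exon-intersecting,
#' intron-intersecting or non-genic. Each repeat's weighted fraction is
#' compared to its context: the intersected feature's CpGs excluding the
#' repeat's own, or a +-2 kb flank excluding any repeat or gene bp for
#' non-genic repeats. A two-sided Wilcoxon rank-sum test is run per class
#' (skipped below 2 repeats).
#'
#' @param bs A [BSCounts] (pooled counts are used).
#' @param annotation A [GeneAnnotation] with repeats.
#' @param flankBp non-genic context width per side (default 2000).
#' @param minCpG minimum covered CpGs in a repeat (default 3).
#' @return data.frame class, n, meanRepeat, meanContext, pRankSum.
#' @export
repeatContextMethylation <- function(bs, annotation, flankBp = 2000L,
                                     minCpG = 3L) {
    reps <- repeatRanges(annotation)
    sites <- rowRanges(bs)
    M <- rowSums(assay(bs, "M")); U <- rowSums(assay(bs, "U"))
    covered <- (M + U) > 0
    wFrac <- function(sel) {
        sel <- sel[covered[sel]]
        if (!length(sel)) return(NA_real_)
        sum(M[sel]) / sum(M[sel] + U[sel])
    }
    ex <- unlist(exonsBy(annotation), use.names = FALSE)
    inx <- unlist(intronsBy(annotation), use.names = FALSE)
    g <- genes(annotation)
    nCov <- GenomicRanges::countOverlaps(reps, sites[covered])
    reps <- reps[nCov >= minCpG]
    if (!length(reps))
        return(data.frame(class = character(0), n = integer(0),
                          meanRepeat = numeric(0), meanContext = numeric(0),
                          pRankSum = numeric(0)))
    cls <- ifelse(GenomicRanges::countOverlaps(reps, ex) > 0, "exon",
           ifelse(GenomicRanges::countOverlaps(reps, inx) > 0, "intron",
           ifelse(GenomicRanges::countOverlaps(reps, g) > 0, "genic-other",
                  "non-genic")))
    allReps <- repeatRanges(annotation)
    out <- list()
    for (cl in c("exon", "intron", "non-genic")) {
        idx <- which(cls == cl)
        if (!length(idx)) next
        rf <- cf <- numeric(length(idx))
        for (k in seq_along(idx)) {
            r <- reps[idx[k]]
            inRep <- queryHits(findOverlaps(sites, r))
            rf[k] <- wFrac(inRep)
            if (cl == "non-genic") {
                fl <- GRanges(seqnames(r),
                              IRanges(max(start(r) - flankBp, 1L),
                                      end(r) + flankBp))
                selC <- queryHits(findOverlaps(sites, fl))
                drop <- unique(c(queryHits(findOverlaps(sites, allReps)),
                                 queryHits(findOverlaps(sites, g))))
                cf[k] <- wFrac(setdiff(selC, drop))
            } else {
                feat <- if (cl == "exon") ex else inx
                container <- feat[subjectHits(findOverlaps(r, feat))]
                selC <- queryHits(findOverlaps(sites, container))
                cf[k] <- wFrac(setdiff(selC, inRep))
            }
        }
        ok <- is.finite(rf) & is.finite(cf)
        p <- if (sum(ok) >= 2)
            suppressWarnings(wilcox.test(rf[ok], cf[ok])$p.value)
        else NA_real_
        out[[cl]] <- data.frame(class = cl, n = sum(ok),
                                meanRepeat = mean(rf[ok]),
                                meanContext = mean(cf[ok]), pRankSum = p)
    }
    res <- do.call(rbind, out)
    rownames(res) <- NULL
    res
}

#' Cross-species ortholog methylation classes
#'
#' Assigns each complete 1-to-1 ortholog triplet to one of the 8 Venn
#' classes of per-species methylation status and tabulates counts and,
#' when fractions are given, per-class mean methylation in the focal
#' species.
#'
#' @param orthologs data.frame with an `ortholog` id column plus one column
#'   per species holding that species' gene id.
#' @param status named list (per species) of named character vectors
#'   gene -> "methylated"/"unmethylated".
#' @param fractions optional named numeric vector of focal-species gene
#'   fractions.
#' @param focalSpecies column name of the focal species (default first
#'   species column).
#' @return list: `perOrtholog` (data.frame ortholog, class), `classes`
#'   (data.frame class, count, meanFraction), `nDropped` (incomplete
#'   triplets).
#' @export
orthologMethylationClasses <- function(orthologs, status, fractions = NULL,
                                       focalSpecies = NULL) {
    if (anyDuplicated(orthologs$ortholog))
        stop("duplicate ortholog row")
    species <- setdiff(colnames(orthologs), "ortholog")
    if (is.null(focalSpecies)) focalSpecies <- species[1]
    st <- vapply(species, function(s)
        unname(status[[s]][as.character(orthologs[[s]])]),
        character(nrow(orthologs)))
    st <- matrix(st, nrow = nrow(orthologs),
                 dimnames = list(NULL, species))
    complete <- rowSums(is.na(st)) == 0
    nDropped <- sum(!complete)
    stC <- st[complete, , drop = FALSE]
    orth <- orthologs[complete, , drop = FALSE]
    cls <- apply(stC, 1, function(r) {
        m <- species[r == "methylated"]
        if (length(m) == 0) "none"
        else if (length(m) == length(species)) "all"
        else paste(m, collapse = "+")
    })
    per <- data.frame(ortholog = orth$ortholog, class = cls,
                      stringsAsFactors = FALSE)
    tab <- as.data.frame(table(class = cls), stringsAsFactors = FALSE)
    colnames(tab) <- c("class", "count")
    tab$meanFraction <- NA_real_
    if (!is.null(fractions)) {
        fr <- fractions[as.character(orth[[focalSpecies]])]
        agg <- tapply(fr, cls, mean, na.rm = TRUE)
        tab$meanFraction <- as.numeric(agg[tab$class])
    }
    list(perOrtholog = per, classes = tab, nDropped = nDropped)
}
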