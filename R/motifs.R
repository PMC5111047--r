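#' @importFrom stats fisher.test
NULL

BASES <- c("A", "C", "G", "T")

#' Read motifs from MEME-like minimal text
#'
#' Parses `MOTIF <id>` blocks followed by a
#' `letter-probability matrix:` header and w rows of 4 probabilities
#' (A C G T order); a `Background letter frequencies` section is honoured
#' when present. Columns are renormalised to sum exactly to 1.
#'
#' @param path MEME-format motif file.
#' @return named list of [MotifModel] objects.
#' @export
readMemeMotifs <- function(path) {
    lines <- readLines(path)
    bg <- c(A = .25, C = .25, G = .25, T = .25)
    bgAt <- grep("^Background letter frequencies", lines)
    if (length(bgAt)) {
        tok <- strsplit(trimws(lines[bgAt[1] + 1L]), "\\s+")[[1]]
        v <- as.numeric(tok[seq(2, length(tok), 2)])
        names(v) <- tok[seq(1, length(tok), 2)]
        bg[names(v)] <- v
    }
    starts <- grep("^MOTIF\\b", lines)
    out <- list()
    for (s in starts) {
        id <- strsplit(trimws(lines[s]), "\\s+")[[1]][2]
        h <- s + grep("letter-probability matrix", lines[(s + 1):length(lines)])[1]
        w <- as.integer(sub(".*w=\\s*(\\d+).*", "\\1", lines[h]))
        rows <- lines[(h + 1):(h + w)]
        m <- t(vapply(rows, function(r)
            as.numeric(strsplit(trimws(r), "\\s+")[[1]][1:4]), numeric(4)))
        mat <- t(m)                       # 4 x w
        rownames(mat) <- BASES
        mat <- sweep(mat, 2, colSums(mat), "/")
        out[[id]] <- MotifModel(id, mat, kind = "pwm", background = bg)
    }
    out
}

#' Mature miRNA sequence to a scannable motif
#'
#' Converts U to T and builds a near-point-mass PWM with pseudocount 0.01
#' on each off-letter (0.97 on the mature base). Both strands are scanned
#' by [pwmScan()], covering the target-site (reverse complement)
#' convention.
#'
#' @param id motif id.
#' @param matureSeq mature miRNA RNA string (ACGU letters only).
#' @param background background letter frequencies.
#' @return A [MotifModel] of kind `"mirna"`.
#' @examples
#' mirnaToMotif("mir-x", "UGAGGUA")
#' @export
mirnaToMotif <- function(id, matureSeq,
                         background = c(A = .25, C = .25, G = .25, T = .25)) {
    s <- toupper(matureSeq)
    if (grepl("[^ACGU]", s)) stop("non-ACGU letter in mature miRNA ", id)
    s <- chartr("U", "T", s)
    letters <- strsplit(s, "")[[1]]
    mat <- matrix(0.01, 4, length(letters), dimnames = list(BASES, NULL))
    mat[cbind(match(letters, BASES), seq_along(letters))] <- 0.97
    MotifModel(id, mat, kind = "mirna", background = background)
}

#' Read mature miRNA FASTA into motif models
#' @param path FASTA of mature miRNA sequences (RNA or DNA alphabet).
#' @param background background letter frequencies.
#' @return named list of [MotifModel] objects.
#' @export
readMirnaMotifs <- function(path,
                            background = c(A = .25, C = .25, G = .25, T = .25)) {
    ss <- Biostrings::readBStringSet(path)
    nm <- sub("\\s.*$", "", names(ss))
    out <- lapply(seq_along(ss), function(i)
        mirnaToMotif(nm[i], as.character(ss[[i]]), background))
    stats::setNames(out, nm)
}

## log2 likelihood-ratio score matrix vs background
scoreMatrix <- function(motif, background = motif@background) {
    log2(motif@matrix / background[BASES])
}

revcompScoreMatrix <- function(S) {
    S[4:1, ncol(S):1, drop = FALSE]
}

## exact null distribution of the single-position score under iid background:
## DP over motif columns, merging equal (rounded) score values
scoreNullDistribution <- function(S, background, digits = 9) {
    sc <- 0; pr <- 1
    for (j in seq_len(ncol(S))) {
        newSc <- as.vector(outer(S[, j], sc, "+"))
        newPr <- as.vector(outer(background[BASES], pr, "*"))
        key <- round(newSc, digits)
        agg <- rowsum(newPr, key)
        sc <- as.numeric(rownames(agg))
        pr <- as.numeric(agg)
        if (length(sc) > 2e5) {           # coarsen pathological supports
            key <- round(sc, 4)
            agg <- rowsum(pr, key)
            sc <- as.numeric(rownames(agg)); pr <- as.numeric(agg)
        }
    }
    o <- order(sc)
    list(score = sc[o], tailP = rev(cumsum(rev(pr[o]))))
}

nullTailP <- function(null, s, tol = 1e-6) {
    ## tail P(score >= s), tolerant of the DP's 9-digit score rounding
    i <- findInterval(s - tol, null$score) + 1L
    ifelse(i > length(null$score), 0, null$tailP[pmax(i, 1L)])
}

#' Scan sequences with a motif (FIMO-like)
#'
#' Scores every position on both strands with the log2 likelihood ratio of
#' the motif against the background, computes each position's p-value from
#' the exact score distribution under the background (dynamic programming
#' over motif columns), BH-adjusts over all scanned positions of the set,
#' and marks hits at q below `qThresh` (or at p below `pThresh` when
#' given). Sequences shorter than the motif contribute no positions;
#' positions covering N contribute none either.
#'
#' @param seqs `DNAStringSet` (or character vector).
#' @param motif A [MotifModel].
#' @param qThresh hit threshold on BH-adjusted p (default 0.1).
#' @param pThresh optional raw-p hit threshold overriding `qThresh`.
#' @param background background letter frequencies; defaults to the
#'   motif's own.
#' @return data.frame seq (index), name, position (1-based start on the
#'   plus strand), strand, score, p, q, hit.
#' @export
pwmScan <- function(seqs, motif, qThresh = 0.1, pThresh = NULL,
                    background = motif@background) {
    if (is.character(seqs)) seqs <- DNAStringSet(seqs)
    S <- scoreMatrix(motif, background)
    Sr <- revcompScoreMatrix(S)
    w <- ncol(S)
    null <- scoreNullDistribution(S, background)
    nm <- names(seqs)
    if (is.null(nm)) nm <- as.character(seq_along(seqs))
    res <- list()
    for (i in seq_along(seqs)) {
        chars <- strsplit(as.character(seqs[[i]]), "")[[1]]
        L <- length(chars)
        if (L < w) next
        code <- match(chars, BASES)
        nPos <- L - w + 1L
        fwd <- rev <- numeric(nPos)
        for (j in seq_len(w)) {
            cj <- code[j:(j + nPos - 1L)]
            fwd <- fwd + S[cbind(cj, j)]
            rev <- rev + Sr[cbind(cj, j)]
        }
        for (strand in c("+", "-")) {
            sc <- if (strand == "+") fwd else rev
            ok <- which(!is.na(sc))
            if (!length(ok)) next
            res[[length(res) + 1L]] <- data.frame(
                seq = i, name = nm[i], position = ok, strand = strand,
                score = sc[ok], p = nullTailP(null, sc[ok]),
                stringsAsFactors = FALSE)
        }
    }
    if (!length(res))
        return(data.frame(seq = integer(0), name = character(0),
                          position = integer(0), strand = character(0),
                          score = numeric(0), p = numeric(0),
                          q = numeric(0), hit = logical(0)))
    out <- do.call(rbind, res)
    out$q <- bhAdjust(out$p)
    out$hit <- if (is.null(pThresh)) out$q < qThresh else out$p < pThresh
    rownames(out) <- NULL
    out
}

#' Build DMC-centered test and flank-matched control sequence sets
#'
#' Test intervals are `width`-bp windows centered on each confident DMC
#' (ceiling((w-1)/2) bp left of the anchor, floor((w-1)/2) right). Control
#' intervals are built the same way around non-differential methylated
#' cytosines that lie within `maxDist` bp of a test anchor but whose
#' intervals do not overlap any test interval. Anchors too close to a
#' scaffold edge are dropped and counted.
#'
#' @param dmcs `GRanges` (width-1) of confident DMC anchors.
#' @param nonDmcs `GRanges` of candidate control anchors (already filtered
#'   to methylation level > 0.30).
#' @param genome `DNAStringSet`.
#' @param width extraction width (default 150).
#' @param maxDist control anchors must lie within this of a test anchor
#'   (default 1500).
#' @return list: `test`, `control` (each a list of `ranges` and `seqs`),
#'   `ratio` (control:test), `droppedTest`, `droppedControl`.
#' @export
buildSequenceSets <- function(dmcs, nonDmcs, genome, width = 150L,
                              maxDist = 1500L) {
    left <- as.integer(ceiling((width - 1) / 2))
    right <- as.integer(floor((width - 1) / 2))
    lens <- genomeLengths(genome)
    expand <- function(anchors) {
        gr <- GRanges(seqnames(anchors),
                      IRanges(start(anchors) - left, start(anchors) + right))
        inb <- start(gr) >= 1L &
               end(gr) <= lens[as.character(seqnames(gr))]
        list(ranges = gr[inb], dropped = sum(!inb), kept = which(inb))
    }
    te <- expand(dmcs)
    keepNd <- rep(TRUE, length(nonDmcs))
    d2t <- GenomicRanges::distanceToNearest(nonDmcs, dmcs)
    near <- rep(FALSE, length(nonDmcs))
    near[queryHits(d2t)] <- mcols(d2t)$distance <= maxDist
    co <- expand(nonDmcs[near])
    noOv <- !IRanges::overlapsAny(co$ranges, te$ranges)
    ctrlRanges <- co$ranges[noOv]
    getSeqs <- function(gr) {
        if (!length(gr)) return(DNAStringSet())
        DNAStringSet(vapply(seq_along(gr), function(i)
            as.character(subseq(genome[[as.character(seqnames(gr))[i]]],
                                start(gr)[i], end(gr)[i])), character(1)))
    }
    list(test = list(ranges = te$ranges, seqs = getSeqs(te$ranges)),
         control = list(ranges = ctrlRanges, seqs = getSeqs(ctrlRanges)),
         ratio = if (length(te$ranges)) length(ctrlRanges) / length(te$ranges)
                 else NA_real_,
         droppedTest = te$dropped,
         droppedControl = co$dropped + sum(!noOv))
}

#' Size-normalised fold enrichment of motif hits
#'
#' `fold = (pos/nPos) / (max(neg, 1)/nNeg)`: the test-set-size-normalised
#' hit count over the control's, with the control count floored at 1 so
#' motifs absent from the controls get a finite fold.
#'
#' @param posHits,negHits significant hit counts in test and control sets.
#' @param nPos,nNeg set sizes (sequence counts); must be positive.
#' @return fold enrichment (numeric).
#' @examples
#' foldEnrichment(55, 0, 5786, 10871)  # 103.337
#' @export
foldEnrichment <- function(posHits, negHits, nPos, nNeg) {
    if (any(nPos <= 0) || any(nNeg <= 0)) stop("set sizes must be positive")
    (posHits / nPos) / (pmax(negHits, 1) / nNeg)
}

#' Fisher enrichment of a motif in test vs control sequences
#'
#' One-sided Fisher exact test on the 2x2 table of sequences with at least
#' one significant hit vs without, test vs control. Degenerate margins give
#' p = 1.
#'
#' @param testWithHit,nTest,controlWithHit,nControl sequence counts.
#' @return list p, sample odds ratio, table.
#' @export
fisherEnrichment <- function(testWithHit, nTest, controlWithHit, nControl) {
    tab <- matrix(c(testWithHit, nTest - testWithHit,
                    controlWithHit, nControl - controlWithHit), 2,
                  dimnames = list(c("hit", "nohit"), c("test", "control")))
    if (any(tab < 0)) stop("hit counts exceed set sizes")
    p <- if (any(rowSums(tab) == 0)) 1
         else fisher.test(tab, alternative = "greater")$p.value
    oddsRatio <- (tab[1, 1] * tab[2, 2]) / max(tab[1, 2] * tab[2, 1], 1)
    list(p = p, oddsRatio = oddsRatio, table = tab)
}

#' Motif enrichment over test and control sequence sets
#'
#' Scans each motif over both sets (hit = FDR-significant position within
#' the set, q < `qThresh`), tests per-sequence hit presence with a
#' one-sided Fisher exact test, BH-adjusts over motifs, and reports the
#' size-normalised fold enrichment of hit counts.
#'
#' @param motifs named list of [MotifModel] objects.
#' @param testSeqs,controlSeqs `DNAStringSet`s.
#' @param qThresh per-position FDR threshold defining a hit (default 0.1).
#' @param backgroundFrom `"control"` (estimate letter frequencies from the
#'   pooled control sequences) or `"uniform"`.
#' @return data.frame motif, posHits, negHits, nPos, nNeg, posSeqs,
#'   negSeqs, fisherP, q, fold.
#' @export
motifEnrichment <- function(motifs, testSeqs, controlSeqs, qThresh = 0.1,
                            backgroundFrom = c("control", "uniform")) {
    backgroundFrom <- match.arg(backgroundFrom)
    bg <- if (backgroundFrom == "control" && length(controlSeqs)) {
        lf <- colSums(letterFrequency(controlSeqs, BASES))
        lf <- lf + 1          # pseudocount keeps all letters scorable
        lf / sum(lf)
    } else c(A = .25, C = .25, G = .25, T = .25)
    rows <- lapply(motifs, function(mo) {
        ht <- pwmScan(testSeqs, mo, qThresh = qThresh, background = bg)
        hc <- pwmScan(controlSeqs, mo, qThresh = qThresh, background = bg)
        posHits <- sum(ht$hit); negHits <- sum(hc$hit)
        fe <- fisherEnrichment(length(unique(ht$seq[ht$hit])),
                               length(testSeqs),
                               length(unique(hc$seq[hc$hit])),
                               length(controlSeqs))
        data.frame(motif = mo@id, posHits = posHits, negHits = negHits,
                   nPos = length(testSeqs), nNeg = length(controlSeqs),
                   posSeqs = length(unique(ht$seq[ht$hit])),
                   negSeqs = length(unique(hc$seq[hc$hit])),
                   fisherP = fe$p,
                   fold = foldEnrichment(posHits, negHits,
                                         max(length(testSeqs), 1),
                                         max(length(controlSeqs), 1)),
                   stringsAsFactors = FALSE)
    })
    out <- do.call(rbind, rows)
    out$q <- bhAdjust(out$fisherP)
    rownames(out) <- NULL
    out[, c("motif", "posHits", "negHits", "nPos", "nNeg",
            "posSeqs", "negSeqs", "fisherP", "q", "fold")]
}

#' Caste- vs sex-specific enrichment labels
#'
#' For each motif already enriched against its own flank controls, re-runs
#' the Fisher enrichment using the other phenotype's test set as the
#' control; a motif significant there is labelled with its phenotype,
#' otherwise `"ns"`.
#'
#' @param motifs named list of [MotifModel] objects.
#' @param casteSeqs,sexSeqs test `DNAStringSet`s of the two phenotypes.
#' @param casteEnriched,sexEnriched motif ids enriched vs flank controls.
#' @param alpha significance threshold for the cross test (default 0.05).
#' @param qThresh per-position hit threshold (default 0.1).
#' @return data.frame motif, set, crossP, comparison (caste/sex/ns).
#' @export
phenotypeSpecificEnrichment <- function(motifs, casteSeqs, sexSeqs,
                                        casteEnriched, sexEnriched,
                                        alpha = 0.05, qThresh = 0.1) {
    runCross <- function(ids, testSeqs, ctrlSeqs, label) {
        if (!length(ids)) return(NULL)
        do.call(rbind, lapply(ids, function(id) {
            mo <- motifs[[id]]
            ht <- pwmScan(testSeqs, mo, qThresh = qThresh)
            hc <- pwmScan(ctrlSeqs, mo, qThresh = qThresh)
            fe <- fisherEnrichment(length(unique(ht$seq[ht$hit])),
                                   length(testSeqs),
                                   length(unique(hc$seq[hc$hit])),
                                   length(ctrlSeqs))
            data.frame(motif = id, set = label, crossP = fe$p,
                       comparison = if (fe$p < alpha) label else "ns",
                       stringsAsFactors = FALSE)
        }))
    }
    out <- rbind(runCross(casteEnriched, casteSeqs, sexSeqs, "caste"),
                 runCross(sexEnriched, sexSeqs, casteSeqs, "sex"))
    if (is.null(out))
        out <- data.frame(motif = character(0), set = character(0),
                          crossP = numeric(0), comparison = character(0))
    rownames(out) <- NULL
    out
}
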