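#' @importFrom stats rpois rbinom rnbinom runif rnorm
NULL

## Deterministic sub-seed from (master seed, stream name): one RNG stream per
## output object, so adding samples never reshuffles existing ones.
streamSeed <- function(master, name) {
    h <- 0
    for (k in utf8ToInt(name)) h <- (h * 131 + k) %% 2147483629
    as.integer((as.numeric(master) * 48271 + h) %% 2147483629)
}

withSeed <- function(seed, expr) {
    old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
    on.exit(if (is.null(old)) rm(".Random.seed", envir = globalenv())
            else assign(".Random.seed", old, envir = globalenv()))
    set.seed(seed)
    expr
}

## clustered arrangement of exactly nMeth methylated labels among n genes:
## sequential draw proportional to remaining counts, boosted when the
## previous gene has the same label. clusterFactor 0 => uniform multiset
## permutation (plain urn draw without boost).
clusteredLabels <- function(n, nMeth, clusterFactor) {
    remaining <- c(meth = nMeth, unmeth = n - nMeth)
    boost <- if (clusterFactor > 0) 1 + 100 * clusterFactor / (1 - clusterFactor) else 1
    out <- character(n)
    prev <- NA_character_
    for (i in seq_len(n)) {
        w <- as.numeric(remaining)
        if (!is.na(prev)) w[names(remaining) == prev] <- w[names(remaining) == prev] * boost
        lab <- sample(names(remaining), 1L, prob = w)
        out[i] <- lab
        remaining[lab] <- remaining[lab] - 1L
        prev <- lab
    }
    out == "meth"
}

#' Simulate a toy genome with clustered methylated genes
#'
#' Builds `nScaffolds` random-uniform nucleotide scaffolds and places
#' `nGenes` multi-exon gene models (4 exons of 300 bp, 200-bp introns) at
#' regular spacing. Exactly `round(fractionMethylated * nGenes)` genes are
#' labelled methylated, arranged along each scaffold with a tunable
#' clustering factor (0 = uniform interleaving). Optional caste/sex
#' differential regions are planted over the bodies of designated methylated
#' genes. The truth table records each gene's class and every planted
#' region.
#'
#' @param design A [SimulationDesign].
#' @return list with `genome` ([Biostrings::DNAStringSet]), `annotation`
#'   ([GeneAnnotation]) and `truth` (list: `genes` data.frame with gene_id,
#'   methylated, pi; `casteDmr`, `sexDmr` `GRanges` with piA/piB columns).
#' @export
simulateGenome <- function(design) {
    d <- design
    geneLen <- 4L * 300L + 3L * 200L
    perScaffold <- ceiling(d@nGenes / d@nScaffolds)
    gap <- floor((d@scaffoldLen - perScaffold * geneLen) / (perScaffold + 1L))
    if (gap < 2200L)  # need room for promoters and flanks between genes
        stop("scaffold capacity overflow: ", d@nGenes, " genes of ", geneLen,
             " bp do not fit ", d@nScaffolds, " x ", d@scaffoldLen, " bp")
    withSeed(streamSeed(d@seed, "genome"), {
        scafNames <- sprintf("scaffold%02d", seq_len(d@nScaffolds))
        seqs <- DNAStringSet(vapply(scafNames, function(s)
            paste(sample(c("A", "C", "G", "T"), d@scaffoldLen, replace = TRUE),
                  collapse = ""), character(1)))
        names(seqs) <- scafNames
        nMeth <- round(d@fractionMethylated * d@nGenes)
        meth <- clusteredLabels(d@nGenes, nMeth, d@clusterFactor)

        geneRows <- list(); exonRows <- list()
        gi <- 0L
        for (s in seq_len(d@nScaffolds)) {
            nHere <- min(perScaffold, d@nGenes - (s - 1L) * perScaffold)
            if (nHere <= 0) break
            ## gaps shrink between adjacent methylated genes, so clustering
            ## of labels becomes spatial clustering; total span is preserved
            methHere <- meth[(s - 1L) * perScaffold + seq_len(nHere)]
            wgt <- rep(1, nHere + 1L)
            if (nHere > 1L) {
                pairMeth <- methHere[-nHere] & methHere[-1L]
                wgt[1L + which(pairMeth)] <- max(0.35, 1 - 0.8 * d@clusterFactor)
            }
            gaps <- floor(wgt / sum(wgt) * (d@scaffoldLen - nHere * geneLen))
            starts <- cumsum(gaps + c(0L, rep(geneLen, nHere)))[seq_len(nHere)] + 1L
            for (k in seq_len(nHere)) {
                gi <- gi + 1L
                gStart <- starts[k]
                exStarts <- gStart + (0:3) * 500L
                id <- sprintf("gene%03d", gi)
                strandHere <- if (gi %% 2L == 0L) "-" else "+"
                geneRows[[gi]] <- data.frame(
                    scaffold = scafNames[s], start = gStart,
                    end = gStart + geneLen - 1L, strand = strandHere,
                    gene_id = id, stringsAsFactors = FALSE)
                exonRows[[gi]] <- data.frame(
                    scaffold = scafNames[s], start = exStarts,
                    end = exStarts + 299L, strand = strandHere,
                    gene_id = id, stringsAsFactors = FALSE)
            }
        }
        gdf <- do.call(rbind, geneRows)
        edf <- do.call(rbind, exonRows)
        geneGr <- GRanges(gdf$scaffold, IRanges(gdf$start, gdf$end),
                          strand = gdf$strand, gene_id = gdf$gene_id)
        exonGr <- GRanges(edf$scaffold, IRanges(edf$start, edf$end),
                          strand = edf$strand, gene_id = edf$gene_id)
        ann <- geneAnnotation(geneGr, exonGr, promoterLen = 1000L,
                              seqLens = genomeLengths(seqs))

        truthGenes <- data.frame(
            gene_id = gdf$gene_id, methylated = meth,
            pi = ifelse(meth, d@highMethLevel, d@lowMethLevel),
            stringsAsFactors = FALSE)

        pickDmrGenes <- function(nWanted, exclude = character()) {
            cand <- truthGenes$gene_id[truthGenes$methylated &
                                       !truthGenes$gene_id %in% exclude]
            if (nWanted > length(cand))
                stop("not enough methylated genes for the requested DMR plant")
            sample(cand, nWanted)
        }
        casteSpec <- d@casteDmrSpec
        if (!nrow(casteSpec) && d@nCasteDmrGenes > 0) {
            g <- pickDmrGenes(d@nCasteDmrGenes)
            casteSpec <- data.frame(gene = g, piA = d@highMethLevel,
                                    piB = d@highMethLevel - d@dmrDelta)
        }
        sexSpec <- d@sexDmrSpec
        if (!nrow(sexSpec) && d@nSexDmrGenes > 0) {
            g <- pickDmrGenes(d@nSexDmrGenes, exclude = casteSpec$gene)
            sexSpec <- data.frame(gene = g, piA = d@highMethLevel,
                                  piB = d@highMethLevel - d@dmrDelta)
        }
        specToGr <- function(spec) {
            if (!nrow(spec)) {
                gr <- GRanges()
                mcols(gr)$gene <- character(); mcols(gr)$piA <- numeric()
                mcols(gr)$piB <- numeric()
                return(gr)
            }
            if (any(spec$piA < 0 | spec$piA > 1 | spec$piB < 0 | spec$piB > 1))
                stop("DMR pi outside [0,1]")
            i <- match(spec$gene, gdf$gene_id)
            GRanges(gdf$scaffold[i], IRanges(gdf$start[i], gdf$end[i]),
                    gene = spec$gene, piA = spec$piA, piB = spec$piB)
        }
        list(genome = seqs, annotation = ann,
             truth = list(genes = truthGenes,
                          casteDmr = specToGr(casteSpec),
                          sexDmr = specToGr(sexSpec)))
    })
}

#' CpG dyad positions of a genome
#' @param genome `DNAStringSet`.
#' @return `GRanges` of width-1 ranges at every plus-strand C of a CG
#'   dinucleotide.
#' @export
cpgSites <- function(genome) {
    starts <- lapply(names(genome), function(s)
        BiocGenerics::start(matchPattern("CG", genome[[s]])))
    gr <- GRanges(rep(names(genome), lengths(starts)),
                  IRanges(unlist(starts), width = 1L))
    seqlengths(gr) <- genomeLengths(genome)[seqlevels(gr)]
    gr
}

#' True methylation probability per CpG site for one phenotype
#'
#' Base level is the intergenic pi; gene bodies override with the gene's
#' class pi; planted caste/sex regions override with piA (alate / female
#' side) or piB according to the phenotype.
#'
#' @param sites CpG `GRanges` from [cpgSites()].
#' @param sim result of [simulateGenome()].
#' @param design the [SimulationDesign].
#' @param caste,sex the phenotype ("alate"/"worker", "male"/"female").
#' @return numeric pi per site.
#' @export
truePi <- function(sites, sim, design, caste, sex) {
    pi <- rep(design@interGenicLevel, length(sites))
    g <- genes(sim$annotation)
    hits <- findOverlaps(sites, g)
    gpi <- sim$truth$genes$pi[match(mcols(g)$gene_id, sim$truth$genes$gene_id)]
    pi[queryHits(hits)] <- gpi[subjectHits(hits)]
    ov <- findOverlaps(sites, sim$truth$casteDmr)
    if (length(ov)) {
        v <- if (caste == "alate") mcols(sim$truth$casteDmr)$piA else
                                   mcols(sim$truth$casteDmr)$piB
        pi[queryHits(ov)] <- v[subjectHits(ov)]
    }
    ov <- findOverlaps(sites, sim$truth$sexDmr)
    if (length(ov)) {
        v <- if (sex == "female") mcols(sim$truth$sexDmr)$piA else
                                  mcols(sim$truth$sexDmr)$piB
        pi[queryHits(ov)] <- v[subjectHits(ov)]
    }
    if (any(pi < 0 | pi > 1)) stop("pi outside [0,1] after overrides")
    pi
}

#' The emulated bisulfite sample design
#' @param design A [SimulationDesign].
#' @return data.frame sample, caste, sex, replicate (4 phenotypes x nReps).
#' @export
bsSampleDesign <- function(design) {
    g <- expand.grid(replicate = seq_len(design@nReps),
                     sex = c("male", "female"),
                     caste = c("alate", "worker"),
                     stringsAsFactors = FALSE)
    data.frame(sample = sprintf("%s%s%d",
                                ifelse(g$caste == "alate", "A", "W"),
                                ifelse(g$sex == "male", "M", "F"),
                                g$replicate),
               caste = g$caste, sex = g$sex, replicate = g$replicate,
               stringsAsFactors = FALSE)
}

#' Simulate replicated methylomes plus the unmethylated spike-in
#'
#' Per CpG and sample: coverage ~ Poisson(meanCoverage); the methylated-read
#' count ~ Binomial(cov, pi + (1 - pi) * conversionError), with pi from the
#' truth table (planted regions override per phenotype). The lambda spike-in
#' control is fully unmethylated with the same conversion error. Each sample
#' has its own RNG stream seeded from the master seed and sample name.
#'
#' @param sim result of [simulateGenome()].
#' @param design the [SimulationDesign].
#' @return list with `bs` (a [BSCounts], one column per sample) and
#'   `lambda` (data.frame sample, unconverted, total).
#' @export
simulateMethylomes <- function(sim, design) {
    sites <- cpgSites(sim$genome)
    sdes <- bsSampleDesign(design)
    n <- length(sites)
    M <- U <- matrix(0L, n, nrow(sdes), dimnames = list(NULL, sdes$sample))
    lam <- data.frame(sample = sdes$sample, unconverted = 0L,
                      total = design@nControlCytosines)
    for (i in seq_len(nrow(sdes))) {
        pi <- truePi(sites, sim, design, sdes$caste[i], sdes$sex[i])
        pObs <- pi + (1 - pi) * design@conversionError
        withSeed(streamSeed(design@seed, paste0("meth_", sdes$sample[i])), {
            cov <- rpois(n, design@meanCoverage)
            m <- rbinom(n, cov, pObs)
            M[, i] <- m; U[, i] <- cov - m
            lam$unconverted[i] <- rbinom(1L, design@nControlCytosines,
                                         design@conversionError)
        })
    }
    list(bs = BSCounts(sites, M, U, sdes), lambda = lam)
}

#' The emulated transcriptome library design
#' @param design A [SimulationDesign].
#' @return data.frame library, caste, sex, replicate (4 phenotypes x
#'   nExprReps).
#' @export
exprLibraryDesign <- function(design) {
    g <- expand.grid(replicate = seq_len(design@nExprReps),
                     sex = c("male", "female"),
                     caste = c("alate", "worker"),
                     stringsAsFactors = FALSE)
    data.frame(library = sprintf("rna_%s%s%d",
                                 ifelse(g$caste == "alate", "A", "W"),
                                 ifelse(g$sex == "male", "M", "F"),
                                 g$replicate),
               caste = g$caste, sex = g$sex, replicate = g$replicate,
               stringsAsFactors = FALSE)
}

#' Simulate stranded expression counts with a small antisense fraction
#'
#' Per gene, a baseline mean is drawn log-uniformly from `exprMeanRange` and
#' multiplied by a per-morph log-normal effect; library totals are negative
#' binomial with size `exprDispersion`. Antisense reads are binomial given
#' the library total at rate `antisenseBase`, except at the designated
#' signal loci where the rate is `antisenseSignal`.
#'
#' @param sim result of [simulateGenome()].
#' @param design the [SimulationDesign].
#' @return list with `sense` and `antisense` count matrices (genes x
#'   libraries), `lengths` (summed exon bp per gene), `design` (library
#'   design), and `antisenseLoci` (character vector of planted gene ids).
#' @export
simulateExpression <- function(sim, design) {
    ids <- sim$truth$genes$gene_id
    lens <- sum(BiocGenerics::width(exonsBy(sim$annotation)))[ids]
    ldes <- exprLibraryDesign(design)
    nG <- length(ids)
    morphs <- unique(paste(ldes$caste, ldes$sex))
    withSeed(streamSeed(design@seed, "expr_base"), {
        base <- exp(runif(nG, log(design@exprMeanRange[1]),
                          log(design@exprMeanRange[2])))
        eff <- matrix(exp(rnorm(nG * length(morphs), 0, design@morphEffectSd)),
                      nG, length(morphs), dimnames = list(ids, morphs))
        antiLoci <- if (design@nAntisenseLoci > 0)
            sample(ids, design@nAntisenseLoci) else character(0)
    })
    antiRate <- ifelse(ids %in% antiLoci, design@antisenseSignal,
                       design@antisenseBase)
    sense <- anti <- matrix(0L, nG, nrow(ldes),
                            dimnames = list(ids, ldes$library))
    for (j in seq_len(nrow(ldes))) {
        mu <- base * eff[, paste(ldes$caste[j], ldes$sex[j])]
        withSeed(streamSeed(design@seed, paste0("expr_", ldes$library[j])), {
            tot <- rnbinom(nG, mu = mu, size = design@exprDispersion)
            a <- rbinom(nG, tot, antiRate)
            anti[, j] <- a; sense[, j] <- tot - a
        })
    }
    list(sense = sense, antisense = anti, lengths = lens, design = ldes,
         antisenseLoci = antiLoci)
}

#' Plant motif instances into a genome
#'
#' Writes the given sequences (e.g. a motif consensus or a miRNA target
#' complement) into the genome at the recorded 1-based start positions.
#' Overlapping plants are an error; the returned truth table lists every
#' planted instance.
#'
#' @param genome `DNAStringSet`.
#' @param plants data.frame with columns `scaffold`, `start` (1-based),
#'   `seq`.
#' @return list with `genome` (edited) and `truth` (the plants with an
#'   `end` column).
#' @export
plantMotifs <- function(genome, plants) {
    if (!nrow(plants))
        return(list(genome = genome, truth = cbind(plants, end = integer(0))))
    plants$end <- plants$start + nchar(plants$seq) - 1L
    gr <- GRanges(plants$scaffold, IRanges(plants$start, plants$end))
    if (any(GenomicRanges::countOverlaps(gr, gr) > 1L))
        stop("overlapping motif plants")
    for (s in unique(plants$scaffold)) {
        i <- plants$scaffold == s
        genome[[s]] <- replaceAt(genome[[s]],
                                 IRanges(plants$start[i], plants$end[i]),
                                 plants$seq[i])
    }
    list(genome = genome, truth = plants)
}

#' Write a simulated bundle to disk in the pipeline's input dialects
#'
#' FASTA genome, GFF3 annotation, one cytosine report per sample, the lambda
#' control table, stranded count tables and transcript lengths, plus the
#' truth tables.
#'
#' @param sim result of [simulateGenome()] (optionally with motifs planted).
#' @param meth result of [simulateMethylomes()].
#' @param expr result of [simulateExpression()] (optional).
#' @param dir output directory (created).
#' @return `dir`, invisibly.
#' @export
writeSimulatedBundle <- function(sim, meth, expr = NULL, dir) {
    dir.create(dir, recursive = TRUE, showWarnings = FALSE)
    writeXStringSet(sim$genome, file.path(dir, "genome.fa"))
    writeAnnotationGff3(sim$annotation, file.path(dir, "genes.gff3"))
    bs <- meth$bs
    sites <- rowRanges(bs)
    for (s in colnames(bs)) {
        df <- data.frame(scaffold = as.character(seqnames(sites)),
                         pos = start(sites),
                         m = assay(bs, "M")[, s], u = assay(bs, "U")[, s])
        writeCytosineReport(df, file.path(dir, paste0(s, ".cov.tsv")))
    }
    writeResultTable(meth$lambda, file.path(dir, "lambda_control.tsv"))
    writeResultTable(sim$truth$genes, file.path(dir, "truth_genes.tsv"))
    writeResultTable(grToDf(sim$truth$casteDmr),
                     file.path(dir, "truth_caste_dmr.tsv"))
    writeResultTable(grToDf(sim$truth$sexDmr),
                     file.path(dir, "truth_sex_dmr.tsv"))
    if (!is.null(expr)) {
        writeResultTable(cbind(gene = rownames(expr$sense),
                               as.data.frame(expr$sense)),
                         file.path(dir, "sense_counts.tsv"))
        writeResultTable(cbind(gene = rownames(expr$antisense),
                               as.data.frame(expr$antisense)),
                         file.path(dir, "antisense_counts.tsv"))
        writeResultTable(data.frame(gene = names(expr$lengths),
                                    length_bp = as.integer(expr$lengths)),
                         file.path(dir, "transcript_lengths.tsv"))
        writeResultTable(expr$design, file.path(dir, "rna_design.tsv"))
    }
    invisible(dir)
}

grToDf <- function(gr) {
    cbind(data.frame(scaffold = as.character(seqnames(gr)),
                     start = start(gr), end = end(gr)),
          as.data.frame(mcols(gr)))
}

#' Write a GeneAnnotation as GFF3 (gene/mRNA/exon features)
#' @param annotation A [GeneAnnotation].
#' @param path output file.
#' @export
writeAnnotationGff3 <- function(annotation, path) {
    g <- genes(annotation)
    lines <- "##gff-version 3"
    for (i in seq_along(g)) {
        id <- mcols(g)$gene_id[i]
        sc <- as.character(seqnames(g))[i]
        st <- as.character(strand(g))[i]
        lines <- c(lines,
            sprintf("%s\tsim\tgene\t%d\t%d\t.\t%s\t.\tID=%s",
                    sc, start(g)[i], end(g)[i], st, id),
            sprintf("%s\tsim\tmRNA\t%d\t%d\t.\t%s\t.\tID=%s.t1;Parent=%s",
                    sc, start(g)[i], end(g)[i], st, id, id))
        ex <- exonsBy(annotation)[[id]]
        lines <- c(lines, sprintf(
            "%s\tsim\texon\t%d\t%d\t.\t%s\t.\tID=%s.e%d;Parent=%s.t1",
            sc, start(ex), end(ex), st, id, seq_along(ex), id))
    }
    writeLines(lines, path)
    invisible(path)
}
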