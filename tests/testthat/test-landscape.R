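## helper: uniform-fraction BSCounts over given sites
uniformBS <- function(sites, m = 5L, u = 5L) {
    n <- length(sites)
    tinyBS(matrix(rep(m, n), ncol = 1), matrix(rep(u, n), ncol = 1),
           pos = start(sites))["dummy" > "", ]  # placeholder never used
}

test_that("metagene profile is flat for a uniform methylome", {
    ann <- smallSim$sim$annotation
    sites <- cpgSites(smallSim$sim$genome)
    n <- length(sites)
    des <- designCasteSex()[1, , drop = FALSE]
    bs <- BSCounts(sites, matrix(rep(5L, n), ncol = 1),
                   matrix(rep(5L, n), ncol = 1), des)
    mp <- metageneProfile(bs, ann)
    expect_true(all(abs(mp$mean - 0.5) < 1e-12))
    expect_equal(nrow(mp), 80L)
    expect_error(metageneProfile(bs, ann, nBins = 0L), "nBins")
})

test_that("minus-strand genes mirror plus-strand genes in the profile", {
    ## one plus and one minus gene with the same 5'->3' gradient
    genome <- DNAStringSet(c(s1 = paste(rep("ACGT", 5000), collapse = "")))
    g <- GRanges("s1", IRanges(c(2001, 12001), width = 2000),
                 strand = c("+", "-"), gene_id = c("gp", "gm"))
    ex <- GRanges("s1", IRanges(c(2001, 3101, 12001, 13101), width = 900),
                  strand = rep(c("+", "-"), each = 2),
                  gene_id = rep(c("gp", "gm"), each = 2))
    ann <- geneAnnotation(g, ex, seqLens = genomeLengths(genome))
    sites <- cpgSites(genome)
    pos <- start(sites)
    ## fraction increases 5'->3': for gp along +, for gm along -
    frac <- rep(0.5, length(sites))
    inP <- pos >= 2001 & pos <= 4000
    frac[inP] <- (pos[inP] - 2001) / 1999
    inM <- pos >= 12001 & pos <= 14000
    frac[inM] <- (14000 - pos[inM]) / 1999
    M <- matrix(as.integer(round(frac * 100)), ncol = 1)
    U <- matrix(100L - M[, 1], ncol = 1)
    bs <- BSCounts(sites, M, U, designCasteSex()[1, , drop = FALSE])
    mp <- metageneProfile(bs, ann, multiexonOnly = TRUE)
    ## recompute per gene by restricting the annotation
    annP <- geneAnnotation(g[1], ex[1:2], seqLens = genomeLengths(genome))
    annM <- geneAnnotation(g[2], ex[3:4], seqLens = genomeLengths(genome))
    mpP <- metageneProfile(bs, annP)
    mpM <- metageneProfile(bs, annM)
    body <- mpP$region == "body"
    expect_equal(mpP$mean[body], mpM$mean[body], tolerance = 0.02)
    ## and the gradient is monotone increasing across body bins
    expect_gt(suppressWarnings(
        cor(seq_len(sum(body)), mp$mean[body], method = "spearman")), 0.95)
})

test_that("junction profile recovers a planted exon-intron step", {
    d <- simulationDesign(seed = 21L, nGenes = 8L, nScaffolds = 1L,
                          scaffoldLen = 50000L, meanCoverage = 40)
    sim <- simulateGenome(d)
    sites <- cpgSites(sim$genome)
    exAll <- unlist(exonsBy(sim$annotation))
    inAll <- unlist(intronsBy(sim$annotation))
    pi <- rep(0.1, length(sites))
    pi[IRanges::overlapsAny(sites, inAll)] <- 0.6
    pi[IRanges::overlapsAny(sites, exAll)] <- 0.8
    set.seed(1)
    cov <- rpois(length(sites), 40) + 1L
    m <- rbinom(length(sites), cov, pi)
    bs <- BSCounts(sites, matrix(as.integer(m), ncol = 1),
                   matrix(as.integer(cov - m), ncol = 1),
                   designCasteSex()[1, , drop = FALSE])
    called <- callMethylation(bs, err = 1e-6)
    jp <- junctionProfile(called, sim$annotation, spanBp = 150L)
    jAll <- jp[jp$set == "all", ]
    exSide <- mean(jAll$mean[jAll$offset < 0])
    inSide <- mean(jAll$mean[jAll$offset > 0])
    expect_equal(exSide - inSide, 0.2, tolerance = 0.05)
    ## single-exon genes contribute no junctions
    g1 <- genes(sim$annotation)[1]
    ex1 <- exonsBy(sim$annotation)[[1]][1]
    mcols(ex1)$gene_id <- mcols(g1)$gene_id
    annSingle <- geneAnnotation(g1, ex1)
    jp1 <- junctionProfile(called, annSingle)
    expect_equal(nrow(jp1), 0L)
})

test_that("CpG o/e follows the dinucleotide definition", {
    expect_equal(cpgObsExp("CGCG"), 2)
    expect_true(is.na(cpgObsExp("AATT")))
    expect_equal(cpgObsExp("ACGT"), 4)
    expect_equal(cpgObsExp(c("CGCG", "ACGT")), c(2, 4))
})

test_that("CpG o/e decays under methylation-driven CpG loss", {
    ## forward mutation-decay simulation: CpG -> TpG at rate prop. to pi
    set.seed(9)
    mkSeq <- function() paste(sample(c("A", "C", "G", "T"), 2000,
                                     replace = TRUE), collapse = "")
    n <- 300
    pis <- runif(n)
    oes <- vapply(seq_len(n), function(i) {
        s <- strsplit(mkSeq(), "")[[1]]
        cg <- which(s[-length(s)] == "C" & s[-1] == "G")
        lost <- cg[runif(length(cg)) < 0.8 * pis[i]]
        s[lost] <- "T"
        cpgObsExp(paste(s, collapse = ""))
    }, numeric(1))
    expect_lt(suppressWarnings(cor(pis, oes, method = "spearman")), -0.5)
})

test_that("methylation deciles are equal-size, stable and guarded", {
    fr <- c(runif(20), rep(0, 5))
    meth <- c(rep(TRUE, 20), rep(FALSE, 5))
    ids <- sprintf("g%02d", seq_along(fr))
    dec <- methylationDeciles(fr, meth, ids)
    expect_equal(sum(dec == "Un"), 5L)
    tab <- table(dec[dec != "Un"])
    expect_true(all(tab == 2L))
    ## ties keep stable gene-id order and equal sizes
    dec2 <- methylationDeciles(rep(0.5, 20), rep(TRUE, 20), sprintf("g%02d", 1:20))
    expect_true(all(table(dec2) == 2L))
    expect_equal(dec2[1], "1"); expect_equal(dec2[20], "10")
    expect_error(methylationDeciles(runif(5), rep(TRUE, 5), letters[1:5]),
                 "at least 10")
    ## a ranked set of 10,240 genes puts 3,072 in the top 3 deciles
    fr3 <- runif(10240)
    d3 <- methylationDeciles(fr3, rep(TRUE, 10240), sprintf("g%05d", 1:10240))
    expect_equal(sum(d3 %in% c("8", "9", "10")), 3072L)
})

test_that("nearest gene distance handles gaps, overlaps and lone genes", {
    g <- GRanges(c("s1", "s1", "s1", "s2"),
                 IRanges(c(1, 151, 140, 5), c(100, 200, 160, 50)),
                 strand = "+",
                 gene_id = c("a", "b", "c", "lone"))
    ex <- g; mcols(ex)$gene_id <- mcols(g)$gene_id
    ann <- geneAnnotation(g, ex)
    d <- nearestGeneDistance(ann)
    expect_equal(unname(d["a"]), 39)   # gap to c at 140
    expect_equal(unname(d["b"]), 0)    # overlaps c
    expect_equal(unname(d["c"]), 0)
    expect_true(is.na(d["lone"]))
})

test_that("clustered methylated genes are closer than unmethylated ones", {
    d <- simulationDesign(seed = 22L, nGenes = 40L, nScaffolds = 2L,
                          scaffoldLen = 100000L, clusterFactor = 0.85)
    sim <- simulateGenome(d)
    nd <- nearestGeneDistance(sim$annotation)
    tm <- sim$truth$genes$methylated
    expect_lt(median(nd[tm]), median(nd[!tm]))
    wt <- suppressWarnings(wilcox.test(nd[tm], nd[!tm]))
    expect_lt(wt$p.value, 0.05)
})

test_that("promoter-island profile dips in methylation and peaks in CpG o/e", {
    ## plant a CpG-dense unmethylated promoter inside a methylated block
    set.seed(5)
    bases <- sample(c("A", "C", "G", "T"), 20000, replace = TRUE)
    prStart <- 7001L; prEnd <- 8000L
    bases[seq(prStart, prEnd - 1, by = 4)] <- "C"
    bases[seq(prStart + 1, prEnd, by = 4)] <- "G"
    genome <- DNAStringSet(c(s1 = paste(bases, collapse = "")))
    g <- GRanges("s1", IRanges(8001, 14000), strand = "+", gene_id = "g1")
    ex <- GRanges("s1", IRanges(c(8001, 10001), width = 1500), strand = "+",
                  gene_id = "g1")
    ann <- geneAnnotation(g, ex, promoterLen = 1000L,
                          seqLens = genomeLengths(genome))
    sites <- cpgSites(genome)
    inProm <- IRanges::overlapsAny(sites, promoterRanges(ann))
    m <- ifelse(inProm, 0L, 18L)
    bs <- BSCounts(sites, matrix(as.integer(m), ncol = 1),
                   matrix(as.integer(20L - m), ncol = 1),
                   designCasteSex()[1, , drop = FALSE])
    called <- callMethylation(bs, err = 1e-4)
    prof <- promoterIslandProfile(called, ann, genome, spanBp = 2000L)
    inside <- prof$offsetBp >= 0 & prof$offsetBp < 1000
    outside <- prof$offsetBp < -500 | prof$offsetBp > 1500
    expect_lt(mean(prof$fraction[inside], na.rm = TRUE),
              mean(prof$fraction[outside], na.rm = TRUE) - 0.5)
    expect_gt(mean(prof$cpgOE[inside], na.rm = TRUE),
              mean(prof$cpgOE[outside], na.rm = TRUE))
    ## uniform methylome: no qualifying promoter, warning + empty profile
    bsU <- BSCounts(sites, matrix(rep(10L, length(sites)), ncol = 1),
                    matrix(rep(10L, length(sites)), ncol = 1),
                    designCasteSex()[1, , drop = FALSE])
    calledU <- callMethylation(bsU, err = 1e-4)
    expect_warning(pU <- promoterIslandProfile(calledU, ann, genome),
                   "no gene")
    expect_equal(nrow(pU), 0L)
})

test_that("repeat-context methylation detects planted hypomethylation", {
    d <- simulationDesign(seed = 23L, nGenes = 10L, nScaffolds = 1L,
                          scaffoldLen = 60000L, meanCoverage = 30)
    sim <- simulateGenome(d)
    ex <- unlist(exonsBy(sim$annotation))
    methGeneIds <- sim$truth$genes$gene_id[sim$truth$genes$methylated]
    exM <- ex[names(ex) %in% methGeneIds]
    ## 50 pseudo-repeats inside methylated exons, hypomethylated pi 0.4 vs 0.8
    set.seed(2)
    picks <- sample(seq_along(exM), 50, replace = TRUE)
    reps <- GRanges(seqnames(exM)[picks],
                    IRanges(start(exM)[picks] + 10,
                            width = pmin(120, width(exM)[picks] - 20)))
    reps <- reduce(reps)
    mcols(reps)$class <- "sim"
    sites <- cpgSites(sim$genome)
    pi <- rep(0.05, length(sites))
    pi[IRanges::overlapsAny(sites, genes(sim$annotation)[
        mcols(genes(sim$annotation))$gene_id %in% methGeneIds])] <- 0.8
    pi[IRanges::overlapsAny(sites, reps)] <- 0.4
    cov <- rpois(length(sites), 30) + 1L
    m <- rbinom(length(sites), cov, pi)
    bs <- BSCounts(sites, matrix(as.integer(m), ncol = 1),
                   matrix(as.integer(cov - m), ncol = 1),
                   designCasteSex()[1, , drop = FALSE])
    ann <- geneAnnotation(genes(sim$annotation),
                          unlist(exonsBy(sim$annotation)), repeats = reps,
                          seqLens = genomeLengths(sim$genome))
    rcm <- repeatContextMethylation(bs, ann)
    exRow <- rcm[rcm$class == "exon", ]
    expect_gt(nrow(exRow), 0)
    expect_lt(exRow$meanRepeat, exRow$meanContext)
    expect_lt(exRow$pRankSum, 0.01)
    ## repeats with <3 covered CpGs are excluded
    tinyRep <- GRanges("scaffold01", IRanges(1, 10), class = "tiny")
    annT <- geneAnnotation(genes(sim$annotation),
                           unlist(exonsBy(sim$annotation)), repeats = tinyRep,
                           seqLens = genomeLengths(sim$genome))
    expect_equal(nrow(repeatContextMethylation(bs, annT)), 0L)
})

test_that("ortholog methylation classes partition complete triplets", {
    orth <- data.frame(ortholog = c("o1", "o2", "o3", "o4"),
                       Znev = c("z1", "z2", "z3", "z4"),
                       Cflo = c("c1", "c2", "c3", "c4"),
                       Amel = c("a1", "a2", "a3", "a4"))
    status <- list(
        Znev = c(z1 = "methylated", z2 = "methylated", z3 = "unmethylated",
                 z4 = "methylated"),
        Cflo = c(c1 = "unmethylated", c2 = "methylated", c3 = "unmethylated"),
        Amel = c(a1 = "unmethylated", a2 = "methylated", a3 = "unmethylated",
                 a4 = "methylated"))
    res <- orthologMethylationClasses(orth, status,
                                      fractions = c(z1 = 0.9, z2 = 0.8,
                                                    z3 = 0.1, z4 = 0.7))
    expect_equal(res$nDropped, 1L)  # o4 lacks Cflo status
    expect_equal(sum(res$classes$count), 3L)
    expect_equal(res$perOrtholog$class[res$perOrtholog$ortholog == "o1"],
                 "Znev")
    expect_equal(res$perOrtholog$class[res$perOrtholog$ortholog == "o2"],
                 "all")
    expect_equal(res$perOrtholog$class[res$perOrtholog$ortholog == "o3"],
                 "none")
    expect_error(orthologMethylationClasses(rbind(orth, orth[1, ]), status),
                 "duplicate")
})
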