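#' @importFrom yaml read_yaml write_yaml
NULL

#' Run the methylome analysis pipeline from a configuration
#'
#' Chains the pipeline stages over a configuration list or YAML file:
#' `simulate` (synthetic bundle generation), `call` (conversion-calibrated
#' methylation calls), `diffmeth` (window tests, DMR merging, gene
#' assignment for the caste and sex comparisons), `permtest`
#' (replicate-shuffling false-discovery analysis), `expression` (FPKM,
#' summaries, antisense flags) and `motifs` (DMC-centered motif
#' enrichment). Stage outputs are TSV tables with a `#` header line in
#' deterministic row order; a machine-readable run log records the
#' thresholds and seed. Re-running an identical configuration reproduces
#' byte-identical outputs.
#'
#' @param config list or path to a YAML file. Recognised keys: `seed`
#'   (mandatory when any stochastic stage runs), `output_dir`, `stages`
#'   (default all applicable), `simulate` (overrides for
#'   [simulationDesign()]), `inputs` (paths: `genome`, `annotation`,
#'   `cytosine_reports` named by sample, `lambda`, `motifs_meme` or
#'   `mirna_fasta`), `design` (sample design rows when loading external
#'   reports), `thresholds` (`alpha_site`, `min_cov_site`, `alpha_dmr`,
#'   `min_diff`, `n_perms`).
#' @param outDir output directory; defaults to `config$output_dir`.
#' @return invisibly, a list of in-memory stage results.
#' @export
runPipeline <- function(config, outDir = NULL) {
    cfg <- if (is.character(config)) read_yaml(config) else config
    if (is.null(outDir)) outDir <- cfg$output_dir
    if (is.null(outDir)) stop("output_dir is required")
    dir.create(outDir, recursive = TRUE, showWarnings = FALSE)
    th <- modifyList(list(alpha_site = 0.01, min_cov_site = 4L,
                          alpha_dmr = 0.05, min_diff = 0.15,
                          n_perms = 20L, promoter_len = 1000L),
                     if (is.null(cfg$thresholds)) list() else cfg$thresholds)
    stages <- cfg$stages
    if (is.null(stages)) {
        stages <- c(if (!is.null(cfg$simulate)) "simulate",
                    "call", "diffmeth", "permtest",
                    if (!is.null(cfg$simulate) ||
                        !is.null(cfg$inputs$sense_counts)) "expression",
                    "motifs")
    }
    stochastic <- intersect(stages, c("simulate", "permtest"))
    if (length(stochastic) && is.null(cfg$seed))
        stop("config must provide a seed for stochastic stage(s): ",
             paste(stochastic, collapse = ", "))
    results <- list()

    genome <- NULL; annotation <- NULL; bs <- NULL; lambda <- NULL
    expr <- NULL; motifs <- NULL; sim <- NULL

    if ("simulate" %in% stages) {
        sd <- do.call(simulationDesign,
                      c(list(seed = cfg$seed),
                        if (is.null(cfg$simulate)) list() else cfg$simulate))
        sim <- simulateGenome(sd)
        meth <- simulateMethylomes(sim, sd)
        exprSim <- simulateExpression(sim, sd)
        writeSimulatedBundle(sim, meth, exprSim, file.path(outDir, "sim"))
        genome <- sim$genome; annotation <- sim$annotation
        bs <- meth$bs
        lambda <- meth$lambda
        expr <- exprSim
        results$sim <- sim
    } else if (!is.null(cfg$inputs)) {
        inp <- cfg$inputs
        if (!is.null(inp$cytosine_reports)) {
            des <- do.call(rbind, lapply(cfg$design, as.data.frame))
            miss <- setdiff(names(inp$cytosine_reports), des$sample)
            if (length(miss))
                stop("no design entry for sample file(s): ",
                     paste(miss, collapse = ", "))
            genome <- readGenome(inp$genome)
            annotation <- readAnnotation(inp$annotation,
                                         promoterLen = th$promoter_len,
                                         seqLens = genomeLengths(genome))
            tabs <- lapply(inp$cytosine_reports, readCytosineReport)
            bs <- assembleBSCounts(tabs, des)
            if (!is.null(inp$lambda)) lambda <- readResultTable(inp$lambda)
        }
    }
    if (is.null(bs)) stop("no bisulfite counts available: provide inputs or a simulate block")

    ## conversion calibration + calling
    err <- if (!is.null(lambda))
        estimateConversionError(sum(lambda$unconverted), sum(lambda$total))$rate
    else th$conversion_error %||% stop("no lambda control and no conversion_error threshold")
    called <- callMethylation(bs, err, alpha = th$alpha_site,
                              minCov = th$min_cov_site)
    results$called <- called
    if ("call" %in% stages) {
        sites <- rowRanges(called)
        pc <- pooledConsensus(called, annotation)
        siteTab <- data.frame(
            scaffold = as.character(seqnames(sites)), pos = start(sites),
            M = rowSums(assay(called, "M")), U = rowSums(assay(called, "U")),
            fraction = round(pooledSiteFractions(called), 6),
            pooledStatus = assay(pc$pooled, "status")[, 1],
            nSamplesMethylated = pc$siteSupport)
        writeResultTable(siteTab[order(siteTab$scaffold, siteTab$pos), ],
                         file.path(outDir, "sites_pooled.tsv"))
        if (!is.null(pc$geneStatus))
            writeResultTable(pc$geneStatus, file.path(outDir, "gene_status.tsv"))
        if (!is.null(annotation)) {
            fm <- featureMethylation(called, exonsBy(annotation))
            writeResultTable(cbind(fm[1], round(fm[-1], 6)),
                             file.path(outDir, "gene_methylation.tsv"))
        }
        results$pooled <- pc
    }

    windows <- NULL; dmRes <- list(); dmrs <- list()
    if (any(c("diffmeth", "permtest", "motifs") %in% stages)) {
        windows <- tileWindows(genome)
    }
    if ("diffmeth" %in% stages) {
        for (cmp in c("caste", "sex")) {
            res <- testWindows(called, windows, cmp,
                               alpha = th$alpha_dmr, minDiff = th$min_diff)
            dmRes[[cmp]] <- res
            ma <- mergeAndAssign(res, annotation)
            dmrs[[cmp]] <- ma
            tab <- cbind(data.frame(scaffold = as.character(seqnames(res)),
                                    start = start(res), end = end(res)),
                         as.data.frame(mcols(res)))
            num <- vapply(tab, is.numeric, logical(1))
            tab[num] <- lapply(tab[num], function(x) round(x, 8))
            writeResultTable(tab[tab$tested, ],
                             file.path(outDir, paste0("dm_windows_", cmp, ".tsv")))
            if (length(ma$dmrs)) {
                mcols(ma$dmrs)$name <- paste0(cmp, "_dmr_",
                                              seq_along(ma$dmrs))
                writeBed(ma$dmrs, file.path(outDir, paste0("dmrs_", cmp, ".bed")))
                writeResultTable(grToDf(ma$dmrs),
                                 file.path(outDir, paste0("dmrs_", cmp, ".tsv")))
            }
            writeResultTable(ma$dmgs, file.path(outDir, paste0("dmgs_", cmp, ".tsv")))
        }
        results$dm <- dmRes; results$dmrs <- dmrs
    }
    if ("permtest" %in% stages) {
        perm <- list()
        for (cmp in c("caste", "sex")) {
            pr <- permutedDmrCounts(called, windows, cmp,
                                    nPerms = th$n_perms,
                                    seed = streamSeed(cfg$seed, paste0("perm_", cmp)),
                                    test = "ttest",
                                    alpha = th$alpha_dmr, minDiff = th$min_diff)
            perm[[cmp]] <- pr
            writeResultTable(data.frame(iteration = seq_along(pr$null),
                                        nullCount = pr$null),
                             file.path(outDir, paste0("perm_null_", cmp, ".tsv")))
            writeResultTable(pr$summary,
                             file.path(outDir, paste0("perm_summary_", cmp, ".tsv")))
        }
        results$perm <- perm
    }
    if ("expression" %in% stages && !is.null(expr)) {
        fp <- fpkm(expr$sense, expr$lengths)
        summ <- expressionSummaries(fp, expr$design)
        af <- antisenseFlags(expr$sense, expr$antisense, expr$design)
        num <- vapply(summ, is.numeric, logical(1))
        summ[num] <- lapply(summ[num], function(x) round(x, 6))
        writeResultTable(summ, file.path(outDir, "expression_summary.tsv"))
        pg <- af$perGene
        pg$meanAntisenseProp <- round(pg$meanAntisenseProp, 6)
        writeResultTable(pg, file.path(outDir, "antisense.tsv"))
        results$expression <- list(fpkm = fp, summaries = summ, antisense = af)
    }
    if ("motifs" %in% stages && "diffmeth" %in% stages) {
        motifSet <- NULL
        if (!is.null(cfg$inputs$motifs_meme))
            motifSet <- readMemeMotifs(cfg$inputs$motifs_meme)
        else if (!is.null(cfg$inputs$mirna_fasta))
            motifSet <- readMirnaMotifs(cfg$inputs$mirna_fasta)
        if (!is.null(motifSet)) {
            me <- dmcMotifEnrichment(called, windows, dmRes$caste, genome,
                                     motifSet)
            if (!is.null(me)) {
                num <- vapply(me$enrichment, is.numeric, logical(1))
                tab <- me$enrichment
                tab[num] <- lapply(tab[num], function(x) signif(x, 8))
                writeResultTable(tab, file.path(outDir, "motif_enrichment.tsv"))
                results$motifs <- me
            }
        }
    }

    write_yaml(list(seed = cfg$seed, thresholds = th,
                    stages = as.list(stages),
                    conversion_error = err),
               file.path(outDir, "run_log.yaml"))
    invisible(results)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' DMC-centered motif enrichment from window results
#'
#' Derives confident DMCs by site-level testing of CpGs inside significant
#' windows (q < 0.01, |diff| > 0.20), takes methylated (fraction > 0.30)
#' non-significant sites as control anchors, builds 150-bp sequence sets
#' and runs [motifEnrichment()].
#'
#' @param called A [BSCounts] after [callMethylation()].
#' @param windows window `GRanges`.
#' @param dmWindows result of [testWindows()] for the comparison.
#' @param genome `DNAStringSet`.
#' @param motifs named list of [MotifModel]s.
#' @param width,maxDist sequence-set geometry (defaults 150, 1500).
#' @return list with `dmcs`, `sets`, `enrichment`, or NULL when no DMC.
#' @export
dmcMotifEnrichment <- function(called, windows, dmWindows, genome, motifs,
                               width = 150L, maxDist = 1500L) {
    sigWin <- dmWindows[mcols(dmWindows)$significant %in% TRUE]
    if (!length(sigWin)) return(NULL)
    sites <- rowRanges(called)
    inSig <- IRanges::overlapsAny(sites, sigWin)
    if (!any(inSig)) return(NULL)
    comparison <- metadata(dmWindows)$comparison
    dmcRes <- testWindows(called, granges(sites[inSig]), comparison,
                          alpha = 0.01, minDiff = 0.20)
    dmcs <- granges(dmcRes[mcols(dmcRes)$significant %in% TRUE])
    if (!length(dmcs)) return(NULL)
    frac <- pooledSiteFractions(called)
    nonDmc <- granges(sites[!inSig & !is.na(frac) & frac > 0.30])
    sets <- buildSequenceSets(dmcs, nonDmc, genome, width = width,
                              maxDist = maxDist)
    if (!length(sets$control$seqs) || !length(sets$test$seqs)) return(NULL)
    enr <- motifEnrichment(motifs, sets$test$seqs, sets$control$seqs)
    list(dmcs = dmcs, sets = sets, enrichment = enr)
}
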