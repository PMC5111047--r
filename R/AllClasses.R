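#' @import methods
#' @importFrom S4Vectors DataFrame metadata metadata<- mcols mcols<- queryHits subjectHits
#' @importFrom IRanges IRanges
#' @importFrom GenomicRanges GRanges granges seqnames start end width strand findOverlaps
#' @importFrom SummarizedExperiment SummarizedExperiment assay assays assayNames rowRanges colData assay<-
#' @importFrom BiocGenerics strand<-
NULL

#' BSCounts: per-CpG methylated/unmethylated read counts across samples
#'
#' A [SummarizedExperiment::RangedSummarizedExperiment] subclass holding one
#' row per CpG dyad (keyed by the 0-based plus-strand C position, stored
#' 1-based in the `GRanges` row ranges) and one column per bisulfite library.
#' The two core assays are `"M"` (methylated, i.e. unconverted, reads) and
#' `"U"` (converted reads); downstream callers add `"p"`, `"q"`, `"status"`
#' and `"fraction"` assays. `colData` carries the sample design with columns
#' `caste` ("alate"/"worker"), `sex` ("male"/"female") and `replicate`.
#'
#' @aliases BSCounts-class
#' @exportClass BSCounts
setClass("BSCounts", contains = "RangedSummarizedExperiment")

setValidity("BSCounts", function(object) {
    msg <- NULL
    an <- assayNames(object)
    if (!all(c("M", "U") %in% an))
        msg <- c(msg, "assays 'M' and 'U' are required")
    else {
        M <- assay(object, "M"); U <- assay(object, "U")
        if (any(M < 0, na.rm = TRUE) || any(U < 0, na.rm = TRUE))
            msg <- c(msg, "read counts must be non-negative")
    }
    cd <- colData(object)
    need <- c("caste", "sex", "replicate")
    miss <- setdiff(need, colnames(cd))
    if (length(miss))
        msg <- c(msg, paste0("colData lacks column(s): ",
                             paste(miss, collapse = ", ")))
    if (anyDuplicated(colnames(object)))
        msg <- c(msg, "sample names must be unique")
    if (is.null(msg)) TRUE else msg
})

#' Construct a BSCounts object
#'
#' @param sites `GRanges` of CpG dyad positions (width-1 ranges at the
#'   plus-strand C; 1-based as usual for `GRanges`).
#' @param M,U integer matrices (sites x samples) of methylated (unconverted)
#'   and unmethylated (converted) read counts.
#' @param design `data.frame` with one row per sample and columns
#'   `sample`, `caste`, `sex`, `replicate`.
#' @return A [BSCounts] object.
#' @examples
#' gr <- GenomicRanges::GRanges("s1", IRanges::IRanges(c(10, 30), width = 1))
#' des <- data.frame(sample = c("a", "b"),
#'                   caste = c("alate", "worker"),
#'                   sex = c("male", "female"), replicate = c(1L, 1L))
#' bs <- BSCounts(gr, M = matrix(0:3, 2), U = matrix(4:7, 2), design = des)
#' @export
BSCounts <- function(sites, M, U, design) {
    M <- as.matrix(M); U <- as.matrix(U)
    storage.mode(M) <- "integer"; storage.mode(U) <- "integer"
    if (!"sample" %in% colnames(design))
        stop("design must have a 'sample' column")
    cd <- DataFrame(design[setdiff(colnames(design), "sample")],
                    row.names = as.character(design$sample))
    colnames(M) <- colnames(U) <- rownames(cd)
    se <- SummarizedExperiment(assays = list(M = M, U = U),
                               rowRanges = sites, colData = cd)
    new("BSCounts", se)
}

#' @describeIn BSCounts total read coverage (M + U) per site and sample
#' @param x,object A `BSCounts` object.
#' @export
methCoverage <- function(x) assay(x, "M") + assay(x, "U")

#' @describeIn BSCounts per-site per-sample methylated fraction M/(M+U)
#'   (`NA` where coverage is zero)
#' @export
methFraction <- function(x) {
    cov <- methCoverage(x)
    f <- assay(x, "M") / cov
    f[cov == 0] <- NA_real_
    f
}

#' @describeIn BSCounts the sample design as a data.frame (with a
#'   `sample` column)
#' @export
sampleDesign <- function(x) {
    cd <- as.data.frame(colData(x))
    cbind(sample = colnames(x), cd)
}

setMethod("show", "BSCounts", function(object) {
    cat(class(object), "with", nrow(object), "CpG sites and",
        ncol(object), "samples\n")
    cat("assays:", paste(assayNames(object), collapse = ", "), "\n")
    cd <- colData(object)
    cat("design:", paste(sprintf("%s(%s/%s)", colnames(object),
        substr(cd$caste, 1, 1), substr(cd$sex, 1, 1)), collapse = " "), "\n")
})

#' MotifModel: a PWM or mature-miRNA motif
#'
#' Holds a position probability matrix (rows A, C, G, T summing to 1 per
#' column) together with the background letter frequencies used when the
#' motif is scored as a log2 likelihood ratio.
#'
#' @slot id motif identifier.
#' @slot kind `"pwm"` or `"mirna"`.
#' @slot matrix 4 x w probability matrix with rownames `c("A","C","G","T")`.
#' @slot background named length-4 numeric, background letter frequencies.
#' @aliases MotifModel-class
#' @exportClass MotifModel
setClass("MotifModel", representation(
    id = "character", kind = "character",
    matrix = "matrix", background = "numeric"))

setValidity("MotifModel", function(object) {
    msg <- NULL
    m <- object@matrix
    if (!identical(rownames(m), c("A", "C", "G", "T")))
        msg <- c(msg, "matrix rownames must be A,C,G,T")
    else if (any(abs(colSums(m) - 1) > 1e-9))
        msg <- c(msg, "matrix columns must sum to 1 (tolerance 1e-9)")
    if (!object@kind %in% c("pwm", "mirna"))
        msg <- c(msg, "kind must be 'pwm' or 'mirna'")
    if (abs(sum(object@background) - 1) > 1e-6)
        msg <- c(msg, "background must sum to 1")
    if (is.null(msg)) TRUE else msg
})

#' Construct a MotifModel
#' @param id motif identifier.
#' @param matrix 4 x w probability matrix, rownames A,C,G,T.
#' @param kind `"pwm"` or `"mirna"`.
#' @param background background letter frequencies (default uniform).
#' @return A [MotifModel].
#' @export
MotifModel <- function(id, matrix, kind = "pwm",
                       background = c(A = .25, C = .25, G = .25, T = .25)) {
    new("MotifModel", id = id, kind = kind, matrix = matrix,
        background = background[c("A", "C", "G", "T")])
}

#' @describeIn MotifModel motif length in bp
#' @param x A `MotifModel`.
#' @export
motifWidth <- function(x) ncol(x@matrix)

setMethod("show", "MotifModel", function(object) {
    cat("MotifModel", object@id, sprintf("(%s, %d bp)\n",
        object@kind, motifWidth(object)))
    cat("consensus:", paste(rownames(object@matrix)[
        apply(object@matrix, 2, which.max)], collapse = ""), "\n")
})

#' SimulationDesign: parameters of the synthetic study generator
#'
#' Encodes the study layout the generator emulates: 4 phenotypes
#' (alate/worker x male/female), 2 bisulfite replicates and 3 transcriptome
#' replicates per phenotype, bimodal gene-body methylation with genomic
#' clustering of methylated genes, a small bisulfite conversion error, and
#' optional planted caste/sex differential regions, antisense loci and motif
#' instances.
#'
#' @slot nScaffolds,scaffoldLen genome layout.
#' @slot nGenes,fractionMethylated,clusterFactor gene placement; the cluster
#'   factor in `[0,1)` controls how strongly methylated genes clump (0 =
#'   uniform interleaving).
#' @slot highMethLevel,lowMethLevel true methylation probability of CpGs in
#'   methylated / unmethylated gene bodies.
#' @slot interGenicLevel true pi outside genes.
#' @slot conversionError bisulfite conversion failure rate.
#' @slot meanCoverage Poisson mean per-CpG read depth.
#' @slot nReps bisulfite replicates per phenotype (2 in the emulated design).
#' @slot nExprReps transcriptome replicates per phenotype.
#' @slot casteDmrSpec,sexDmrSpec data.frames (gene, piA, piB) naming genes
#'   whose bodies get phenotype-dependent pi (piA = alate or female side).
#' @slot nCasteDmrGenes,nSexDmrGenes,dmrDelta convenience: number of planted
#'   differential genes and the pi contrast used when the specs are empty.
#' @slot antisenseBase,antisenseSignal,nAntisenseLoci antisense read
#'   proportion at background loci, at designated signal loci, and how many
#'   signal loci to plant.
#' @slot exprMeanRange,exprDispersion,morphEffectSd negative-binomial
#'   expression model: range of baseline means, NB size parameter, and the
#'   log-normal sd of per-morph effects.
#' @slot nControlCytosines size of the unmethylated spike-in control.
#' @slot seed master seed (mandatory).
#' @aliases SimulationDesign-class
#' @exportClass SimulationDesign
setClass("SimulationDesign", representation(
    nScaffolds = "integer", scaffoldLen = "integer",
    nGenes = "integer", fractionMethylated = "numeric",
    clusterFactor = "numeric",
    highMethLevel = "numeric", lowMethLevel = "numeric",
    interGenicLevel = "numeric",
    conversionError = "numeric", meanCoverage = "numeric",
    nReps = "integer", nExprReps = "integer",
    casteDmrSpec = "data.frame", sexDmrSpec = "data.frame",
    nCasteDmrGenes = "integer", nSexDmrGenes = "integer",
    dmrDelta = "numeric",
    antisenseBase = "numeric", antisenseSignal = "numeric",
    nAntisenseLoci = "integer",
    exprMeanRange = "numeric", exprDispersion = "numeric",
    morphEffectSd = "numeric",
    nControlCytosines = "integer",
    seed = "integer"))

setValidity("SimulationDesign", function(object) {
    msg <- NULL
    probs <- c(object@fractionMethylated, object@highMethLevel,
               object@lowMethLevel, object@interGenicLevel,
               object@conversionError, object@antisenseBase,
               object@antisenseSignal)
    if (any(probs < 0 | probs > 1))
        msg <- c(msg, "all probabilities must lie in [0,1]")
    if (object@meanCoverage <= 0)
        msg <- c(msg, "meanCoverage must be positive")
    if (length(object@seed) != 1L || is.na(object@seed))
        msg <- c(msg, "a scalar seed is mandatory")
    if (object@clusterFactor < 0 || object@clusterFactor >= 1)
        msg <- c(msg, "clusterFactor must lie in [0,1)")
    for (sp in list(object@casteDmrSpec, object@sexDmrSpec))
        if (nrow(sp) && any(sp$piA < 0 | sp$piA > 1 | sp$piB < 0 | sp$piB > 1))
            msg <- c(msg, "DMR spec pi values must lie in [0,1]")
    if (is.null(msg)) TRUE else msg
})

#' Construct a SimulationDesign
#'
#' Defaults encode the emulated study: 4 phenotypes x 2 bisulfite replicates
#' (8 methylomes), 3 transcriptome replicates (12 libraries), bimodal
#' gene-body methylation (about half of genes methylated at pi 0.85 vs 0.02),
#' spatial clustering of methylated genes, 0.5% conversion error and 20x mean
#' coverage.
#'
#' @param nScaffolds,scaffoldLen,nGenes,fractionMethylated,clusterFactor,highMethLevel,lowMethLevel,interGenicLevel,conversionError,meanCoverage,nReps,nExprReps,casteDmrSpec,sexDmrSpec,nCasteDmrGenes,nSexDmrGenes,dmrDelta,antisenseBase,antisenseSignal,nAntisenseLoci,exprMeanRange,exprDispersion,morphEffectSd,nControlCytosines,seed see the class documentation.
#' @return A [SimulationDesign].
#' @examples
#' simulationDesign(seed = 1L, nGenes = 10L)
#' @export
simulationDesign <- function(seed,
                             nScaffolds = 2L, scaffoldLen = 100000L,
                             nGenes = 40L, fractionMethylated = 0.5,
                             clusterFactor = 0.8,
                             highMethLevel = 0.85, lowMethLevel = 0,
                             interGenicLevel = 0,
                             conversionError = 0.005, meanCoverage = 20,
                             nReps = 2L, nExprReps = 3L,
                             casteDmrSpec = emptyDmrSpec(),
                             sexDmrSpec = emptyDmrSpec(),
                             nCasteDmrGenes = 0L, nSexDmrGenes = 0L,
                             dmrDelta = 0.3,
                             antisenseBase = 0.05, antisenseSignal = 0.3,
                             nAntisenseLoci = 0L,
                             exprMeanRange = c(50, 2000),
                             exprDispersion = 8,
                             morphEffectSd = 0.25,
                             nControlCytosines = 50000L) {
    if (missing(seed)) stop("seed is mandatory for a SimulationDesign")
    new("SimulationDesign",
        nScaffolds = as.integer(nScaffolds),
        scaffoldLen = as.integer(scaffoldLen),
        nGenes = as.integer(nGenes),
        fractionMethylated = fractionMethylated,
        clusterFactor = clusterFactor,
        highMethLevel = highMethLevel, lowMethLevel = lowMethLevel,
        interGenicLevel = interGenicLevel,
        conversionError = conversionError, meanCoverage = meanCoverage,
        nReps = as.integer(nReps), nExprReps = as.integer(nExprReps),
        casteDmrSpec = casteDmrSpec, sexDmrSpec = sexDmrSpec,
        nCasteDmrGenes = as.integer(nCasteDmrGenes),
        nSexDmrGenes = as.integer(nSexDmrGenes),
        dmrDelta = dmrDelta,
        antisenseBase = antisenseBase, antisenseSignal = antisenseSignal,
        nAntisenseLoci = as.integer(nAntisenseLoci),
        exprMeanRange = exprMeanRange, exprDispersion = exprDispersion,
        morphEffectSd = morphEffectSd,
        nControlCytosines = as.integer(nControlCytosines),
        seed = as.integer(seed))
}

#' @describeIn simulationDesign empty planted-DMR specification
#' @export
emptyDmrSpec <- function()
    data.frame(gene = character(), piA = numeric(), piB = numeric())

setMethod("show", "SimulationDesign", function(object) {
    cat("SimulationDesign:", object@nScaffolds, "scaffold(s) x",
        object@scaffoldLen, "bp,", object@nGenes, "genes\n")
    cat(sprintf("  methylated fraction %.2f (pi %.2f vs %.2f), cluster %.2f\n",
                object@fractionMethylated, object@highMethLevel,
                object@lowMethLevel, object@clusterFactor))
    cat(sprintf("  conversion error %.4f, coverage %.1fx, %d BS reps, %d RNA reps, seed %d\n",
                object@conversionError, object@meanCoverage,
                object@nReps, object@nExprReps, object@seed))
})
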