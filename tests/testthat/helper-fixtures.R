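suppressPackageStartupMessages({
    library(GenomicRanges)
    library(Biostrings)
    library(SummarizedExperiment)
    library(S4Vectors)
})

## small shared simulated dataset: 1 scaffold, 10 genes, 2 planted caste DMR
## genes, 8 methylomes at 20x
smallSim <- local({
    d <- simulationDesign(seed = 101L, nGenes = 10L, nScaffolds = 1L,
                          scaffoldLen = 50000L, nCasteDmrGenes = 2L,
                          nControlCytosines = 20000L)
    sim <- simulateGenome(d)
    meth <- simulateMethylomes(sim, d)
    err <- estimateConversionError(sum(meth$lambda$unconverted),
                                   sum(meth$lambda$total))$rate
    list(design = d, sim = sim, meth = meth, err = err,
         called = callMethylation(meth$bs, err))
})

## minimal hand-built BSCounts
tinyBS <- function(M, U, pos = seq_len(nrow(M)) * 10L) {
    n <- ncol(M)
    des <- data.frame(sample = paste0("s", seq_len(n)),
                      caste = rep(c("alate", "worker"), length.out = n),
                      sex = rep(c("male", "female"), each = ceiling(n / 2),
                                length.out = n),
                      replicate = seq_len(n))
    BSCounts(GRanges("chr1", IRanges(pos, width = 1L)), M, U, des)
}

## 8-sample design used by comparison machinery
designCasteSex <- function() {
    data.frame(sample = c("AM1", "AM2", "AF1", "AF2",
                          "WM1", "WM2", "WF1", "WF2"),
               caste = rep(c("alate", "worker"), each = 4),
               sex = rep(rep(c("male", "female"), each = 2), 2),
               replicate = rep(1:2, 4))
}
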