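pointMassPWM <- function(id, seqChr) {
    mat <- matrix(1e-12, 4, nchar(seqChr),
                  dimnames = list(c("A", "C", "G", "T"), NULL))
    letters <- strsplit(seqChr, "")[[1]]
    mat[cbind(match(letters, c("A", "C", "G", "T")),
              seq_along(letters))] <- 1
    mat <- sweep(mat, 2, colSums(mat), "/")
    MotifModel(id, mat)
}

test_that("sequence sets are centered, bounded and mutually exclusive", {
    genome <- DNAStringSet(c(s1 = paste(rep("ACGT", 2500), collapse = "")))
    dmc <- GRanges("s1", IRanges(c(101, 30), width = 1))  # second near edge
    nonDmc <- GRanges("s1", IRanges(c(120, 150, 5000), width = 1))
    sets <- buildSequenceSets(dmc, nonDmc, genome, width = 150,
                              maxDist = 1500)
    ## 150-bp window centered on the anchor: 75 left, 74 right
    expect_equal(start(sets$test$ranges)[1], 26)
    expect_equal(end(sets$test$ranges)[1], 175)
    expect_equal(sets$droppedTest, 1L)   # anchor at 30 exits the scaffold
    ## controls at 120 and 150 overlap the test interval -> excluded;
    ## 5000 is farther than 1.5 kb from any DMC -> excluded
    expect_equal(length(sets$control$ranges), 0L)
    nonDmc2 <- GRanges("s1", IRanges(400, width = 1))
    sets2 <- buildSequenceSets(dmc, nonDmc2, genome)
    expect_equal(length(sets2$control$ranges), 1L)
    expect_equal(width(sets2$control$seqs), 150L)
})

test_that("point-mass PWM scores its consensus at the log2 maximum", {
    mo <- pointMassPWM("pm", "ACGT")
    hits <- pwmScan(DNAStringSet(c(x = "ACGT")), mo, pThresh = 0.01)
    plus <- hits[hits$strand == "+", ]
    ## log2(1/0.25) * 4 = 8 bits at position 1
    expect_equal(plus$score[plus$position == 1], 8, tolerance = 1e-6)
    expect_equal(plus$p[plus$position == 1], 1 / 256, tolerance = 1e-12)
    ## the reverse complement of ACGT is ACGT: minus-strand hit at the
    ## same locus
    minus <- hits[hits$strand == "-", ]
    expect_equal(minus$score[minus$position == 1], 8, tolerance = 1e-6)
})

test_that("scan p-values equal full k-mer enumeration for short motifs", {
    set.seed(19)
    for (w in c(3, 5, 8)) {
        mat <- matrix(rexp(4 * w), 4, dimnames = list(c("A", "C", "G", "T"),
                                                      NULL))
        mat <- sweep(mat, 2, colSums(mat), "/")
        mo <- MotifModel(paste0("r", w), mat)
        S <- methCaste:::scoreMatrix(mo)
        null <- methCaste:::scoreNullDistribution(S, mo@background)
        km <- as.matrix(expand.grid(rep(list(1:4), w)))
        scores <- vapply(seq_len(nrow(km)), function(i)
            sum(S[cbind(km[i, ], seq_len(w))]), numeric(1))
        probe <- sample(scores, 50)
        dp <- methCaste:::nullTailP(null, probe)
        enum <- vapply(probe, function(s) mean(scores >= s - 1e-9),
                       numeric(1))
        expect_equal(dp, enum, tolerance = 1e-9)
    }
})

test_that("miRNA motifs convert, validate and are found on both strands", {
    mo <- mirnaToMotif("mir-x", "UGAGGUA")
    expect_equal(motifWidth(mo), 7L)
    expect_true(all(abs(colSums(mo@matrix) - 1) < 1e-12))
    consensus <- paste(rownames(mo@matrix)[apply(mo@matrix, 2, which.max)],
                       collapse = "")
    expect_equal(consensus, "TGAGGTA")
    expect_error(mirnaToMotif("bad", "UGAXGUA"), "non-ACGU")
    ## a planted target-site complement is found via the minus strand
    site <- as.character(reverseComplement(DNAString("TGAGGTA")))
    seq <- paste0("AAAA", site, "AAAA")
    hits <- pwmScan(DNAStringSet(c(s = seq)), mo, pThresh = 1e-3)
    expect_true(any(hits$hit & hits$strand == "-"))
})

test_that("Fisher enrichment handles strong, null and degenerate tables", {
    fe <- fisherEnrichment(30, 100, 10, 300)
    expect_lt(fe$p, 1e-10)
    expect_equal(fe$oddsRatio, (30 * 290) / (70 * 10))
    expect_equal(round(fe$oddsRatio, 2), 12.43)
    ## equal rates are unremarkable
    feNull <- fisherEnrichment(10, 100, 30, 300)
    expect_gt(feNull$p, 0.4)
    ## zero hits everywhere: degenerate margin, p = 1
    expect_equal(fisherEnrichment(0, 100, 0, 300)$p, 1)
    expect_error(fisherEnrichment(101, 100, 0, 300), "exceed")
})

test_that("fold enrichment floors the control count at 1", {
    expect_equal(round(foldEnrichment(55, 0, 5786, 10871), 3), 103.337)
    expect_equal(round(foldEnrichment(267, 16, 5786, 10871), 3), 31.353)
    expect_equal(round(foldEnrichment(24, 0, 5786, 10871), 3), 45.092)
    expect_equal(foldEnrichment(10, 10, 100, 100), 1)
    expect_error(foldEnrichment(1, 0, 0, 100), "positive")
})

test_that("planted motif instances are recovered and enrich the test set", {
    set.seed(20)
    mkSeq <- function(n) vapply(seq_len(n), function(i)
        paste(sample(c("A", "C", "G", "T"), 150, replace = TRUE),
              collapse = ""), character(1))
    motif <- "TGACGTCA"
    mo <- pointMassPWM("planted", motif)
    test <- mkSeq(40)
    ## plant the consensus into 30 of 40 test sequences
    for (i in 1:30) substr(test[i], 60, 67) <- motif
    ctrl <- mkSeq(120)
    ## every exact-consensus plant is found at a stringent p threshold
    hits <- pwmScan(DNAStringSet(test[1:30]), mo, pThresh = 1e-4)
    expect_equal(sort(unique(hits$seq[hits$hit])), 1:30)
    enr <- motifEnrichment(list(planted = mo), DNAStringSet(test),
                           DNAStringSet(ctrl))
    expect_lt(enr$fisherP, 0.01)
    expect_gt(enr$fold, 3)
    ## shuffling test/control labels destroys the enrichment
    all <- c(test, ctrl)
    shufP <- replicate(20, {
        idx <- sample(length(all), 40)
        motifEnrichment(list(planted = mo), DNAStringSet(all[idx]),
                        DNAStringSet(all[-idx]))$fisherP
    })
    expect_gte(mean(shufP > 0.05), 0.9)
})

test_that("phenotype-specific labels arise from cross-set control tests", {
    set.seed(21)
    mkSeq <- function(n) vapply(seq_len(n), function(i)
        paste(sample(c("A", "C", "G", "T"), 150, replace = TRUE),
              collapse = ""), character(1))
    casteMotif <- pointMassPWM("casteTF", "TTGACGTCAA")
    caste <- mkSeq(30); sex <- mkSeq(30)
    for (i in 1:25) substr(caste[i], 40, 49) <- "TTGACGTCAA"
    res <- phenotypeSpecificEnrichment(
        list(casteTF = casteMotif),
        DNAStringSet(caste), DNAStringSet(sex),
        casteEnriched = "casteTF", sexEnriched = character(0))
    expect_equal(res$comparison, "caste")
    ## a motif equally present in both sets stays "ns"
    both <- pointMassPWM("shared", "CCCGGGTTTA")
    for (i in 1:20) substr(caste[i], 90, 99) <- "CCCGGGTTTA"
    for (i in 1:20) substr(sex[i], 90, 99) <- "CCCGGGTTTA"
    res2 <- phenotypeSpecificEnrichment(
        list(shared = both), DNAStringSet(caste), DNAStringSet(sex),
        casteEnriched = "shared", sexEnriched = character(0))
    expect_equal(res2$comparison, "ns")
})

test_that("MEME-like motif text round-trips through the parser", {
    f <- tempfile(fileext = ".meme")
    writeLines(c(
        "MEME version 4", "",
        "ALPHABET= ACGT", "",
        "Background letter frequencies",
        "A 0.3 C 0.2 G 0.2 T 0.3", "",
        "MOTIF testTF",
        "letter-probability matrix: alength= 4 w= 3 nsites= 20 E= 0",
        " 0.97 0.01 0.01 0.01",
        " 0.01 0.97 0.01 0.01",
        " 0.01 0.01 0.01 0.97"), f)
    ms <- readMemeMotifs(f)
    expect_equal(names(ms), "testTF")
    mo <- ms[["testTF"]]
    expect_equal(motifWidth(mo), 3L)
    expect_equal(unname(mo@background["A"]), 0.3)
    expect_equal(unname(mo@matrix["A", 1]), 0.97)
    expect_true(all(abs(colSums(mo@matrix) - 1) < 1e-9))
})
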