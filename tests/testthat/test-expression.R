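test_that("FPKM follows the definition and is scale-invariant", {
    expect_equal(fpkm(matrix(10), lengths = 1000, librarySizes = 1e6)[1, 1],
                 10)
    expect_equal(fpkm(matrix(0), lengths = 1000, librarySizes = 1e6)[1, 1], 0)
    m <- matrix(c(10, 20), 2)
    f1 <- fpkm(m, c(1000, 500), librarySizes = 1e6)
    f2 <- fpkm(m, c(1000, 500), librarySizes = 2e6)
    expect_equal(f1 / 2, f2)
    ## multiplying counts and the library size by c cancels
    f3 <- fpkm(m * 5, c(1000, 500), librarySizes = 5e6)
    expect_equal(f1, f3)
    expect_error(fpkm(m, c(0, 500)), "length")
})

test_that("expression summaries: CV, absolute difference and tau", {
    des <- data.frame(library = sprintf("l%02d", 1:12),
                      caste = rep(c("alate", "worker"), each = 6),
                      sex = rep(rep(c("male", "female"), each = 3), 2),
                      replicate = rep(1:3, 4))
    ## gene 1: identical replicates and morphs; gene 2: expressed in one morph
    fp <- rbind(rep(100, 12), c(rep(60, 3), rep(0, 9)))
    rownames(fp) <- c("flat", "specific")
    s <- expressionSummaries(fp, des)
    expect_equal(s$cv[1], 0)
    expect_equal(s$absDiff[1], 0)
    expect_equal(s$tau[1], 0)
    expect_equal(s$tau[2], 1)
    ## direct-formula oracle for tau and CV on a random gene
    set.seed(8)
    fp3 <- matrix(rexp(12, 1 / 50), 1)
    rownames(fp3) <- "r"
    s3 <- expressionSummaries(fp3, des)
    morph <- paste(des$caste, des$sex)
    mm <- tapply(fp3[1, ], morph, mean)[unique(morph)]
    expect_equal(s3$tau, sum(1 - mm / max(mm)) / 3, tolerance = 1e-12)
    cvs <- tapply(seq_len(12), morph, function(i) sd(fp3[1, i]) / mean(fp3[1, i]))
    expect_equal(s3$cv, mean(cvs[unique(morph)]), tolerance = 1e-12)
})

test_that("antisense binomial procedure matches exact tail probabilities", {
    ## 5 antisense of 100 at a 5% global rate is unremarkable
    expect_equal(binomialTailP(5, 100, 0.05), 0.5640187, tolerance = 1e-6)
    ## 30 of 100 is overwhelming
    expect_lt(binomialTailP(30, 100, 0.05), 1e-10)
    des <- data.frame(library = sprintf("l%02d", 1:12),
                      caste = rep(c("alate", "worker"), each = 6),
                      sex = rep(rep(c("male", "female"), each = 3), 2),
                      replicate = rep(1:3, 4))
    set.seed(14)
    nG <- 150
    tot <- matrix(rpois(nG * 12, 100), nG)
    anti <- matrix(rbinom(nG * 12, tot, 0.05), nG)
    anti[1, ] <- rbinom(12, tot[1, ], 0.40)
    sense <- tot - anti
    rownames(sense) <- rownames(anti) <- sprintf("g%03d", 1:nG)
    af <- antisenseFlags(sense, anti, des)
    expect_true(af$flags[1])
    expect_lte(mean(af$flags[-1]), 0.05)
    expect_equal(colnames(af$metric),
                 unique(paste(des$caste, des$sex, sep = "_")))
    ## flag rule: significant in more than a third of libraries
    expect_true(all(af$nSignificant[af$flags] > 4))
})

test_that("excluded overlapping genes never get flagged", {
    des <- data.frame(library = c("l1", "l2", "l3"),
                      caste = "alate", sex = "male", replicate = 1:3)
    sense <- matrix(c(70, 70, 70, 100, 100, 100), 2, byrow = TRUE)
    anti <- matrix(c(30, 30, 30, 5, 5, 5), 2, byrow = TRUE)
    rownames(sense) <- rownames(anti) <- c("gA", "gB")
    af <- antisenseFlags(sense, anti, des, excluded = c(TRUE, FALSE))
    expect_false(af$flags["gA"])
    ## and the global rate is computed over included loci only
    expect_equal(af$globalRate[1], 5 / 105)
})

test_that("rank model recovers a planted monotone predictor", {
    set.seed(15)
    n <- 500
    cv <- runif(n)
    meth <- 1 - cv^1.3 + rnorm(n, 0, 0.01)   # monotone decreasing in cv
    noise1 <- rnorm(n); noise2 <- rnorm(n)
    df <- data.frame(methylation = meth, cv = cv, n1 = noise1, n2 = noise2)
    fit <- methylationExpressionModel(df)
    marg <- fit$marginal
    expect_lt(marg$rho[marg$predictor == "cv"], -0.95)
    expect_equal(fit$coefficients$predictor[
        fit$coefficients$magnitudeRank == 1], "cv")
    ## independent predictors stay near zero
    expect_true(all(abs(marg$rho[marg$predictor != "cv"]) < 0.15))
})

test_that("degenerate predictors are dropped with warnings", {
    df <- data.frame(methylation = runif(50), a = runif(50),
                     const = rep(1, 50))
    expect_warning(fit <- methylationExpressionModel(df), "zero-variance")
    expect_false("const" %in% fit$marginal$predictor)
    df2 <- data.frame(methylation = runif(50), a = runif(50))
    df2$b <- df2$a
    expect_warning(fit2 <- methylationExpressionModel(df2), "collinear")
    expect_equal(fit2$coefficients$predictor, "a")
})

test_that("family metrics quantify conservation and duplication", {
    orth <- data.frame(
        family = rep(c("f1", "f2"), c(5, 4)),
        species = c("Znev", "Cflo", "Amel", "Dmel", "Tcas",
                    "Znev", "Cflo", "Amel", "Dmel"),
        copies = c(3L, 1L, 1L, 1L, 0L,
                   1L, 1L, 1L, 1L))
    fm <- familyMetrics(orth)
    f1 <- fm[fm$family == "f1", ]
    expect_equal(f1$propSpecies, 4 / 5)
    expect_equal(f1$meanCopies, 1.2)
    expect_equal(f1$focalRatio, 3 / 1.2)
    expect_true(f1$duplicated)
    f2 <- fm[fm$family == "f2", ]
    expect_false(f2$duplicated)
    ## copies (1,1,1,3) with focal 3 -> ratio 3/1.5 = 2
    orth3 <- data.frame(family = "f", species = c("a", "b", "c", "Znev"),
                        copies = c(1L, 1L, 1L, 3L))
    expect_equal(familyMetrics(orth3)$focalRatio, 2)
})

test_that("duplication stratifies the methylation-expression slope", {
    set.seed(16)
    n <- 400
    dup <- rep(c(TRUE, FALSE), each = n / 2)
    lvl <- runif(n)
    meth <- ifelse(dup, 0.9 * lvl, 0.2 * lvl) + rnorm(n, 0, 0.05)
    df <- data.frame(methylation = meth, logLevel = lvl, duplicated = dup)
    dc <- duplicationContrast(df)
    expect_gt(dc$beta[dc$stratum == "duplicated"],
              dc$beta[dc$stratum == "single"])
})

test_that("DMG contrasts: rank-sum, Fisher table and DMR distances", {
    set.seed(17)
    genes <- sprintf("g%03d", 1:200)
    summ <- data.frame(gene = genes, cv = runif(200), absDiff = runif(200))
    ## DMGs markedly less variable
    dmg <- genes[1:50]
    summ$cv[1:50] <- summ$cv[1:50] * 0.2
    spliced <- c(genes[1:30], genes[51:60])   # 30/50 DMG vs 10/150 others
    res <- dmgExpressionContrasts(dmg, summ, spliced)
    expect_lt(res$expression$pRankSum[res$expression$metric == "cv"], 1e-4)
    expect_equal(res$splicing$oddsRatio, (30 * 140) / (20 * 10))
    expect_lt(res$splicing$pFisher, 0.01)
    ## the classic 30/70 vs 10/90 sample odds ratio
    or <- (30 * 90) / (70 * 10)
    expect_equal(round(or, 3), 3.857)
    ## planted DMRs next to spliced exons come out closer than non-DMRs
    dmrs <- GRanges("s1", IRanges(c(1000, 5000), width = 200))
    nonDmr <- GRanges("s1", IRanges(seq(20000, 40000, by = 2000), width = 200))
    splEx <- GRanges("s1", IRanges(c(1300, 5300), width = 100))
    res2 <- dmgExpressionContrasts(dmg, summ, spliced, dmrs = dmrs,
                                   nonDmrWindows = nonDmr,
                                   splicedExons = splEx)
    expect_lt(res2$distance$medianDmr, res2$distance$medianNonDmr)
})
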