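test_that("tiling covers scaffolds with a terminal remainder", {
    w <- tileWindows(c(s1 = 500L))
    expect_equal(start(w), c(1L, 201L, 401L))
    expect_equal(end(w), c(200L, 400L, 500L))
    expect_equal(length(tileWindows(c(s1 = 200L))), 1L)
    expect_equal(length(tileWindows(c(s1 = 0L))), 0L)
    expect_error(tileWindows(c(s1 = 500L), width = 0L), "width")
})

test_that("testability filter enforces per-side coverage and methylation", {
    des <- designCasteSex()
    ## 3 windows x 8 samples; window 1 fully covered, window 2 has only 2
    ## covered alate samples, window 3 covered but never methylated
    M <- matrix(0L, 3, 8); U <- matrix(0L, 3, 8)
    M[1, ] <- 10L; U[1, ] <- 2L
    M[2, 1:2] <- 10L; U[2, 1:2] <- 2L; M[2, 5:8] <- 10L; U[2, 5:8] <- 2L
    U[3, ] <- 12L
    sites <- GRanges("s1", IRanges(c(50L, 250L, 450L), width = 1L))
    bs <- BSCounts(sites, M, U, des)
    called <- callMethylation(bs, err = 0.005)
    w <- tileWindows(c(s1 = 600L))
    wc <- windowCounts(called, w)
    ok <- filterTestable(wc, des, "caste", called = called)
    expect_equal(ok, c(TRUE, FALSE, FALSE))
    ## without the methylation criterion window 3 is coverage-testable
    ok2 <- filterTestable(wc, des, "caste")
    expect_equal(ok2, c(TRUE, FALSE, TRUE))
    expect_error(filterTestable(wc, des[1:4, ], "caste"), "3 samples")
})

test_that("beta-binomial fit collapses for identical groups", {
    f <- betaBinomFit(c(8L, 9L), c(2L, 1L), c(8L, 9L), c(2L, 1L), theta = 20)
    expect_equal(f$piA, f$piB, tolerance = 1e-6)
    expect_equal(f$piA, f$piNull, tolerance = 1e-6)
    expect_equal(f$lrt, 0, tolerance = 1e-6)
})

test_that("large theta recovers the binomial likelihood", {
    m <- c(5L, 7L); u <- c(5L, 3L)
    pi <- 0.6
    bino <- sum(dbinom(m, m + u, pi, log = TRUE))
    bb <- methCaste:::betaBinLogLik(m, u, pi, theta = 1e8)
    expect_equal(bb, bino, tolerance = 1e-5)
})

test_that("ML proportions match a fine-grid brute-force oracle", {
    gridML <- function(m, u, theta) {
        grid <- seq(1e-4, 1 - 1e-4, by = 1e-4)
        ll <- vapply(grid, function(p)
            methCaste:::betaBinLogLik(m, u, p, theta), numeric(1))
        grid[which.max(ll)]
    }
    f <- betaBinomFit(c(8L, 9L), c(2L, 1L), c(2L, 1L), c(8L, 9L), theta = 20)
    expect_equal(f$piA, gridML(c(8L, 9L), c(2L, 1L), 20), tolerance = 1e-3)
    expect_equal(f$piB, gridML(c(2L, 1L), c(8L, 9L), 20), tolerance = 1e-3)
    set.seed(4)
    for (i in 1:20) {
        th <- runif(1, 2, 80)
        n <- rpois(3, 15) + 1L
        m <- rbinom(3, n, runif(1, 0.05, 0.95))
        expect_equal(methCaste:::fitPi(m, n - m, th), gridML(m, n - m, th),
                     tolerance = 1e-3)
    }
})

test_that("dispersion estimation recovers theta and hits its bounds", {
    ## identical replicates have no overdispersion: theta at the ceiling
    expect_equal(thetaMoM(c(5, 5, 5, 5), c(5, 5, 5, 5),
                          rep("a", 4)), 1e6)
    ## recovery: median over 100 sims within [10, 22] for true theta 15
    set.seed(12)
    est <- replicate(100, {
        m <- u <- c(); cell <- c()
        for (j in 1:50) for (g in 1:2) {
            pi <- runif(1, .2, .8)
            n <- rpois(4, 20) + 1L
            mm <- rbinom(4, n, rbeta(4, pi * 15, (1 - pi) * 15))
            m <- c(m, mm); u <- c(u, n - mm)
            cell <- c(cell, rep(paste(j, g), 4))
        }
        thetaMoM(m, u, cell)
    })
    expect_gt(median(est), 10)
    expect_lt(median(est), 22)
})

test_that("local dispersion falls back to the window alone without flanks", {
    des <- designCasteSex()
    sides <- methCaste:::comparisonSides(des, "caste")
    set.seed(7)
    M <- matrix(rbinom(8, 20, 0.5), 1); U <- 20L - M
    sites <- GRanges("s1", IRanges(50L, width = 1L))
    bs <- BSCounts(sites, M, U, des)
    w <- tileWindows(c(s1 = 200L))   # single window, no flanks exist
    wc <- windowCounts(bs, w)
    thWin <- localDispersion(wc, w, 1L, sides)
    thDirect <- thetaMoM(as.vector(wc$M[1, ]), as.vector(wc$U[1, ]),
                         rep(c("A", "B"), each = 4))
    expect_equal(thWin, thDirect)
})

test_that("the effect-size filter vetoes small but significant differences", {
    ## build one window with a true small diff at huge coverage
    des <- designCasteSex()
    nA <- nB <- rep(20000L, 4)
    mA <- as.integer(round(nA * 0.50)); mB <- as.integer(round(nB * 0.36))
    M <- matrix(c(mA, mB), 1); U <- matrix(c(nA - mA, nB - mB), 1)
    bs <- BSCounts(GRanges("s1", IRanges(50, width = 1)), M, U, des)
    called <- callMethylation(bs, err = 0.005)
    w <- tileWindows(c(s1 = 200L))
    res14 <- testWindows(called, w, "caste", minDiff = 0.15)
    expect_lt(mcols(res14)$q[1], 1e-4)
    expect_equal(abs(mcols(res14)$diff[1]), 0.14, tolerance = 0.01)
    expect_false(mcols(res14)$significant[1])
})

test_that("adjacent same-direction windows merge; opposite directions do not", {
    d <- smallSim
    w <- tileWindows(d$sim$genome)
    res <- testWindows(d$called, w, "caste")
    ma <- mergeAndAssign(res, d$sim$annotation)
    sig <- res[mcols(res)$significant %in% TRUE]
    ## every merged DMR is wider than or equal to a window and directions pure
    expect_true(all(width(ma$dmrs) %% 1 == 0))
    expect_true(all(countOverlaps(ma$dmrs, sig) >= 1))
    ## merging is idempotent: re-reducing changes nothing
    again <- reduce(granges(ma$dmrs), min.gapwidth = 1L)
    expect_equal(length(again), length(ma$dmrs))
    ## synthetic check of direction separation
    wins <- GRanges("scaffold01", IRanges(c(1, 201, 401), width = 200))
    mcols(wins) <- S4Vectors::DataFrame(
        tested = TRUE, nCpG = 3L, piA = c(.9, .9, .1), piB = c(.1, .1, .9),
        diff = c(.8, .8, -.8), theta = 20, lrt = 50, p = 1e-10, q = 1e-9,
        direction = c("hyper-alate", "hyper-alate", "hyper-worker"),
        significant = TRUE)
    metadata(wins) <- list(comparison = "caste", alpha = 0.05,
                           minDiff = 0.15,
                           sides = list(labels = c("hyper-alate",
                                                   "hyper-worker")))
    ann <- d$sim$annotation
    ma2 <- mergeAndAssign(wins, ann)
    expect_equal(length(ma2$dmrs), 2L)
    expect_equal(width(ma2$dmrs)[order(start(ma2$dmrs))][1], 400L)
})

test_that("DMRs are assigned the feature with maximal overlap", {
    g <- GRanges("s1", IRanges(101, 400), strand = "+", gene_id = "gX")
    ex <- GRanges("s1", IRanges(c(101, 321), c(220, 400)), strand = "+",
                  gene_id = "gX")
    ann <- geneAnnotation(g, ex, promoterLen = 100L)
    win <- GRanges("s1", IRanges(101, 300))  # 120 bp exon, 80 bp intron
    mcols(win) <- S4Vectors::DataFrame(
        tested = TRUE, nCpG = 3L, piA = .9, piB = .1, diff = .8, theta = 20,
        lrt = 50, p = 1e-10, q = 1e-9, direction = "hyper-alate",
        significant = TRUE)
    metadata(win) <- list(comparison = "caste", alpha = 0.05, minDiff = 0.15,
                          sides = list(labels = c("hyper-alate",
                                                  "hyper-worker")))
    ma <- mergeAndAssign(win, ann)
    expect_equal(mcols(ma$dmrs)$feature, "exon")
    expect_equal(mcols(ma$dmrs)$gene_id, "gX")
})

test_that("paired intersection keeps consistent-direction genes only", {
    a <- data.frame(gene_id = c("g1", "g2", "g3"),
                    direction = c("hyper-alate", "hyper-alate",
                                  "hyper-worker"))
    b <- data.frame(gene_id = c("g1", "g3", "g4"),
                    direction = c("hyper-alate", "hyper-alate",
                                  "hyper-alate"))
    pi <- pairedIntersection(a, b)
    expect_equal(pi$gene_id, "g1")      # g2 absent in b, g3 flips direction
    expect_equal(pi$direction, "hyper-alate")
})

test_that("type-I error of the window test is controlled on null data", {
    ## null genome: methylated genes but no planted group difference
    d <- simulationDesign(seed = 31L, nGenes = 20L, nScaffolds = 1L,
                          scaffoldLen = 100000L)
    sim <- simulateGenome(d)
    meth <- simulateMethylomes(sim, d)
    err <- estimateConversionError(sum(meth$lambda$unconverted),
                                   sum(meth$lambda$total))$rate
    called <- callMethylation(meth$bs, err)
    w <- tileWindows(sim$genome)
    res <- testWindows(called, w, "caste")
    tested <- sum(mcols(res)$tested)
    expect_gt(tested, 50)
    expect_lte(sum(mcols(res)$significant) / tested, 0.05)
})
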