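# Shared small search problem for the GA tests: 3 x 3 grid, one planted
# informative cell at (2, 2) (linear index 5).
gaProblem <- local({
    spec <- syntheticSpec(nSamples = 14, height = 60, width = 90,
                          roi1 = 3, roi2 = 3, informativeCells = c(2, 2),
                          peakSigma = 2, nBackgroundPeaks = 6)
    ss <- generateSyntheticSet(spec, seed = 51)
    list(ss = ss, cache = cellHistogramCache(ss$images, ss$grid))
})

test_that("initial populations respect the 1..Nim constraint", {
    cfg1 <- gaConfig(popSize = 50, nim = 1)
    set.seed(1)
    P1 <- initPopulation(cfg1, nGenes = 9)
    expect_true(all(rowSums(P1) == 1))
    cfg <- gaConfig(popSize = 2000, nim = 9)
    set.seed(2)
    P <- initPopulation(cfg, nGenes = 9)
    counts <- rowSums(P)
    expect_true(all(counts >= 1 & counts <= 9))
    expect_setequal(sort(unique(counts)), 1:9)
    set.seed(7); A <- initPopulation(cfg1, 9)
    set.seed(7); B <- initPopulation(cfg1, 9)
    expect_identical(A, B)
    expect_error(initPopulation(gaConfig(nim = 10), nGenes = 9), "nim")
})

test_that("fitness equals the LOOCV RMSECV of the pooled model", {
    cfg <- gaConfig(nLV = 2)
    genes <- integer(9); genes[c(1, 5)] <- 1L
    f <- chromosomeFitness(genes, gaProblem$cache, gaProblem$ss$y, cfg)
    fm <- buildFeatureMatrix(gaProblem$ss$images, gaProblem$ss$y,
                             gaProblem$ss$grid, selected = c(1, 5))
    expect_equal(f, loocv(fm, nLV = 2)$rmsecv)
    # all-ones chromosome equals the full-image model
    all1 <- rep(1L, 9)
    fFull <- chromosomeFitness(all1, gaProblem$cache, gaProblem$ss$y, cfg)
    fmFull <- buildFeatureMatrix(gaProblem$ss$images, gaProblem$ss$y,
                                 gaProblem$ss$grid)
    expect_equal(fFull, loocv(fmFull, nLV = 2)$rmsecv)
    expect_error(chromosomeFitness(integer(9), gaProblem$cache,
                                   gaProblem$ss$y, cfg), "no subimage")
})

test_that("roulette selection weights parents by inverse RMSECV", {
    expect_equal(rouletteSelect(c(2, Inf, Inf)), c(1, 1))
    set.seed(3)
    draws <- replicate(20000, rouletteSelect(c(1, 2, 2, Inf)))
    freq <- tabulate(draws, nbins = 4) / length(draws)
    expect_equal(freq[4], 0)                  # non-finite excluded
    expect_equal(freq[1] / freq[2], 2, tolerance = 0.1)
    set.seed(4)
    uni <- replicate(20000, rouletteSelect(c(3, 3, 3)))
    expect_equal(max(abs(tabulate(uni, 3) / length(uni) - 1 / 3)), 0,
                 tolerance = 0.02)
})

test_that("crossover swaps suffixes at a single cut point", {
    a <- c(1L, 0L, 0L); b <- c(0L, 1L, 1L)
    set.seed(5)
    same <- crossoverSinglePoint(a, a, rate = 1)
    expect_identical(same[[1]], a)
    for (i in 1:50) {
        kids <- crossoverSinglePoint(a, b, rate = 1)
        # positionwise union of genes is conserved
        expect_equal(kids[[1]] + kids[[2]], a + b)
        # offspring must correspond to a cut at 1 or 2
        expect_true(identical(kids[[1]], c(1L, 1L, 1L)) ||
                    identical(kids[[1]], c(1L, 0L, 1L)))
    }
    none <- crossoverSinglePoint(a, b, rate = 0)
    expect_identical(none, list(a, b))
})

test_that("mutation flips genes at the configured rate", {
    g <- c(1L, 0L, 1L, 0L)
    expect_identical(mutateGenes(g, 0), g)
    expect_identical(mutateGenes(g, 1), 1L - g)
    set.seed(6)
    flips <- replicate(400, sum(mutateGenes(integer(100), 0.05)))
    expect_equal(mean(flips), 5, tolerance = 0.15)
})

test_that("repair enforces the chromosome cardinality bounds", {
    set.seed(7)
    r0 <- repairChromosome(integer(4), nim = 2)
    expect_equal(sum(r0), 1)
    gOK <- c(1L, 1L, 0L, 0L)
    expect_identical(repairChromosome(gOK, nim = 2), gOK)
    gBig <- rep(1L, 8)
    r <- repairChromosome(gBig, nim = 3)
    expect_equal(sum(r), 3)
    expect_true(all(which(r == 1L) %in% which(gBig == 1L)))
})

test_that("evolution is elitist, reproducible, and finds the planted cell", {
    cfg <- gaConfig(popSize = 14, generations = 8, nim = 2, nLV = 2,
                    nRestarts = 3)
    r1 <- evolve(gaProblem$cache, gaProblem$ss$y, cfg, seed = 9)
    expect_true(all(diff(r1@bestPerGeneration) <= 0))
    r2 <- evolve(gaProblem$cache, gaProblem$ss$y, cfg, seed = 9)
    expect_identical(r1@bestGenes, r2@bestGenes)
    expect_identical(r1@bestPerGeneration, r2@bestPerGeneration)
    rr <- runRestarts(gaProblem$cache, gaProblem$ss$y, cfg,
                      masterSeed = 10)
    fits <- vapply(rr$runs, function(r) r@bestFitness, numeric(1))
    expect_equal(rr$best@bestFitness, min(fits))
    expect_length(rr$runs, 3)
    # the planted cell (index 5) carries the signal
    expect_true(5L %in% which(rr$best@bestGenes == 1L))
    rr2 <- runRestarts(gaProblem$cache, gaProblem$ss$y, cfg,
                       masterSeed = 10)
    expect_identical(rr$best@bestGenes, rr2$best@bestGenes)
})

test_that("GA agrees with exhaustive search on a small grid", {
    cfg <- gaConfig(popSize = 14, generations = 8, nim = 2, nLV = 2,
                    nRestarts = 3)
    ex <- exhaustiveBest(gaProblem$cache, gaProblem$ss$y, cfg, nim = 2)
    rr <- runRestarts(gaProblem$cache, gaProblem$ss$y, cfg,
                      masterSeed = 12)
    expect_identical(sort(which(rr$best@bestGenes == 1L)),
                     as.integer(sort(ex$subset)))
})

test_that("Monte-Carlo reliability scores the planted cell highest", {
    cfg <- gaConfig(popSize = 12, generations = 6, nim = 2, nLV = 2)
    freq <- monteCarloReliability(gaProblem$cache, gaProblem$ss$y, cfg,
                                  nMC = 4, masterSeed = 13)
    expect_length(freq, 9)
    expect_true(all(freq >= 0 & freq <= 1))
    expect_equal(which.max(freq), 5)
})

test_that("selected ROI tables carry labels and retention frames", {
    grid <- partitionImage(roi1 = 5, roi2 = 5, J = 705, K = 1195)
    genes <- integer(25)
    genes[unfoldIndex(2, 3, grid)] <- 1L
    tab <- selectedROITable(genes, grid, xRange = c(0, 90),
                            yRange = c(0, 10))
    expect_equal(tab$row, 2)
    expect_equal(tab$col, 3)
    expect_equal(tab$x_from, 90 * grid@colBounds[3] / 1195)
    expect_equal(tab$y_to, 10 * grid@rowBounds[3] / 705)
})
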