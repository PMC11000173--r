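# Frozen study-condition experiments used by the acceptance suite.

# 4 x 4 grid, one planted informative cell, chromosomes capped at two
# subimages: can best-of-10 GA find the exhaustive-search optimum?
ga4x4Spec <- function() {
    syntheticSpec(nSamples = 24, height = 128, width = 192,
                  roi1 = 4, roi2 = 4, informativeCells = c(2, 3),
                  peakSigma = 3, nBackgroundPeaks = 15)
}

ga4x4Config <- function() {
    gaConfig(popSize = 20, generations = 12, nim = 2, nRestarts = 10,
             nLV = 2)
}

ga4x4Trial <- function(seed) {
    ss <- generateSyntheticSet(ga4x4Spec(), seed = seed)
    cache <- cellHistogramCache(ss$images, ss$grid)
    cfg <- ga4x4Config()
    ex <- exhaustiveBest(cache, ss$y, cfg, nim = 2)
    rr <- runRestarts(cache, ss$y, cfg, masterSeed = seed)
    identical(sort(which(rr$best@bestGenes == 1L)),
              as.integer(sort(ex$subset)))
}

# Full study-scale end-to-end run: default synthetic spec (38 samples,
# 705 x 1195 px, 5 x 5 grid, informative cells (2,3) and (1,4)),
# best-of-10 GA with chromosomes capped at four subimages.
e2eConfig <- function() {
    gaConfig(popSize = 20, generations = 12, nim = 4, nRestarts = 10,
             nLV = 2)
}

e2eTrial <- function(seed) {
    ss <- generateSyntheticSet(syntheticSpec(), seed = seed)
    cache <- cellHistogramCache(ss$images, ss$grid)
    cfg <- e2eConfig()
    full <- chromosomeFitness(rep(1L, nSubimages(ss$grid)), cache,
                              ss$y, cfg)
    rr <- runRestarts(cache, ss$y, cfg, masterSeed = seed)
    list(fullRmsecv = full, gaRmsecv = rr$best@bestFitness,
         recovery = recoveryScore(rr$best@bestGenes, ss$truth))
}

# Ten master seeds derived from one base seed.
masterSeeds <- function(base, n = 10) {
    set.seed(base)
    sample.int(1e6, n)
}
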