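# Small in-code fixtures shared across test files.

# Uniform-color image.
uniformImage <- function(J, K, rgb = c(255, 255, 255)) {
    RasterImage(array(rep(rgb, each = J * K), dim = c(J, K, 3)))
}

# Seeded random-noise image.
noiseImage <- function(J, K, seed = 1) {
    set.seed(seed)
    RasterImage(array(sample(0:255, J * K * 3, replace = TRUE),
                      dim = c(J, K, 3)))
}

# Scaled-down synthetic spec for unit tests (same structure as the
# default, much smaller images).
smallSpec <- function(...) {
    args <- utils::modifyList(
        list(nSamples = 16, height = 100, width = 150,
             roi1 = 5, roi2 = 5, informativeCells = c(2, 3),
             peakSigma = 2, nBackgroundPeaks = 10),
        list(...))
    do.call(syntheticSpec, args)
}

# Random full-rank regression instance.
randomInstance <- function(I, J, seed) {
    set.seed(seed)
    list(X = matrix(rnorm(I * J), I, J), y = rnorm(I))
}
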