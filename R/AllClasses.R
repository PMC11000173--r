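#' @import methods
#' @importFrom stats predict rnorm runif sd qt cor dist
#' @importFrom tools file_ext
NULL

#' RasterImage: an 8-bit RGB image
#'
#' A 24-bit raster image held as an integer array of dimension
#' \code{J x K x 3} (rows x columns x channel), channel order red, green,
#' blue, values in 0--255. Rows run top to bottom: row 1 is the top of the
#' image. For a rendered 2D chromatogram the vertical axis is the second
#' chromatographic dimension and the horizontal axis the first.
#'
#' @slot pixels integer array \code{J x K x 3}, values in \code{[0, 255]}.
#' @exportClass RasterImage
setClass("RasterImage", representation(pixels = "array"))

setValidity("RasterImage", function(object) {
    px <- object@pixels
    d <- dim(px)
    if (length(d) != 3L || d[3] != 3L)
        return("pixels must be a J x K x 3 array")
    if (d[1] < 1L || d[2] < 1L)
        return("image must have at least one row and one column")
    if (anyNA(px)) return("pixels contain NA")
    rng <- range(px)
    if (rng[1] < 0 || rng[2] > 255)
        return("channel values must lie in [0, 255]")
    TRUE
})

#' Construct a RasterImage
#'
#' @param pixels numeric or integer array \code{J x K x 3} with values in
#'   0--255 (fractional values are rounded).
#' @return A \linkS4class{RasterImage}.
#' @export
RasterImage <- function(pixels) {
    px <- round(pixels)
    storage.mode(px) <- "integer"
    new("RasterImage", pixels = px)
}

#' ROIGrid: a rectangular partition of an image into subimages
#'
#' Splits a \code{J x K} image into \code{roi2} rows and \code{roi1}
#' columns of near-equal rectangular subimages (regions of interest).
#' Boundaries are half-open pixel offsets \code{floor(i * dim / roi)}, so
#' every pixel belongs to exactly one subimage and block sizes differ by at
#' most one pixel per axis.
#'
#' @slot roi1 integer, number of grid columns.
#' @slot roi2 integer, number of grid rows.
#' @slot rowBounds integer vector of \code{roi2 + 1} offsets (0 .. J).
#' @slot colBounds integer vector of \code{roi1 + 1} offsets (0 .. K).
#' @exportClass ROIGrid
setClass("ROIGrid", representation(
    roi1 = "integer", roi2 = "integer",
    rowBounds = "integer", colBounds = "integer"))

setValidity("ROIGrid", function(object) {
    rb <- object@rowBounds; cb <- object@colBounds
    if (length(rb) != object@roi2 + 1L) return("rowBounds has wrong length")
    if (length(cb) != object@roi1 + 1L) return("colBounds has wrong length")
    if (rb[1] != 0L || cb[1] != 0L) return("bounds must start at 0")
    if (any(diff(rb) <= 0L) || any(diff(cb) <= 0L))
        return("bounds must be strictly increasing")
    TRUE
})

#' FeatureMatrix: samples-by-features histogram matrix with response
#'
#' Rows are samples, columns are concatenated per-channel 256-bin
#' color-frequency histograms; \code{y} is the numeric response (for the
#' wine application, age in years). The channel layout is recorded so that
#' column blocks can be mapped back to color channels.
#'
#' @slot X numeric matrix, samples x features.
#' @slot y numeric response vector aligned with rows of \code{X}.
#' @slot sampleIds character vector of sample identifiers.
#' @slot channels character vector of channel names, in column-block order.
#' @slot binsPerChannel integer, bins per channel block (256).
#' @exportClass FeatureMatrix
setClass("FeatureMatrix", representation(
    X = "matrix", y = "numeric", sampleIds = "character",
    channels = "character", binsPerChannel = "integer"))

setValidity("FeatureMatrix", function(object) {
    if (nrow(object@X) != length(object@y))
        return("nrow(X) must equal length(y)")
    if (nrow(object@X) != length(object@sampleIds))
        return("nrow(X) must equal length(sampleIds)")
    if (ncol(object@X) !=
        length(object@channels) * object@binsPerChannel)
        return("ncol(X) must equal length(channels) * binsPerChannel")
    if (any(!is.finite(object@y))) return("y must be finite")
    TRUE
})

#' PLSModel: a fitted PLS1 regression
#'
#' Mean-centered NIPALS PLS1 model. Slots hold everything needed to
#' predict: the regression vector in the centered space plus the training
#' column means and mean response.
#'
#' @slot nLV integer, number of latent variables retained.
#' @slot coef numeric regression vector (length = number of features).
#' @slot xMeans numeric training column means.
#' @slot yMean numeric training response mean.
#' @slot scores numeric matrix of training scores (samples x nLV).
#' @slot loadings numeric matrix of X loadings (features x nLV).
#' @slot weights numeric matrix of X weights (features x nLV).
#' @exportClass PLSModel
setClass("PLSModel", representation(
    nLV = "integer", coef = "numeric", xMeans = "numeric",
    yMean = "numeric", scores = "matrix", loadings = "matrix",
    weights = "matrix"))

#' MeritReport: figures of merit for a calibration/prediction model pair
#'
#' @slot nLV integer latent-variable count.
#' @slot rmsecv numeric, cross-validation RMSE (response units).
#' @slot repCV numeric, RMSECV / mean(y) (dimensionless ratio).
#' @slot r2CV numeric, cross-validation R-squared.
#' @slot rmsep numeric, prediction-set RMSE (NA if no prediction set).
#' @slot rep numeric, RMSEP / mean(y).
#' @slot r2 numeric, prediction-set R-squared.
#' @slot bias numeric, mean prediction residual.
#' @slot tCal numeric, bias t statistic.
#' @slot tCrit numeric, one-sided critical value.
#' @slot biasSignificant logical, \code{tCal > tCrit}.
#' @exportClass MeritReport
setClass("MeritReport", representation(
    nLV = "integer", rmsecv = "numeric", repCV = "numeric",
    r2CV = "numeric", rmsep = "numeric", rep = "numeric", r2 = "numeric",
    bias = "numeric", tCal = "numeric", tCrit = "numeric",
    biasSignificant = "logical"))

#' GAConfig: genetic-algorithm run parameters
#'
#' Defaults follow the reported chromatogram experiment: population 100,
#' 100 generations, per-gene mutation probability 0.05, crossover
#' probability 0.65, elitism 0.10. \code{nim} caps the number of subimages
#' a chromosome may select (default: the whole grid).
#'
#' @slot popSize integer, population size p.
#' @slot generations integer, generation count g.
#' @slot elitismRate numeric in [0,1].
#' @slot crossoverRate numeric in [0,1].
#' @slot mutationRate numeric in [0,1], per-gene flip probability.
#' @slot nim integer, maximum selected subimages (NA = grid size).
#' @slot nRestarts integer, independent restarts.
#' @slot nLV integer, fixed latent-variable count for fitness (NA = select).
#' @slot lvMax integer, LV search ceiling when \code{nLV} is NA.
#' @slot channels character, color channels used for histograms.
#' @exportClass GAConfig
setClass("GAConfig", representation(
    popSize = "integer", generations = "integer", elitismRate = "numeric",
    crossoverRate = "numeric", mutationRate = "numeric", nim = "integer",
    nRestarts = "integer", nLV = "integer", lvMax = "integer",
    channels = "character"))

setValidity("GAConfig", function(object) {
    rates <- c(object@elitismRate, object@crossoverRate,
               object@mutationRate)
    if (any(rates < 0 | rates > 1)) return("rates must lie in [0, 1]")
    if (object@popSize < 2L) return("popSize must be at least 2")
    if (object@generations < 1L) return("generations must be at least 1")
    if (object@nRestarts < 1L) return("nRestarts must be at least 1")
    if (!is.na(object@nim) && object@nim < 1L)
        return("nim must be at least 1")
    TRUE
})

#' GARunResult: outcome of one GA run (or the best of several restarts)
#'
#' @slot bestGenes integer 0/1 vector, the winning chromosome.
#' @slot bestFitness numeric, its RMSECV (response units).
#' @slot bestPerGeneration numeric vector, best RMSECV after each
#'   generation (non-increasing whenever elitism is positive).
#' @slot seed integer, RNG seed that produced the run.
#' @slot nEvaluations integer, fitness evaluations performed (cache misses).
#' @exportClass GARunResult
setClass("GARunResult", representation(
    bestGenes = "integer", bestFitness = "numeric",
    bestPerGeneration = "numeric", seed = "integer",
    nEvaluations = "integer"))

#' SyntheticSpec: parameters of the synthetic chromatogram generator
#'
#' Describes a set of pseudo-color heat-map images in which only designated
#' grid cells carry response-correlated signal. Defaults emulate the wine
#' study conditions: 38 samples, 705 x 1195 pixel images, a 5 x 5 grid, one
#' informative cell at grid position (2, 3), ages spanning 6--34 years.
#'
#' @slot nSamples integer sample count I.
#' @slot height,width integer image dimensions in pixels.
#' @slot roi1,roi2 integer grid columns / rows.
#' @slot informativeCells integer matrix, one (row, col) pair per row.
#' @slot peaksPerCell integer Gaussian peaks planted per informative cell.
#' @slot peakSigma numeric peak width (pixels).
#' @slot gain numeric intensity units per year of response.
#' @slot noiseSigma numeric pixel noise standard deviation.
#' @slot yRange numeric length-2, response range in years.
#' @slot nBackgroundPeaks integer shared response-independent peaks.
#' @slot backgroundAmplitude numeric intensity of background peaks.
#' @slot baseline numeric background intensity level.
#' @slot colormap character, name of the intensity-to-RGB colormap.
#' @exportClass SyntheticSpec
setClass("SyntheticSpec", representation(
    nSamples = "integer", height = "integer", width = "integer",
    roi1 = "integer", roi2 = "integer", informativeCells = "matrix",
    peaksPerCell = "integer", peakSigma = "numeric", gain = "numeric",
    noiseSigma = "numeric", yRange = "numeric",
    nBackgroundPeaks = "integer", backgroundAmplitude = "numeric",
    baseline = "numeric", colormap = "character"))

setValidity("SyntheticSpec", function(object) {
    ic <- object@informativeCells
    if (ncol(ic) != 2L) return("informativeCells must have two columns")
    if (any(ic[, 1] < 1L) || any(ic[, 1] > object@roi2) ||
        any(ic[, 2] < 1L) || any(ic[, 2] > object@roi1))
        return("informative cell outside the grid")
    if (object@gain < 0) return("gain must be non-negative")
    if (object@noiseSigma < 0) return("noiseSigma must be non-negative")
    if (diff(object@yRange) < 0) return("yRange must be non-decreasing")
    TRUE
})
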