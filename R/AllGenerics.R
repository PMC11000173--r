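#' Image height (pixel rows)
#' @param x a \linkS4class{RasterImage}
#' @return integer
#' @export
setGeneric("imageHeight", function(x) standardGeneric("imageHeight"))

#' Image width (pixel columns)
#' @param x a \linkS4class{RasterImage}
#' @return integer
#' @export
setGeneric("imageWidth", function(x) standardGeneric("imageWidth"))

#' Pixel array accessor
#' @param x a \linkS4class{RasterImage}
#' @return integer array \code{J x K x 3}
#' @export
setGeneric("pixelArray", function(x) standardGeneric("pixelArray"))

#' Number of subimages in a grid
#' @param x a \linkS4class{ROIGrid}
#' @return integer \code{roi1 * roi2}
#' @export
setGeneric("nSubimages", function(x) standardGeneric("nSubimages"))

#' Feature matrix accessor
#' @param x a \linkS4class{FeatureMatrix}
#' @return numeric matrix (samples x features)
#' @export
setGeneric("featureValues", function(x) standardGeneric("featureValues"))

#' Response vector accessor
#' @param x a \linkS4class{FeatureMatrix}
#' @return numeric vector
#' @export
setGeneric("response", function(x) standardGeneric("response"))

#' @rdname imageHeight
setMethod("imageHeight", "RasterImage", function(x) dim(x@pixels)[1])

#' @rdname imageWidth
setMethod("imageWidth", "RasterImage", function(x) dim(x@pixels)[2])

#' @rdname pixelArray
setMethod("pixelArray", "RasterImage", function(x) x@pixels)

#' @rdname nSubimages
setMethod("nSubimages", "ROIGrid", function(x) x@roi1 * x@roi2)

#' @rdname featureValues
setMethod("featureValues", "FeatureMatrix", function(x) x@X)

#' @rdname response
setMethod("response", "FeatureMatrix", function(x) x@y)

setMethod("show", "RasterImage", function(object) {
    d <- dim(object@pixels)
    cat("RasterImage:", d[1], "x", d[2], "pixels, 24-bit RGB\n")
})

setMethod("show", "ROIGrid", function(object) {
    cat("ROIGrid:", object@roi2, "rows x", object@roi1, "columns (",
        nSubimages(object), "subimages )\n")
    cat("  row bounds:", paste(object@rowBounds, collapse = " "), "\n")
    cat("  col bounds:", paste(object@colBounds, collapse = " "), "\n")
})

setMethod("show", "FeatureMatrix", function(object) {
    cat("FeatureMatrix:", nrow(object@X), "samples x", ncol(object@X),
        "features\n")
    cat("  channels:", paste(object@channels, collapse = ", "),
        "(", object@binsPerChannel, "bins each )\n")
    cat("  response range:", paste(signif(range(object@y), 4),
        collapse = " - "), "\n")
})

setMethod("show", "PLSModel", function(object) {
    cat("PLSModel: PLS1 (NIPALS, mean-centered),", object@nLV,
        "latent variable(s),", length(object@coef), "features\n")
})

setMethod("show", "MeritReport", function(object) {
    cat("MeritReport (LV =", object@nLV, ")\n")
    cat(sprintf("  RMSECV %.4g  REPcv %.4g  R2cv %.4g\n",
        object@rmsecv, object@repCV, object@r2CV))
    if (!is.na(object@rmsep))
        cat(sprintf("  RMSEP  %.4g  REP   %.4g  R2   %.4g\n",
            object@rmsep, object@rep, object@r2))
    if (!is.na(object@tCal))
        cat(sprintf("  bias %.4g  t_cal %.4g  t_crit %.4g (%s)\n",
            object@bias, object@tCal, object@tCrit,
            if (object@biasSignificant) "significant" else "absent"))
})

setMethod("show", "GARunResult", function(object) {
    cat("GARunResult: best RMSECV", signif(object@bestFitness, 5),
        "with", sum(object@bestGenes), "subimage(s) selected\n")
    cat("  generations:", length(object@bestPerGeneration),
        " fitness evaluations:", object@nEvaluations,
        " seed:", object@seed, "\n")
})

setMethod("show", "GAConfig", function(object) {
    cat("GAConfig: p =", object@popSize, ", g =", object@generations,
        "\n  elitism", object@elitismRate, " crossover",
        object@crossoverRate, " mutation", object@mutationRate,
        " Nim", object@nim, " restarts", object@nRestarts, "\n")
})

setMethod("show", "SyntheticSpec", function(object) {
    cat("SyntheticSpec:", object@nSamples, "samples,",
        object@height, "x", object@width, "px,",
        object@roi2, "x", object@roi1, "grid,",
        nrow(object@informativeCells), "informative cell(s)\n")
})
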