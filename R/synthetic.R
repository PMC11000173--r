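# Synthetic chromatogram-like images with planted, response-correlated
# regions. Rendered the way real 2D chromatogram images are: a scalar
# intensity field (baseline + peaks + noise) mapped through a pseudo-color
# colormap to 24-bit RGB, so color-histogram features arise from an
# intensity-to-color mapping exactly as they do for instrument data.

#' Synthetic-set specification
#'
#' Defaults emulate the wine study conditions: 38 samples, 705 x 1195 px
#' images on a 5 x 5 grid, responses (ages) spanning 6--34 years, two
#' informative cells at grid positions (2, 3) and (1, 4). Background
#' peaks shared by
#' all samples stand in for the matrix compounds every wine carries, so a
#' full-image model works but is beatable by ROI selection.
#'
#' @param nSamples sample count.
#' @param height,width image size in pixels.
#' @param roi1,roi2 grid columns / rows.
#' @param informativeCells matrix (or 2-vector) of 1-based (row, col)
#'   grid cells that carry response-correlated signal.
#' @param peaksPerCell Gaussian peaks planted per informative cell.
#' @param peakSigma peak width, pixels.
#' @param gain peak amplitude per year of response (intensity units).
#' @param noiseSigma pixel noise standard deviation (intensity units).
#' @param yRange response range, years.
#' @param nBackgroundPeaks shared response-independent peaks.
#' @param backgroundAmplitude their intensity.
#' @param baseline background intensity level.
#' @param colormap colormap name (currently \code{"jet"}).
#' @return A \linkS4class{SyntheticSpec}.
#' @export
syntheticSpec <- function(nSamples = 38, height = 705, width = 1195,
                          roi1 = 5, roi2 = 5,
                          informativeCells = rbind(c(2, 3), c(1, 4)),
                          peaksPerCell = 3, peakSigma = 6, gain = 3,
                          noiseSigma = 6, yRange = c(6, 34),
                          nBackgroundPeaks = 40,
                          backgroundAmplitude = 90, baseline = 15,
                          colormap = "jet") {
    ic <- informativeCells
    if (!is.matrix(ic)) ic <- matrix(ic, ncol = 2, byrow = TRUE)
    storage.mode(ic) <- "integer"
    colnames(ic) <- c("row", "col")
    new("SyntheticSpec", nSamples = as.integer(nSamples),
        height = as.integer(height), width = as.integer(width),
        roi1 = as.integer(roi1), roi2 = as.integer(roi2),
        informativeCells = ic, peaksPerCell = as.integer(peaksPerCell),
        peakSigma = peakSigma, gain = gain, noiseSigma = noiseSigma,
        yRange = as.numeric(yRange),
        nBackgroundPeaks = as.integer(nBackgroundPeaks),
        backgroundAmplitude = backgroundAmplitude, baseline = baseline,
        colormap = colormap)
}

#' 256-entry colormap lookup table
#'
#' \code{"jet"} is the classic blue-cyan-yellow-red heat-map ramp used to
#' render chromatogram intensity maps.
#'
#' @param name colormap name.
#' @return integer matrix 256 x 3 of RGB values in 0--255.
#' @export
colormapLUT <- function(name = "jet") {
    if (name != "jet") stop("unknown colormap: ", name)
    x <- seq(0, 1, length.out = 256)
    clamp <- function(v) pmin(pmax(v, 0), 1)
    lut <- cbind(R = clamp(1.5 - abs(4 * x - 3)),
                 G = clamp(1.5 - abs(4 * x - 2)),
                 B = clamp(1.5 - abs(4 * x - 1)))
    round(lut * 255)
}

# Add a Gaussian peak in place over a +-4 sigma window.
addPeak <- function(field, r0, c0, amp, sigma) {
    J <- nrow(field); K <- ncol(field)
    w <- ceiling(4 * sigma)
    rows <- max(1L, r0 - w):min(J, r0 + w)
    cols <- max(1L, c0 - w):min(K, c0 + w)
    g <- exp(-outer((rows - r0)^2, (cols - c0)^2, "+") / (2 * sigma^2))
    field[rows, cols] <- field[rows, cols] + amp * g
    field
}

#' Generate a synthetic image set
#'
#' Per sample: the response is drawn uniformly over \code{yRange}; a
#' scalar intensity field is built from baseline Gaussian noise, shared
#' response-independent background peaks (same positions and base
#' amplitudes in every sample, with mild per-sample amplitude jitter), and
#' Gaussian peaks inside the informative cells whose amplitude is
#' \code{gain * y} plus noise; the field is clipped to 0--255 and mapped
#' through the colormap to 24-bit RGB. Bit-reproducible from \code{seed}.
#'
#' @param spec a \linkS4class{SyntheticSpec}.
#' @param seed integer RNG seed.
#' @return list with \code{images} (list of \linkS4class{RasterImage}),
#'   \code{y} (numeric, years), \code{grid} (the \linkS4class{ROIGrid}),
#'   \code{truth} (linear indices of the informative cells) and
#'   \code{spec}.
#' @export
generateSyntheticSet <- function(spec, seed = 1L) {
    set.seed(seed)
    J <- spec@height; K <- spec@width
    grid <- partitionImage(roi1 = spec@roi1, roi2 = spec@roi2,
                           J = J, K = K)
    truth <- sort(as.integer(unfoldIndex(spec@informativeCells[, "row"],
                             spec@informativeCells[, "col"], grid)))
    lut <- colormapLUT(spec@colormap)
    y <- runif(spec@nSamples, spec@yRange[1], spec@yRange[2])
    # shared structure: background peak positions/amplitudes, planted
    # peak positions inside their cells
    bg <- data.frame(
        r = sample.int(J, spec@nBackgroundPeaks, replace = TRUE),
        c = sample.int(K, spec@nBackgroundPeaks, replace = TRUE),
        a = spec@backgroundAmplitude *
            runif(spec@nBackgroundPeaks, 0.5, 1.5))
    # planted peaks are inset 4 sigma from the cell border so their mass
    # stays inside the informative cell and the ground truth is crisp
    planted <- do.call(rbind, lapply(truth, function(cell) {
        blk <- cellPixelBlock(grid, cell)
        inset <- function(v) {
            m <- ceiling(4 * spec@peakSigma)
            if (length(v) > 2 * m + 1) v[(m + 1):(length(v) - m)] else v
        }
        data.frame(
            r = sample(inset(blk$rows), spec@peaksPerCell, replace = TRUE),
            c = sample(inset(blk$cols), spec@peaksPerCell, replace = TRUE))
    }))
    images <- vector("list", spec@nSamples)
    for (i in seq_len(spec@nSamples)) {
        field <- matrix(rnorm(J * K, spec@baseline, spec@noiseSigma),
                        J, K)
        jitter <- runif(nrow(bg), 0.9, 1.1)
        for (p in seq_len(nrow(bg)))
            field <- addPeak(field, bg$r[p], bg$c[p],
                             bg$a[p] * jitter[p], spec@peakSigma)
        amp <- spec@gain * y[i] +
            rnorm(nrow(planted), 0, spec@noiseSigma)
        for (p in seq_len(nrow(planted)))
            field <- addPeak(field, planted$r[p], planted$c[p],
                             amp[p], spec@peakSigma)
        idx <- pmin(pmax(floor(field), 0), 255) + 1L
        px <- array(0L, dim = c(J, K, 3L))
        px[, , 1] <- lut[idx, 1]
        px[, , 2] <- lut[idx, 2]
        px[, , 3] <- lut[idx, 3]
        images[[i]] <- RasterImage(px)
    }
    list(images = images, y = y, grid = grid, truth = truth, spec = spec)
}

#' Wine sample roster (38 Tokaj samples)
#'
#' The packaged sample table: identifier, producer, wine category, vintage
#' year and the published calibration/prediction set label (C = 28
#' calibration, P = 10 prediction samples). Wine age is computed as
#' \code{referenceYear - vintage}.
#'
#' @param referenceYear year against which age is computed (default 2023).
#' @return data.frame with columns \code{sample_id, producer, category,
#'   vintage, set_label, age}.
#' @export
wineSampleTable <- function(referenceYear = 2023) {
    path <- system.file("extdata", "tokaj_samples.csv",
                        package = "chromROI", mustWork = TRUE)
    tab <- utils::read.csv(path, stringsAsFactors = FALSE)
    tab$age <- referenceYear - tab$vintage
    tab
}

#' Jaccard recovery score of a selection against the planted truth
#'
#' \code{|selected intersect truth| / |selected union truth|}: 1 for exact
#' recovery, 0 for disjoint sets.
#'
#' @param selected integer indices (or a 0/1 gene vector) of selected
#'   subimages.
#' @param truth integer indices of the planted informative cells.
#' @return numeric in [0, 1].
#' @export
recoveryScore <- function(selected, truth) {
    if (all(selected %in% c(0L, 1L)) && length(selected) > length(truth))
        selected <- which(selected == 1L)
    length(intersect(selected, truth)) / length(union(selected, truth))
}
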