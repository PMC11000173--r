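# End-to-end pipeline: sample table in, Table-2-shaped merit reports out.
# Ties together image loading, grid partition, SPXY (or published labels),
# GA search, merit reporting and interval refinement, with every output
# stamped with the seed that produced it.

#' Read a sample table
#'
#' CSV with columns \code{sample_id}, \code{y} (response, e.g. age in
#' years), optional \code{image_path} and optional \code{set_label}
#' (\code{C} = calibration, \code{P} = prediction).
#'
#' @param path CSV path.
#' @param imageDir optional directory to resolve relative image paths
#'   against.
#' @return data.frame.
#' @export
readSampleTable <- function(path, imageDir = NULL) {
    tab <- utils::read.csv(path, stringsAsFactors = FALSE)
    need <- c("sample_id", "y")
    miss <- setdiff(need, names(tab))
    if (length(miss))
        stop("sample table lacks column(s): ", paste(miss, collapse = ", "))
    if (!is.null(imageDir) && "image_path" %in% names(tab))
        tab$image_path <- file.path(imageDir, tab$image_path)
    tab
}

#' Read a run configuration file
#'
#' A YAML file whose keys override the pipeline defaults (which mirror
#' the reported chromatogram run: 5 x 5 and 10 x 10 grid sweep, RGB
#' channels, GA 100/100 with mutation 0.05 and crossover 0.65, 10
#' restarts, 28 calibration samples).
#'
#' @param path YAML file path, or \code{NULL} for pure defaults.
#' @return named list of settings.
#' @export
readRunConfig <- function(path = NULL) {
    defaults <- list(
        grids = list(c(5, 5), c(10, 10)),
        channels = c("R", "G", "B"),
        popSize = 100, generations = 100, elitismRate = 0.10,
        crossoverRate = 0.65, mutationRate = 0.05, nim = NA,
        nRestarts = 10, nLV = 2, lvMax = 5,
        nCal = 28, useLabels = TRUE,
        nIntervals = 48, maxIntervals = 3,
        masterSeed = 1)
    if (is.null(path)) return(defaults)
    user <- yaml::read_yaml(path)
    bad <- setdiff(names(user), names(defaults))
    if (length(bad))
        stop("unknown configuration key(s): ", paste(bad, collapse = ", "))
    # wholesale replacement (not modifyList: nested lists such as
    # `grids` must be overridden, not merged element-wise)
    for (k in names(user)) defaults[[k]] <- user[[k]]
    defaults
}

#' Write a synthetic dataset to disk
#'
#' Generates a synthetic image set and writes one image per sample, a
#' sample-table CSV in the dialect [runROISelection()] consumes, and the
#' generator settings as YAML for provenance. Same spec + seed always
#' produce identical files.
#'
#' @param spec a \linkS4class{SyntheticSpec}.
#' @param dir output directory (created if needed).
#' @param seed integer RNG seed.
#' @param format \code{"bmp"} or \code{"png"}.
#' @return invisibly, the sample table data.frame.
#' @export
simulateToDisk <- function(spec, dir, seed = 1L, format = "bmp") {
    dir.create(dir, recursive = TRUE, showWarnings = FALSE)
    ss <- generateSyntheticSet(spec, seed)
    paths <- sprintf("sample_%02d.%s", seq_along(ss$images), format)
    for (i in seq_along(ss$images))
        writeChromImage(ss$images[[i]], file.path(dir, paths[i]))
    tab <- data.frame(sample_id = seq_along(ss$images),
                      image_path = paths, y = ss$y)
    utils::write.csv(tab, file.path(dir, "samples.csv"),
                     row.names = FALSE, quote = FALSE)
    yaml::write_yaml(list(
        seed = as.integer(seed), nSamples = spec@nSamples,
        height = spec@height, width = spec@width,
        roi1 = spec@roi1, roi2 = spec@roi2,
        informativeCells = apply(spec@informativeCells, 1L, paste,
                                 collapse = ","),
        gain = spec@gain, noiseSigma = spec@noiseSigma,
        yRange = spec@yRange, colormap = spec@colormap),
        file.path(dir, "spec.yaml"))
    invisible(tab)
}

# Calibration/prediction indices: published labels when present and
# requested, SPXY on full-image features otherwise.
resolveSplit <- function(tab, Xfull, y, nCal, useLabels) {
    if (useLabels && "set_label" %in% names(tab) &&
        !anyNA(tab$set_label)) {
        list(calibration = which(tab$set_label == "C"),
             prediction = which(tab$set_label == "P"),
             source = "labels")
    } else {
        s <- spxySplit(Xfull, y, nCal)
        s$source <- "spxy"
        s
    }
}

#' Run the full ROI-selection pipeline
#'
#' For each grid in the sweep: per-cell histograms are cached, the sample
#' set is split into calibration and prediction (published labels or
#' SPXY), the GA is run best-of-\code{nRestarts} on the calibration set,
#' and merit reports are produced for the GA-selected model and for the
#' full-image baseline (the all-ones chromosome). When \code{outputDir}
#' is given, a Table-2-shaped merit CSV, selected-ROI CSVs and
#' per-generation RMSECV traces are written, all stamped with the seed.
#'
#' @param images list of \linkS4class{RasterImage}s, aligned with
#'   \code{tab} rows; if \code{NULL}, images are read from
#'   \code{tab$image_path}.
#' @param tab sample table data.frame (see [readSampleTable()]).
#' @param grids list of \code{c(roi1, roi2)} pairs to sweep.
#' @param config a \linkS4class{GAConfig}.
#' @param nCal calibration-set size for SPXY (ignored when labels are
#'   used).
#' @param useLabels honor a \code{set_label} column when present.
#' @param masterSeed master RNG seed; per-grid GA seeds derive from it.
#' @param outputDir optional report directory.
#' @return list with one element per grid (\code{grid}, \code{split},
#'   \code{ga}, \code{reports}, \code{roiTable}) plus \code{meritTable},
#'   a combined data.frame over all grids and baselines.
#' @export
runROISelection <- function(images = NULL, tab, grids = list(c(5, 5)),
                            config = gaConfig(), nCal = 28,
                            useLabels = TRUE, masterSeed = 1L,
                            outputDir = NULL) {
    if (is.null(images)) {
        if (!"image_path" %in% names(tab))
            stop("no images supplied and no image_path column")
        missing <- !file.exists(tab$image_path)
        if (any(missing))
            stop("missing image for sample(s): ",
                 paste(tab$sample_id[missing], collapse = ", "))
        images <- lapply(tab$image_path, readChromImage)
    }
    y <- tab$y
    if (sd(y) == 0) stop("degenerate response: y has zero variance")
    set.seed(masterSeed)
    gridSeeds <- sample.int(.Machine$integer.max, length(grids))
    results <- list()
    merit_rows <- list()
    for (gi in seq_along(grids)) {
        roi1 <- grids[[gi]][1]; roi2 <- grids[[gi]][2]
        gname <- sprintf("GA (%d x %d)", roi1, roi2)
        grid <- partitionImage(images[[1]], roi1 = roi1, roi2 = roi2)
        cache <- cellHistogramCache(images, grid, config@channels,
                                    sampleIds = as.character(tab$sample_id))
        Xfull <- pooledFeatures(cache, seq_len(nSubimages(grid)))
        split <- resolveSplit(tab, Xfull, y, nCal, useLabels)
        cal <- split$calibration; prd <- split$prediction
        calCache <- cache[, , cal, drop = FALSE]
        attr(calCache, "channels") <- attr(cache, "channels")
        attr(calCache, "sampleIds") <- attr(cache, "sampleIds")[cal]
        ga <- runRestarts(calCache, y[cal], config,
                          masterSeed = gridSeeds[gi])
        sel <- which(ga$best@bestGenes == 1L)
        Xsel <- pooledFeatures(cache, sel)
        lvRule <- function(Xc, yc) {
            cap <- min(nrow(Xc) - 2L, ncol(Xc), config@lvMax)
            if (!is.na(config@nLV)) min(config@nLV, cap)
            else selectLV(Xc, yc, cap)$nLV
        }
        mkReport <- function(Xall) {
            nlv <- lvRule(Xall[cal, , drop = FALSE], y[cal])
            meritReport(Xall[cal, , drop = FALSE], y[cal], nlv,
                        if (length(prd)) Xall[prd, , drop = FALSE],
                        if (length(prd)) y[prd])
        }
        reports <- list()
        if (gi == 1L)
            reports[["Full image"]] <- mkReport(Xfull)
        reports[[gname]] <- mkReport(Xsel)
        roiTab <- selectedROITable(ga$best@bestGenes, grid)
        results[[gname]] <- list(grid = grid, split = split, ga = ga,
                                 reports = reports, roiTable = roiTab,
                                 seed = gridSeeds[gi])
        mt <- meritTable(reports)
        mt$grid <- gname
        mt$seed <- masterSeed
        mt$channels <- paste(config@channels, collapse = "")
        merit_rows[[gi]] <- mt
        if (!is.null(outputDir)) {
            dir.create(outputDir, recursive = TRUE, showWarnings = FALSE)
            stem <- sprintf("grid_%dx%d", roi1, roi2)
            roiTab$seed <- masterSeed
            utils::write.csv(roiTab,
                file.path(outputDir, paste0(stem, "_selected_roi.csv")),
                row.names = FALSE, quote = FALSE)
            trace <- do.call(cbind, lapply(ga$runs, function(r)
                r@bestPerGeneration))
            colnames(trace) <- paste0("run_", seq_along(ga$runs))
            utils::write.csv(data.frame(generation =
                seq_len(nrow(trace)), trace),
                file.path(outputDir, paste0(stem, "_rmsecv_trace.csv")),
                row.names = FALSE, quote = FALSE)
        }
    }
    merit <- do.call(rbind, merit_rows)
    rownames(merit) <- NULL
    if (!is.null(outputDir))
        utils::write.csv(merit, file.path(outputDir, "merit_table.csv"),
                         row.names = FALSE, quote = FALSE)
    c(results, list(meritTable = merit))
}

#' Interval refinement of a pipeline result
#'
#' Runs iPLS and iSPA-PLS on the calibration-set features of the winning
#' chromosome of one grid from [runROISelection()].
#'
#' @param result one grid element of a [runROISelection()] return value.
#' @param cache the matching per-cell histogram cache, or the images and
#'   sample table to rebuild features from; simplest is to pass the
#'   original \code{images}/\code{tab} used for the pipeline.
#' @param images,tab original pipeline inputs (used when \code{cache} is
#'   \code{NULL}).
#' @param nIntervals number of feature intervals.
#' @param maxIntervals largest iSPA-PLS combination.
#' @param lvMax LV search ceiling.
#' @param outputDir optional directory for interval CSV tables.
#' @return list with \code{ipls} (interval table) and \code{ispa}.
#' @export
runIntervalRefinement <- function(result, cache = NULL, images = NULL,
                                  tab = NULL, nIntervals = 48,
                                  maxIntervals = 3, lvMax = 5,
                                  outputDir = NULL) {
    if (is.null(cache)) {
        stopifnot(!is.null(images), !is.null(tab))
        cache <- cellHistogramCache(images, result$grid,
            sampleIds = as.character(tab$sample_id))
    }
    sel <- which(result$ga$best@bestGenes == 1L)
    X <- pooledFeatures(cache, sel)
    cal <- result$split$calibration
    yc <- if (!is.null(tab)) tab$y[cal] else
        stop("sample table required for the response")
    Xc <- X[cal, , drop = FALSE]
    part <- makeIntervals(ncol(Xc), nIntervals)
    ip <- ipls(Xc, yc, part, lvMax = lvMax)
    sp <- ispaPLS(Xc, yc, part, maxIntervals = maxIntervals,
                  lvMax = lvMax)
    if (!is.null(outputDir)) {
        dir.create(outputDir, recursive = TRUE, showWarnings = FALSE)
        ipOut <- ip
        ipOut$seed <- result$seed
        utils::write.csv(ipOut, file.path(outputDir, "ipls_table.csv"),
                         row.names = FALSE, quote = FALSE)
        utils::write.csv(sp$candidates,
                         file.path(outputDir, "ispa_candidates.csv"),
                         row.names = FALSE, quote = FALSE)
    }
    list(ipls = ip, ispa = sp)
}
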