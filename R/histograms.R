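# Color-frequency histogram features. A chromosome's feature vector is one
# pooled 256-bin histogram per channel over the union of its selected
# subimages, concatenated in the declared channel order, so the feature
# length is the same for every chromosome and one PLS architecture serves
# the whole search.

#' Histogram of one channel over a set of pixel blocks
#'
#' @param channelGrid integer matrix of intensities in 0--255.
#' @param blocks list of pixel blocks, each a list with integer vectors
#'   \code{rows} and \code{cols} (1-based).
#' @return numeric vector of length 256; bin \code{b + 1} counts pixels of
#'   intensity \code{b}; bins sum to the pooled pixel count.
#' @export
channelHistogram <- function(channelGrid, blocks) {
    if (length(blocks) == 0L)
        stop("empty mask: at least one pixel block is required")
    vals <- unlist(lapply(blocks, function(b) {
        if (any(b$rows > nrow(channelGrid)) ||
            any(b$cols > ncol(channelGrid)))
            stop("pixel block outside the grid")
        channelGrid[b$rows, b$cols]
    }), use.names = FALSE)
    if (any(vals < 0L) || any(vals > 255L))
        stop("intensities must lie in [0, 255]")
    tabulate(vals + 1L, nbins = 256L)
}

#' Pooled histogram feature vector for selected subimages
#'
#' Pools the pixels of all selected subimages and computes one 256-bin
#' frequency histogram per channel, concatenated in the order of
#' \code{channels}. The feature length \code{256 * length(channels)} does
#' not depend on how many subimages are selected.
#'
#' @param img a \linkS4class{RasterImage}.
#' @param grid a \linkS4class{ROIGrid}.
#' @param selected integer vector of linear subimage indices (non-empty).
#' @param channels character subset of
#'   \code{c("R","G","B","gray","H","S","V")}; default RGB.
#' @return named numeric vector of length \code{256 * length(channels)};
#'   names are \code{<channel>_<bin>} with 3-digit zero-padded bins.
#' @export
roiHistogram <- function(img, grid, selected = seq_len(nSubimages(grid)),
                         channels = c("R", "G", "B")) {
    if (length(selected) == 0L)
        stop("empty subimage selection (invalid chromosome)")
    selected <- sort(unique(as.integer(selected)))
    blocks <- lapply(selected, function(i) cellPixelBlock(grid, i))
    grids <- channelGrids(img, channels)
    v <- unlist(lapply(grids, channelHistogram, blocks = blocks),
                use.names = FALSE)
    names(v) <- featureNames(channels)
    v
}

featureNames <- function(channels) {
    as.vector(vapply(channels,
        function(ch) sprintf("%s_%03d", ch, 0:255), character(256)))
}

#' Assemble the sample-by-feature matrix for a fixed subimage selection
#'
#' @param images list of \linkS4class{RasterImage}s sharing dimensions.
#' @param y numeric response vector (e.g. wine age in years).
#' @param grid a \linkS4class{ROIGrid}.
#' @param selected integer vector of subimage indices; default all.
#' @param channels channel selection as in [roiHistogram()].
#' @param sampleIds character ids; default \code{"s1", "s2", ...}.
#' @return A \linkS4class{FeatureMatrix}.
#' @export
buildFeatureMatrix <- function(images, y, grid,
                               selected = seq_len(nSubimages(grid)),
                               channels = c("R", "G", "B"),
                               sampleIds = paste0("s", seq_along(images))) {
    stopifnot(length(images) == length(y), all(is.finite(y)))
    d0 <- c(imageHeight(images[[1]]), imageWidth(images[[1]]))
    for (i in seq_along(images)) {
        di <- c(imageHeight(images[[i]]), imageWidth(images[[i]]))
        if (!identical(di, d0))
            stop("image dimensions of sample '", sampleIds[i],
                 "' (", di[1], " x ", di[2],
                 ") differ from the first sample (", d0[1], " x ",
                 d0[2], ")")
    }
    X <- t(vapply(images,
        function(im) roiHistogram(im, grid, selected, channels),
        numeric(256L * length(channels))))
    rownames(X) <- sampleIds
    new("FeatureMatrix", X = X, y = as.numeric(y),
        sampleIds = sampleIds, channels = channels,
        binsPerChannel = 256L)
}

#' Precompute per-cell histograms for fast subset evaluation
#'
#' The genetic algorithm evaluates thousands of subimage subsets; because
#' pooled histograms are additive over disjoint cells, per-cell histograms
#' computed once allow any subset's feature matrix to be formed by summing
#' rows. Returns a 3-D array \code{[cell, feature, sample]}.
#'
#' @inheritParams buildFeatureMatrix
#' @return numeric array \code{nSubimages x (256 * nChannels) x nSamples}
#'   with attributes \code{channels} and \code{sampleIds}.
#' @export
cellHistogramCache <- function(images, grid, channels = c("R", "G", "B"),
                               sampleIds = paste0("s", seq_along(images))) {
    n_cells <- nSubimages(grid)
    n_feat <- 256L * length(channels)
    out <- array(0, dim = c(n_cells, n_feat, length(images)))
    blocks <- lapply(seq_len(n_cells), function(i) cellPixelBlock(grid, i))
    for (s in seq_along(images)) {
        grids <- channelGrids(images[[s]], channels)
        for (cell in seq_len(n_cells)) {
            out[cell, , s] <- unlist(lapply(grids, channelHistogram,
                blocks = blocks[cell]), use.names = FALSE)
        }
    }
    attr(out, "channels") <- channels
    attr(out, "sampleIds") <- sampleIds
    out
}

# Feature matrix (samples x features) for a subset of cells, from a cache.
pooledFeatures <- function(cache, selected) {
    if (length(selected) == 0L)
        stop("empty subimage selection (invalid chromosome)")
    n_samples <- dim(cache)[3]
    if (length(selected) == 1L) {
        X <- t(cache[selected, , ])
        if (n_samples == 1L) X <- matrix(X, nrow = 1L)
    } else {
        X <- t(apply(cache[selected, , , drop = FALSE], 3L, colSums))
        if (n_samples == 1L) X <- matrix(X, nrow = 1L)
    }
    colnames(X) <- featureNames(attr(cache, "channels"))
    rownames(X) <- attr(cache, "sampleIds")
    X
}

#' Write / read a FeatureMatrix as CSV
#'
#' Columns: \code{sample_id}, \code{y}, then the layout-tagged bin columns
#' (\code{R_000} ... \code{B_255} for an RGB layout).
#'
#' @param fm a \linkS4class{FeatureMatrix}.
#' @param path CSV file path.
#' @return \code{exportFeatureMatrix}: \code{path}, invisibly.
#' @export
exportFeatureMatrix <- function(fm, path) {
    df <- data.frame(sample_id = fm@sampleIds, y = fm@y,
                     fm@X, check.names = FALSE)
    utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
    invisible(path)
}

#' @rdname exportFeatureMatrix
#' @return \code{readFeatureMatrix}: a \linkS4class{FeatureMatrix}.
#' @export
readFeatureMatrix <- function(path) {
    df <- utils::read.csv(path, check.names = FALSE)
    X <- as.matrix(df[, -(1:2), drop = FALSE])
    rownames(X) <- df$sample_id
    channels <- unique(sub("_[0-9]+$", "", colnames(X)))
    new("FeatureMatrix", X = X, y = as.numeric(df$y),
        sampleIds = as.character(df$sample_id), channels = channels,
        binsPerChannel = as.integer(ncol(X) / length(channels)))
}
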