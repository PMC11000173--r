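# Grid partition of an image into subimages (regions of interest) and the
# row-major unfolding that maps grid cells onto positions of the candidate
# vector searched by the genetic algorithm.

#' Partition an image into a grid of subimages
#'
#' Splits a \code{J x K} image into \code{roi2} rows and \code{roi1}
#' columns. Boundaries are \code{floor(i * dim / roi)}, giving near-equal
#' blocks (sizes differ by at most one pixel per axis) with no dropped
#' pixels. Boundaries depend only on the image dimensions, never on pixel
#' content.
#'
#' @param img a \linkS4class{RasterImage}, or \code{NULL} if \code{J} and
#'   \code{K} are given directly.
#' @param roi1 number of grid columns.
#' @param roi2 number of grid rows.
#' @param J,K image height and width in pixels; taken from \code{img} when
#'   supplied.
#' @return A \linkS4class{ROIGrid}.
#' @examples
#' g <- partitionImage(roi1 = 5, roi2 = 10, J = 705, K = 1195)
#' g@rowBounds   # 0, 70, 141, ..., 705
#' @export
partitionImage <- function(img = NULL, roi1, roi2, J = NULL, K = NULL) {
    if (!is.null(img)) {
        J <- imageHeight(img); K <- imageWidth(img)
    }
    stopifnot(!is.null(J), !is.null(K))
    roi1 <- as.integer(roi1); roi2 <- as.integer(roi2)
    if (roi2 < 1L || roi2 > J)
        stop("roi2 must lie in [1, image height = ", J, "]")
    if (roi1 < 1L || roi1 > K)
        stop("roi1 must lie in [1, image width = ", K, "]")
    new("ROIGrid", roi1 = roi1, roi2 = roi2,
        rowBounds = as.integer(floor(seq(0L, roi2) * J / roi2)),
        colBounds = as.integer(floor(seq(0L, roi1) * K / roi1)))
}

#' Map a grid cell to its position in the unfolded candidate vector
#'
#' The grid is unfolded row-major with row 1 at the top of the image:
#' \code{index = (row - 1) * roi1 + col}. This order is declared once and
#' used everywhere ROI labels appear.
#'
#' @param row,col 1-based grid coordinates.
#' @param grid a \linkS4class{ROIGrid}.
#' @return 1-based linear index in \code{[1, roi1 * roi2]}.
#' @seealso [foldIndex()] for the inverse.
#' @export
unfoldIndex <- function(row, col, grid) {
    if (any(row < 1L) || any(row > grid@roi2) ||
        any(col < 1L) || any(col > grid@roi1))
        stop("grid coordinates out of range")
    (row - 1L) * grid@roi1 + col
}

#' Recover (row, col) grid coordinates from a linear index
#'
#' @param index 1-based linear index.
#' @param grid a \linkS4class{ROIGrid}.
#' @return integer matrix with columns \code{row}, \code{col}.
#' @export
foldIndex <- function(index, grid) {
    if (any(index < 1L) || any(index > nSubimages(grid)))
        stop("linear index out of range")
    idx0 <- as.integer(index) - 1L
    cbind(row = idx0 %/% grid@roi1 + 1L, col = idx0 %% grid@roi1 + 1L)
}

# Half-open pixel block of one cell: list(rows = r0:(r1-1)+1, cols = ...)
# in 1-based R indexing.
cellPixelBlock <- function(grid, index) {
    rc <- foldIndex(index, grid)
    r <- rc[1, "row"]; c <- rc[1, "col"]
    list(rows = (grid@rowBounds[r] + 1L):grid@rowBounds[r + 1L],
         cols = (grid@colBounds[c] + 1L):grid@colBounds[c + 1L])
}

#' Table of subimage pixel bounds
#'
#' One row per grid cell with 1-based (row, col) labels and half-open
#' 0-based pixel offsets, matching the internal partition exactly.
#'
#' @param grid a \linkS4class{ROIGrid}.
#' @return data.frame with columns \code{index, row, col, y0, y1, x0, x1}.
#' @export
gridBoundsTable <- function(grid) {
    idx <- seq_len(nSubimages(grid))
    rc <- foldIndex(idx, grid)
    data.frame(
        index = idx, row = rc[, "row"], col = rc[, "col"],
        y0 = grid@rowBounds[rc[, "row"]],
        y1 = grid@rowBounds[rc[, "row"] + 1L],
        x0 = grid@colBounds[rc[, "col"]],
        x1 = grid@colBounds[rc[, "col"] + 1L])
}

#' Export a grid preview
#'
#' Writes a copy of the image with grid lines burned in (white, one pixel
#' wide) and a CSV of subimage bounds, for visual verification of the
#' partition before running a search.
#'
#' @param img a \linkS4class{RasterImage}.
#' @param grid a \linkS4class{ROIGrid} partitioning \code{img}.
#' @param imagePath output image path (\code{.png} or \code{.bmp}).
#' @param csvPath output CSV path for [gridBoundsTable()].
#' @return invisibly, the bounds table.
#' @export
writeGridPreview <- function(img, grid, imagePath, csvPath) {
    px <- pixelArray(img)
    inner_r <- grid@rowBounds[-c(1L, length(grid@rowBounds))]
    inner_c <- grid@colBounds[-c(1L, length(grid@colBounds))]
    px[inner_r + 1L, , ] <- 255L
    px[, inner_c + 1L, ] <- 255L
    writeChromImage(RasterImage(px), imagePath)
    tab <- gridBoundsTable(grid)
    utils::write.csv(tab, csvPath, row.names = FALSE, quote = FALSE)
    invisible(tab)
}
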