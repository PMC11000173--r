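# Color-model conversions. All converted channels are quantized to the
# integer range 0..255 so every channel shares the same 256-bin histogram
# domain.

#' Convert an RGB image to 8-bit grayscale
#'
#' Uses the ITU-R 601 luma weights: \code{round(0.299 R + 0.587 G +
#' 0.114 B)}.
#'
#' @param img a \linkS4class{RasterImage}.
#' @return integer matrix \code{J x K} of intensities in 0--255.
#' @export
toGrayscale <- function(img) {
    px <- pixelArray(img)
    g <- round(0.299 * px[, , 1] + 0.587 * px[, , 2] + 0.114 * px[, , 3])
    g <- matrix(pmin(pmax(g, 0), 255), dim(px)[1], dim(px)[2])
    storage.mode(g) <- "integer"
    g
}

#' Convert an RGB image to quantized HSV
#'
#' Standard hexcone conversion; hue (0--360 degrees), saturation and value
#' (0--1) are each rescaled linearly to 0--255 and rounded, so HSV channels
#' can be histogrammed on the same 256-bin domain as RGB.
#'
#' @param img a \linkS4class{RasterImage}.
#' @return integer array \code{J x K x 3} with channels H, S, V in 0--255.
#' @export
toHSV <- function(img) {
    px <- pixelArray(img)
    d <- dim(px)
    rgb <- rbind(as.vector(px[, , 1]), as.vector(px[, , 2]),
                 as.vector(px[, , 3]))
    hsv <- grDevices::rgb2hsv(rgb, maxColorValue = 255)
    out <- array(0L, dim = d)
    out[, , 1] <- as.integer(round(hsv[1, ] * 255))
    out[, , 2] <- as.integer(round(hsv[2, ] * 255))
    out[, , 3] <- as.integer(round(hsv[3, ] * 255))
    out
}

# Intensity grids for a set of channel names, in the declared order.
# Valid names: "R", "G", "B", "gray", "H", "S", "V".
channelGrids <- function(img, channels) {
    stopifnot(length(channels) >= 1L)
    known <- c("R", "G", "B", "gray", "H", "S", "V")
    bad <- setdiff(channels, known)
    if (length(bad))
        stop("unknown channel(s): ", paste(bad, collapse = ", "))
    px <- pixelArray(img)
    hsv <- if (any(channels %in% c("H", "S", "V"))) toHSV(img) else NULL
    plane <- function(a, k) matrix(a[, , k], dim(a)[1], dim(a)[2])
    lapply(channels, function(ch) switch(ch,
        R = plane(px, 1), G = plane(px, 2), B = plane(px, 3),
        gray = toGrayscale(img),
        H = plane(hsv, 1), S = plane(hsv, 2), V = plane(hsv, 3)))
}
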