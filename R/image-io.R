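# Reading and writing 24-bit raster images (BMP and PNG).
#
# PNG goes through the png package. BMP (the format 2D chromatograms are
# typically exported in) is decoded here directly: only the uncompressed
# 24-bit BITMAPINFOHEADER flavor is accepted, which is what chromatography
# software writes.

#' Read a 24-bit chromatogram image
#'
#' Loads a BMP or PNG file into a \linkS4class{RasterImage}. Only true-color
#' 24-bit images are accepted (a PNG alpha channel is tolerated and
#' dropped); grayscale, palette or 16-bit-per-channel files raise a format
#' error naming the offending property, because histogram features assume
#' 8-bit RGB pixels.
#'
#' @param path file path; format is detected from the file signature.
#' @return A \linkS4class{RasterImage} with channel order red, green, blue.
#' @examples
#' img <- RasterImage(array(255L, dim = c(2, 2, 3)))
#' f <- tempfile(fileext = ".bmp")
#' writeChromImage(img, f)
#' identical(pixelArray(readChromImage(f)), pixelArray(img))
#' @export
readChromImage <- function(path) {
    if (!file.exists(path)) stop("cannot read image file: ", path)
    magic <- readBin(path, "raw", n = 8L)
    png_sig <- as.raw(c(0x89, 0x50, 0x4e, 0x47, 0x0d, 0x0a, 0x1a, 0x0a))
    if (length(magic) >= 2L && rawToChar(magic[1:2]) == "BM")
        return(readBMP(path))
    if (length(magic) >= 8L && identical(magic, png_sig))
        return(readPNGImage(path))
    stop("unsupported image format (not BMP or PNG): ", path)
}

readPNGImage <- function(path) {
    arr <- png::readPNG(path, info = TRUE)
    info <- attr(arr, "info")
    if (!is.null(info$bit.depth) && info$bit.depth > 8L)
        stop("format error: PNG bit depth ", info$bit.depth,
             " per channel; 8-bit true-color required")
    d <- dim(arr)
    if (length(d) == 2L)
        stop("format error: grayscale PNG; 24-bit true-color required")
    if (d[3] == 2L)
        stop("format error: grayscale+alpha PNG; 24-bit true-color required")
    RasterImage(arr[, , 1:3, drop = FALSE] * 255)
}

readBMP <- function(path) {
    con <- file(path, "rb")
    on.exit(close(con))
    if (rawToChar(readBin(con, "raw", 2L)) != "BM")
        stop("format error: not a BMP file: ", path)
    readBin(con, "integer", 2L, size = 4L)          # file size, reserved
    offset <- readBin(con, "integer", 1L, size = 4L)
    hdr_size <- readBin(con, "integer", 1L, size = 4L)
    if (hdr_size < 40L)
        stop("format error: unsupported BMP header size ", hdr_size)
    width <- readBin(con, "integer", 1L, size = 4L)
    height <- readBin(con, "integer", 1L, size = 4L)
    readBin(con, "integer", 1L, size = 2L)          # planes
    bits <- readBin(con, "integer", 1L, size = 2L)
    compression <- readBin(con, "integer", 1L, size = 4L)
    if (bits != 24L)
        stop("format error: BMP bit depth ", bits, "; 24-bit required")
    if (compression != 0L)
        stop("format error: compressed BMP (method ", compression,
             "); uncompressed required")
    top_down <- height < 0L
    height <- abs(height)
    seek(con, offset)
    row_bytes <- ((width * 3L + 3L) %/% 4L) * 4L
    data <- readBin(con, "raw", n = row_bytes * height)
    if (length(data) < row_bytes * height)
        stop("cannot read image file (truncated BMP): ", path)
    bytes <- matrix(as.integer(data), nrow = row_bytes, ncol = height)
    bytes <- bytes[seq_len(width * 3L), , drop = FALSE]   # strip padding
    # columns of `bytes` are image rows, bottom-up unless top_down, BGR
    px <- array(0L, dim = c(height, width, 3L))
    b <- array(bytes, dim = c(3L, width, height))
    rows <- if (top_down) seq_len(height) else rev(seq_len(height))
    px[rows, , 1L] <- t(b[3L, , ])
    px[rows, , 2L] <- t(b[2L, , ])
    px[rows, , 3L] <- t(b[1L, , ])
    RasterImage(px)
}

#' Write a RasterImage to disk
#'
#' @param img a \linkS4class{RasterImage}.
#' @param path output path; format chosen by extension (\code{.bmp} or
#'   \code{.png}).
#' @return \code{path}, invisibly.
#' @export
writeChromImage <- function(img, path) {
    stopifnot(is(img, "RasterImage"))
    ext <- tolower(tools::file_ext(path))
    if (ext == "bmp") writeBMP(img, path)
    else if (ext == "png")
        png::writePNG(pixelArray(img) / 255, path)
    else stop("unsupported output extension: .", ext)
    invisible(path)
}

writeBMP <- function(img, path) {
    px <- pixelArray(img)
    h <- dim(px)[1]; w <- dim(px)[2]
    row_bytes <- ((w * 3L + 3L) %/% 4L) * 4L
    pad <- row_bytes - w * 3L
    # interleave BGR along rows, bottom-up
    b <- array(0L, dim = c(3L, w, h))
    b[1L, , ] <- t(px[rev(seq_len(h)), , 3L])
    b[2L, , ] <- t(px[rev(seq_len(h)), , 2L])
    b[3L, , ] <- t(px[rev(seq_len(h)), , 1L])
    rows <- matrix(0L, nrow = row_bytes, ncol = h)
    rows[seq_len(3L * w), ] <- b
    data_size <- row_bytes * h
    con <- file(path, "wb")
    on.exit(close(con))
    writeBin(charToRaw("BM"), con)
    writeBin(as.integer(54L + data_size), con, size = 4L)
    writeBin(0L, con, size = 4L)
    writeBin(54L, con, size = 4L)                      # pixel data offset
    writeBin(40L, con, size = 4L)                      # info header size
    writeBin(as.integer(w), con, size = 4L)
    writeBin(as.integer(h), con, size = 4L)
    writeBin(1L, con, size = 2L)
    writeBin(24L, con, size = 2L)
    writeBin(0L, con, size = 4L)                       # BI_RGB
    writeBin(as.integer(data_size), con, size = 4L)
    writeBin(c(2835L, 2835L, 0L, 0L), con, size = 4L)
    writeBin(as.raw(rows), con)
    invisible(path)
}
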