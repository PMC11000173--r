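test_that("BMP and PNG files round-trip through read/write", {
    img <- noiseImage(10, 7, seed = 4)
    for (ext in c(".bmp", ".png")) {
        f <- tempfile(fileext = ext)
        writeChromImage(img, f)
        back <- readChromImage(f)
        expect_identical(pixelArray(back), pixelArray(img))
    }
    one <- uniformImage(1, 1)
    f <- tempfile(fileext = ".png")
    writeChromImage(one, f)
    expect_identical(pixelArray(readChromImage(f))[1, 1, ],
                     c(255L, 255L, 255L))
})

test_that("non-24-bit images are rejected with a format error", {
    f <- tempfile(fileext = ".png")
    png::writePNG(matrix(runif(12), 3, 4), f)      # grayscale
    expect_error(readChromImage(f), "grayscale")
    expect_error(readChromImage(tempfile()), "cannot read")
    # a BMP header claiming 8 bits per pixel
    f2 <- tempfile(fileext = ".bmp")
    con <- file(f2, "wb")
    writeBin(charToRaw("BM"), con)
    writeBin(c(1078L, 0L, 1078L, 40L, 4L, 4L), con, size = 4L)
    writeBin(1L, con, size = 2L); writeBin(8L, con, size = 2L)
    writeBin(0L, con, size = 4L)
    close(con)
    expect_error(readChromImage(f2), "bit depth 8")
})

test_that("color conversions match the declared formulas", {
    img <- RasterImage(array(c(255, 0, 128, 0,   # R of 4 pixels
                               255, 0, 128, 255, # G
                               255, 0, 128, 0),  # B
                             dim = c(2, 2, 3)))
    g <- toGrayscale(img)
    expect_identical(g[1, 1], 255L)
    expect_identical(g[2, 1], 0L)
    expect_identical(g[1, 2], 128L)
    expect_identical(toGrayscale(uniformImage(1, 1, c(255, 0, 0)))[1, 1],
                     76L)   # round(0.299 * 255)
    hsv <- toHSV(uniformImage(1, 1, c(255, 0, 0)))
    expect_identical(as.integer(hsv[1, 1, ]), c(0L, 255L, 255L))
    expect_identical(toHSV(uniformImage(1, 1, c(128, 128, 128)))[1, 1, 2],
                     0L)    # gray has zero saturation
    expect_identical(toHSV(uniformImage(1, 1, c(0, 255, 0)))[1, 1, 1],
                     85L)   # round(120/360 * 255)
})

test_that("partition boundaries follow floor(i * dim / roi)", {
    g <- partitionImage(roi1 = 5, roi2 = 10, J = 705, K = 1195)
    expect_identical(g@rowBounds,
        c(0L, 70L, 141L, 211L, 282L, 352L, 423L, 493L, 564L, 634L, 705L))
    expect_identical(g@colBounds, as.integer(floor(0:5 * 1195 / 5)))
    g2 <- partitionImage(roi1 = 2, roi2 = 2, J = 4, K = 4)
    expect_identical(g2@rowBounds, c(0L, 2L, 4L))
    expect_equal(nSubimages(partitionImage(roi1 = 5, roi2 = 5,
                                           J = 705, K = 1195)), 25)
    expect_error(partitionImage(roi1 = 10, roi2 = 2, J = 4, K = 4),
                 "roi1")
})

test_that("every pixel belongs to exactly one subimage", {
    for (dims in list(c(705, 1195, 10, 10), c(7, 5, 3, 2),
                      c(100, 100, 15, 15))) {
        g <- partitionImage(roi1 = dims[4], roi2 = dims[3],
                            J = dims[1], K = dims[2])
        sizes <- vapply(seq_len(nSubimages(g)), function(i) {
            b <- chromROI:::cellPixelBlock(g, i)
            length(b$rows) * length(b$cols)
        }, numeric(1))
        expect_equal(sum(sizes), dims[1] * dims[2])
        expect_lte(diff(range(diff(g@rowBounds))), 1)
        expect_lte(diff(range(diff(g@colBounds))), 1)
    }
})

test_that("unfolding is a row-major bijection", {
    g5 <- partitionImage(roi1 = 5, roi2 = 5, J = 100, K = 100)
    expect_equal(unfoldIndex(1, 1, g5), 1)
    expect_equal(unfoldIndex(2, 3, g5), 8)
    g <- partitionImage(roi1 = 10, roi2 = 10, J = 100, K = 100)
    for (r in 1:10) for (cc in 1:10) {
        idx <- unfoldIndex(r, cc, g)
        rc <- foldIndex(idx, g)
        expect_equal(unname(rc[1, ]), c(r, cc))
    }
    expect_error(unfoldIndex(11, 1, g), "out of range")
    expect_error(foldIndex(101, g), "out of range")
})

test_that("grid preview export writes image and consistent bounds CSV", {
    img <- noiseImage(20, 30, seed = 2)
    g <- partitionImage(img, roi1 = 3, roi2 = 2)
    fimg <- tempfile(fileext = ".png"); fcsv <- tempfile(fileext = ".csv")
    tab <- writeGridPreview(img, g, fimg, fcsv)
    expect_true(file.exists(fimg))
    back <- utils::read.csv(fcsv)
    expect_equal(back$y1 - back$y0,
                 rep(diff(g@rowBounds), each = 3))
    expect_equal(nrow(back), 6)
})
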