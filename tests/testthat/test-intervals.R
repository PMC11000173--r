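# Synthetic interval problem: response depends only on a known block of
# columns.
intervalProblem <- function(I = 16, J = 40, signalCols = 11:20,
                            seed = 61) {
    set.seed(seed)
    X <- matrix(rnorm(I * J), I, J)
    y <- rowSums(X[, signalCols]) + rnorm(I, sd = 0.05)
    list(X = X, y = y)
}

test_that("interval partitions are equidistant and covering", {
    p <- makeIntervals(768, 1)
    expect_equal(p$from, 1); expect_equal(p$to, 768)
    p3 <- makeIntervals(10, 3)
    expect_equal(p3$to - p3$from + 1, c(3, 3, 4))
    expect_equal(p3$to, floor(1:3 * 10 / 3))
    p16 <- makeIntervals(768, 16)
    expect_equal(sort(unlist(Map(seq, p16$from, p16$to))), 1:768)
    expect_error(makeIntervals(10, 11), "nIntervals")
})

test_that("iPLS ranks the informative interval first", {
    prob <- intervalProblem()
    part <- makeIntervals(40, 4)       # signal is exactly interval 2
    tab <- ipls(prob$X, prob$y, part, lvMax = 3)
    expect_equal(attr(tab, "best"), 2)
    expect_equal(tab$rank[2], 1)
    # exhaustive per-interval oracle: each interval scored independently
    oracle <- vapply(1:4, function(i) {
        cols <- part$from[i]:part$to[i]
        selectLV(prob$X[, cols], prob$y, 3)$rmsecvChosen
    }, numeric(1))
    expect_equal(tab$rmsecv, oracle)
    # single interval equals the full model
    tab1 <- ipls(prob$X, prob$y, makeIntervals(40, 1), lvMax = 3)
    expect_equal(tab1$rmsecv, attr(tab1, "fullRmsecv"))
    expect_equal(tab1$rmsecv,
                 selectLV(prob$X, prob$y, 3)$rmsecvChosen)
})

test_that("duplicated interval columns give identical iPLS entries", {
    prob <- intervalProblem(J = 20, signalCols = 1:5, seed = 62)
    X2 <- cbind(prob$X, prob$X)        # intervals 1..2 duplicate 3..4
    tab <- ipls(X2, prob$y, makeIntervals(40, 4), lvMax = 2)
    expect_equal(tab$rmsecv[1:2], tab$rmsecv[3:4])
})

test_that("iSPA-PLS reduces to the best single interval at size one", {
    prob <- intervalProblem()
    part <- makeIntervals(40, 4)
    tab <- ipls(prob$X, prob$y, part, lvMax = 3)
    sp <- ispaPLS(prob$X, prob$y, part, maxIntervals = 1, lvMax = 3)
    expect_equal(sp$intervals, attr(tab, "best"))
    expect_equal(sp$rmsecv, min(tab$rmsecv, na.rm = TRUE))
})

test_that("iSPA-PLS recovers two planted orthogonal intervals", {
    set.seed(63)
    I <- 18; J <- 40
    X <- matrix(rnorm(I * J), I, J)
    s1 <- rnorm(I); s2 <- rnorm(I)
    X[, 1:10] <- X[, 1:10] * 0.05 + s1       # interval 1
    X[, 31:40] <- X[, 31:40] * 0.05 + s2     # interval 4
    y <- s1 + s2 + rnorm(I, sd = 0.02)
    part <- makeIntervals(40, 4)
    sp <- ispaPLS(X, y, part, maxIntervals = 2, lvMax = 3)
    expect_equal(sp$intervals, c(1L, 4L))
    # exhaustive pair oracle
    pairs <- utils::combn(4, 2, simplify = FALSE)
    pairFits <- vapply(pairs, function(pr) {
        cols <- unlist(Map(seq, part$from[pr], part$to[pr]))
        selectLV(X[, cols], y, 3)$rmsecvChosen
    }, numeric(1))
    best_single <- min(vapply(1:4, function(i)
        selectLV(X[, part$from[i]:part$to[i]], y, 3)$rmsecvChosen,
        numeric(1)))
    expect_equal(sp$rmsecv, min(c(pairFits, best_single)))
    # candidates include every single interval, so the winner can never
    # be worse than the best single interval
    expect_lte(sp$rmsecv, best_single)
})

test_that("interval outputs are deterministic", {
    prob <- intervalProblem(seed = 64)
    part <- makeIntervals(40, 5)
    a <- ispaPLS(prob$X, prob$y, part, maxIntervals = 2, lvMax = 2)
    b <- ispaPLS(prob$X, prob$y, part, maxIntervals = 2, lvMax = 2)
    expect_identical(a, b)
})
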