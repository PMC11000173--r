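test_that("PLS1 fits recover linear structure and centering behavior", {
    set.seed(1)
    X <- cbind(info = 1:10, matrix(0, 10, 3))
    y <- 2 * X[, 1] + 5
    m <- fitPLS(X, y, nLV = 1)
    expect_lt(max(abs(predict(m, X) - y)), 1e-8)
    # predicting at the column-mean point returns the mean response
    inst <- randomInstance(8, 5, seed = 2)
    m2 <- fitPLS(inst$X, inst$y, nLV = 3)
    expect_equal(predict(m2, matrix(colMeans(inst$X), 1)),
                 mean(inst$y))
    # duplicated rows give duplicated predictions
    p <- predict(m2, inst$X[c(1, 1), , drop = FALSE])
    expect_equal(p[1], p[2])
    expect_error(fitPLS(inst$X, inst$y, nLV = 9), "nLV")
    expect_error(fitPLS(inst$X, rep(1, 8), nLV = 2), "zero variance")
    expect_error(predict(m2, inst$X[, 1:3]), "columns")
})

test_that("PLS at the full LV count equals least squares", {
    for (seed in 1:5) {
        I <- sample(6:10, 1)
        J <- sample(2:(I - 2), 1)
        inst <- randomInstance(I, J, seed = 100 + seed)
        m <- fitPLS(inst$X, inst$y, nLV = J)
        ols <- stats::lm.fit(cbind(1, inst$X), inst$y)
        pred_ols <- cbind(1, inst$X) %*% ols$coefficients
        expect_equal(predict(m, inst$X), as.numeric(pred_ols),
                     tolerance = 1e-8)
    }
})

test_that("predictions equal explicit regression-vector multiplication", {
    inst <- randomInstance(9, 6, seed = 11)
    m <- fitPLS(inst$X, inst$y, nLV = 3)
    manual <- m@yMean +
        sweep(inst$X, 2, m@xMeans, "-") %*% m@coef
    expect_equal(predict(m, inst$X), as.numeric(manual))
})

test_that("LOOCV equals the brute-force refit loop", {
    inst <- randomInstance(10, 6, seed = 12)
    cv <- loocv(inst$X, inst$y, nLV = 2)
    expect_equal(cv$rmsecv, oracleLOOCV(inst$X, inst$y, 2),
                 tolerance = 1e-12)
    # and the held-out predictions match a fitPLS/predict loop exactly
    pred <- vapply(1:10, function(i)
        predict(fitPLS(inst$X[-i, , drop = FALSE], inst$y[-i], 2),
                inst$X[i, , drop = FALSE]), numeric(1))
    expect_equal(cv$predictions, pred)
    expect_error(loocv(inst$X, inst$y, nLV = 9), "nLV")
    expect_error(loocv(matrix(1, 5, 3), rep(2, 5), 1), "zero variance")
})

test_that("the LV selection rule is minimum-RMSECV with parsimony", {
    expect_equal(chromROI:::chooseLVFromCurve(c(3, 2, 1)), 3)
    expect_equal(chromROI:::chooseLVFromCurve(c(2, 2, 2)), 1)
    # minimum at 4 but LV2 within 5%
    curve <- c(1.20, 1.04, 1.02, 1.00)
    expect_equal(chromROI:::chooseLVFromCurve(curve, tolerance = 0.05), 2)
    expect_equal(chromROI:::chooseLVFromCurve(curve, tolerance = 0), 4)
    inst <- randomInstance(12, 6, seed = 13)
    sel <- selectLV(inst$X, inst$y, lvMax = 4)
    expect_equal(sel$rmsecv,
        vapply(1:4, function(a) loocv(inst$X, inst$y, a)$rmsecv,
               numeric(1)))
    expect_equal(sel$nLV, which.min(sel$rmsecv))
})

test_that("figures of merit follow their definitions", {
    perfect <- figuresOfMerit(1:5, 1:5)
    expect_equal(perfect$rmse, 0)
    expect_equal(perfect$r2, 1)
    fm <- figuresOfMerit(c(10, 10, 10, 10), c(13, 7, 13, 7))
    expect_equal(fm$rmse, 3)
    yt <- c(18, 20, 22, 20)  # mean 20
    e <- c(2.8, -2.8, 2.8, -2.8)
    expect_equal(figuresOfMerit(yt, yt + e)$rep, 2.8 / 20)
    expect_error(figuresOfMerit(c(-1, 1), c(0, 0)), "rep undefined")
})

test_that("the bias t-test matches the one-sample t construction", {
    # critical value at 95% with 9 degrees of freedom
    set.seed(3)
    y <- rnorm(10); e <- rnorm(10)
    bt <- biasTTest(y, y + e)
    expect_equal(round(bt$tCrit, 4), 1.8331)
    tt <- stats::t.test(e)
    expect_equal(bt$tCal, abs(unname(tt$statistic)))
    expect_equal(bt$bias, mean(e))
    sym <- c(1, -1, 2, -2)
    bt2 <- biasTTest(rep(0, 4), sym)
    expect_equal(bt2$bias, 0)
    expect_equal(bt2$tCal, 0)
    expect_false(bt2$significant)
    expect_error(biasTTest(1:4, (1:4) + 1), "degenerate residuals")
})

test_that("merit reports assemble cross-validation and prediction stats", {
    inst <- randomInstance(14, 5, seed = 14)
    cal <- 1:10; prd <- 11:14
    r <- meritReport(inst$X[cal, ], inst$y[cal], nLV = 2,
                     inst$X[prd, ], inst$y[prd])
    expect_s4_class(r, "MeritReport")
    expect_equal(r@rmsecv, loocv(inst$X[cal, ], inst$y[cal], 2)$rmsecv)
    m <- fitPLS(inst$X[cal, ], inst$y[cal], 2)
    fom <- figuresOfMerit(inst$y[prd], predict(m, inst$X[prd, ]))
    expect_equal(r@rmsep, fom$rmse)
    expect_equal(r@biasSignificant, r@tCal > r@tCrit)
    tab <- meritTable(list(model = r))
    expect_equal(tab$RMSECV, r@rmsecv)
})
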