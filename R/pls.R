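# PLS1 regression (NIPALS, mean-centered), leave-one-out cross-validation,
# latent-variable selection and figures of merit.
#
# The cross-validation error RMSECV is the fitness the genetic algorithm
# minimizes, and Table-2-style merit reports are derived from the same
# primitives, so numerical behavior here is deliberately plain: the LOOCV
# loop really refits the model once per left-out sample.

# NIPALS core on already-centered data. Returns weights W, loadings P,
# y-loadings q, and the regression vector b (centered space). Stops early
# if the residual X carries no covariance with y (rank exhausted).
nipals_pls1 <- function(Xc, yc, nLV) {
    J <- ncol(Xc)
    W <- matrix(0, J, nLV); P <- matrix(0, J, nLV)
    Tm <- matrix(0, nrow(Xc), nLV); q <- numeric(nLV)
    a_used <- 0L
    for (a in seq_len(nLV)) {
        w <- crossprod(Xc, yc)
        wn <- sqrt(sum(w^2))
        if (wn < 1e-12) break
        w <- w / wn
        t <- Xc %*% w
        tt <- sum(t^2)
        if (tt < 1e-12) break
        p <- crossprod(Xc, t) / tt
        q[a] <- sum(yc * t) / tt
        Xc <- Xc - t %*% t(p)
        yc <- yc - q[a] * t
        W[, a] <- w; P[, a] <- p; Tm[, a] <- t
        a_used <- a
    }
    if (a_used == 0L)
        stop("degenerate input: X carries no covariance with y")
    W <- W[, seq_len(a_used), drop = FALSE]
    P <- P[, seq_len(a_used), drop = FALSE]
    Tm <- Tm[, seq_len(a_used), drop = FALSE]
    q <- q[seq_len(a_used)]
    b <- W %*% solve(crossprod(P, W), q)
    list(W = W, P = P, Tm = Tm, q = q, b = as.numeric(b),
         nLV = a_used)
}

#' Fit a PLS1 regression
#'
#' NIPALS PLS1 on column-mean-centered predictors and mean-centered
#' response (no autoscaling by default; histogram bins share units).
#' Deterministic for fixed input. If the requested number of latent
#' variables exceeds the covariance structure available, the model stops at
#' the last extractable component.
#'
#' @param X numeric matrix, samples x features (or a
#'   \linkS4class{FeatureMatrix}).
#' @param y numeric response; ignored when \code{X} is a FeatureMatrix.
#' @param nLV number of latent variables, \code{1 <= nLV <= min(I-1, J)}.
#' @param scale logical; if TRUE, autoscale columns to unit variance
#'   (constant columns are left unscaled).
#' @return A \linkS4class{PLSModel}.
#' @export
fitPLS <- function(X, y = NULL, nLV, scale = FALSE) {
    if (is(X, "FeatureMatrix")) { y <- response(X); X <- featureValues(X) }
    X <- as.matrix(X)
    I <- nrow(X); J <- ncol(X)
    if (I < 2L) stop("at least two samples are required")
    nLV <- as.integer(nLV)
    if (nLV < 1L || nLV > min(I - 1L, J))
        stop("nLV must lie in [1, min(I-1, J) = ", min(I - 1L, J), "]")
    if (!all(is.finite(X)) || !all(is.finite(y)))
        stop("X and y must be finite")
    if (sd(y) == 0) stop("degenerate input: y has zero variance")
    xm <- colMeans(X)
    ym <- mean(y)
    Xc <- sweep(X, 2L, xm, "-")
    xs <- rep(1, J)
    if (scale) {
        s <- apply(Xc, 2L, sd)
        xs <- ifelse(s > 0, s, 1)
        Xc <- sweep(Xc, 2L, xs, "/")
    }
    fit <- nipals_pls1(Xc, y - ym, nLV)
    new("PLSModel", nLV = fit$nLV, coef = fit$b / xs, xMeans = xm,
        yMean = ym, scores = fit$Tm, loadings = fit$P,
        weights = fit$W)
}

#' Predict responses from a fitted PLS1 model
#'
#' @param object a \linkS4class{PLSModel}.
#' @param newdata numeric matrix (samples x features) with the training
#'   column layout.
#' @param ... unused.
#' @return numeric vector of predictions.
#' @export
setMethod("predict", "PLSModel", function(object, newdata, ...) {
    newdata <- as.matrix(newdata)
    if (ncol(newdata) != length(object@coef))
        stop("newdata has ", ncol(newdata), " columns; model expects ",
             length(object@coef))
    as.numeric(object@yMean +
        sweep(newdata, 2L, object@xMeans, "-") %*% object@coef)
})

#' Leave-one-out cross-validation of a PLS1 model
#'
#' For each sample \code{i} the model is refitted on the remaining
#' \code{I - 1} samples and used to predict sample \code{i}; RMSECV is the
#' root mean squared error of those held-out predictions.
#'
#' @inheritParams fitPLS
#' @return list with \code{rmsecv} and \code{predictions} (per-sample
#'   held-out predictions, in sample order).
#' @export
loocv <- function(X, y = NULL, nLV, scale = FALSE) {
    if (is(X, "FeatureMatrix")) { y <- response(X); X <- featureValues(X) }
    X <- as.matrix(X)
    I <- nrow(X)
    if (I < 3L) stop("LOOCV requires at least three samples")
    nLV <- as.integer(nLV)
    if (nLV > I - 2L)
        stop("nLV must not exceed I - 2 = ", I - 2L, " for LOOCV")
    if (sd(y) == 0) stop("degenerate input: y has zero variance")
    pred <- numeric(I)
    for (i in seq_len(I)) {
        # plain refit per fold; same arithmetic as fitPLS + predict but
        # without per-fold S4 object construction
        Xi <- X[-i, , drop = FALSE]
        yi <- y[-i]
        xm <- colMeans(Xi)
        ym <- mean(yi)
        Xc <- sweep(Xi, 2L, xm, "-")
        if (scale) {
            s <- apply(Xc, 2L, sd)
            xs <- ifelse(s > 0, s, 1)
            Xc <- sweep(Xc, 2L, xs, "/")
        }
        fit <- nipals_pls1(Xc, yi - ym, nLV)
        b <- if (scale) fit$b / xs else fit$b
        pred[i] <- ym + (X[i, ] - xm) %*% b
    }
    list(rmsecv = sqrt(mean((pred - y)^2)), predictions = pred)
}

#' Choose the number of latent variables by minimum RMSECV
#'
#' Returns the smallest LV count whose RMSECV is within \code{tolerance}
#' (relative) of the minimum over \code{1..lvMax} — a parsimony tie-break
#' toward fewer latent variables.
#'
#' @inheritParams fitPLS
#' @param lvMax LV search ceiling (capped at \code{min(I-2, J)}).
#' @param tolerance relative slack on the minimum RMSECV (default 0).
#' @return list with \code{nLV}, \code{rmsecv} (vector over 1..lvMax) and
#'   \code{rmsecvChosen}.
#' @export
selectLV <- function(X, y = NULL, lvMax, tolerance = 0, scale = FALSE) {
    if (is(X, "FeatureMatrix")) { y <- response(X); X <- featureValues(X) }
    X <- as.matrix(X)
    lvMax <- min(as.integer(lvMax), nrow(X) - 2L, ncol(X))
    stopifnot(lvMax >= 1L)
    rmse <- vapply(seq_len(lvMax),
        function(a) loocv(X, y, a, scale = scale)$rmsecv, numeric(1))
    chosen <- chooseLVFromCurve(rmse, tolerance)
    list(nLV = chosen, rmsecv = rmse, rmsecvChosen = rmse[chosen])
}

# The selection rule itself, separated so it can be applied to any RMSECV
# curve: smallest LV within (1 + tolerance) * min.
chooseLVFromCurve <- function(rmse, tolerance = 0) {
    which(rmse <= (1 + tolerance) * min(rmse))[1]
}

#' Root mean square error, relative error and R-squared
#'
#' \code{rmse = sqrt(mean(e^2))}, \code{rep = rmse / mean(yTrue)}
#' (dimensionless ratio; multiply by 100 for percent), and
#' \code{r2 = 1 - sum(e^2) / sum((yTrue - mean(yTrue))^2)}.
#'
#' @param yTrue,yPred numeric vectors of equal length >= 2.
#' @return list with \code{rmse}, \code{rep}, \code{r2}.
#' @export
figuresOfMerit <- function(yTrue, yPred) {
    stopifnot(length(yTrue) == length(yPred), length(yTrue) >= 2L)
    if (mean(yTrue) == 0)
        stop("rep undefined: mean of reference values is zero")
    e <- yPred - yTrue
    rmse <- sqrt(mean(e^2))
    list(rmse = rmse, rep = rmse / mean(yTrue),
         r2 = 1 - sum(e^2) / sum((yTrue - mean(yTrue))^2))
}

#' One-sided bias t-test on prediction residuals
#'
#' Tests whether the mean prediction residual differs from zero:
#' \code{t_cal = |mean(e)| * sqrt(n) / sd(e)} compared against the
#' one-sided Student-t quantile at the given confidence with \code{n - 1}
#' degrees of freedom (1.8331 at 95\% for n = 10). Bias is declared
#' significant when \code{t_cal > t_crit}.
#'
#' @param yTrue,yPred numeric vectors of equal length >= 2.
#' @param confidence confidence level (default 0.95).
#' @return list with \code{bias}, \code{tCal}, \code{tCrit},
#'   \code{significant}.
#' @export
biasTTest <- function(yTrue, yPred, confidence = 0.95) {
    stopifnot(length(yTrue) == length(yPred), length(yTrue) >= 2L)
    e <- yPred - yTrue
    n <- length(e)
    bias <- mean(e)
    sdv <- sqrt(sum((e - bias)^2) / (n - 1))
    if (sdv == 0) stop("degenerate residuals: zero standard deviation")
    tCal <- abs(bias) * sqrt(n) / sdv
    tCrit <- qt(confidence, df = n - 1)
    list(bias = bias, tCal = tCal, tCrit = tCrit,
         significant = tCal > tCrit)
}

#' Full merit report for a calibration model and optional prediction set
#'
#' Cross-validates on the calibration set, then (if given) predicts the
#' independent prediction set and runs the bias t-test on its residuals.
#'
#' @param Xcal,ycal calibration predictors and response.
#' @param nLV latent-variable count for the final model.
#' @param Xpred,ypred optional prediction-set predictors and response.
#' @param confidence confidence level for the bias test.
#' @param scale autoscaling flag passed to [fitPLS()].
#' @return A \linkS4class{MeritReport}.
#' @export
meritReport <- function(Xcal, ycal, nLV, Xpred = NULL, ypred = NULL,
                        confidence = 0.95, scale = FALSE) {
    cv <- loocv(Xcal, ycal, nLV, scale = scale)
    fom_cv <- figuresOfMerit(ycal, cv$predictions)
    rmsep <- rep_p <- r2_p <- bias <- tCal <- tCrit <- NA_real_
    signif_p <- NA
    if (!is.null(Xpred)) {
        m <- fitPLS(Xcal, ycal, nLV, scale = scale)
        yp <- predict(m, Xpred)
        fom_p <- figuresOfMerit(ypred, yp)
        bt <- biasTTest(ypred, yp, confidence)
        rmsep <- fom_p$rmse; rep_p <- fom_p$rep; r2_p <- fom_p$r2
        bias <- bt$bias; tCal <- bt$tCal; tCrit <- bt$tCrit
        signif_p <- bt$significant
    }
    new("MeritReport", nLV = as.integer(nLV), rmsecv = cv$rmsecv,
        repCV = fom_cv$rep, r2CV = fom_cv$r2, rmsep = rmsep,
        rep = rep_p, r2 = r2_p, bias = bias, tCal = tCal, tCrit = tCrit,
        biasSignificant = signif_p)
}

#' Render merit reports as a Table-2-shaped data frame
#'
#' @param reports named list of \linkS4class{MeritReport}s; names become
#'   the model column.
#' @return data.frame with columns model, LV, RMSECV, REP_cv, R2_cv,
#'   RMSEP, REP, R2, bias, t_cal, t_crit, bias_significant.
#' @export
meritTable <- function(reports) {
    do.call(rbind, lapply(names(reports), function(nm) {
        r <- reports[[nm]]
        data.frame(model = nm, LV = r@nLV, RMSECV = r@rmsecv,
                   REP_cv = r@repCV, R2_cv = r@r2CV, RMSEP = r@rmsep,
                   REP = r@rep, R2 = r@r2, bias = r@bias, t_cal = r@tCal,
                   t_crit = r@tCrit, bias_significant = r@biasSignificant)
    }))
}
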