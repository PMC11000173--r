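# Independent oracles: brute-force or textbook implementations used only
# to check the package's results, never shared with the implementation.

# Per-pixel counting histogram: explicit double loop over every pixel of
# every block.
oracleHistogram <- function(channelGrid, blocks) {
    counts <- numeric(256)
    for (b in blocks) {
        for (r in b$rows) for (cc in b$cols) {
            v <- channelGrid[r, cc]
            counts[v + 1] <- counts[v + 1] + 1
        }
    }
    counts
}

# Textbook NIPALS PLS1 written independently: explicit component loop
# with stored weight/loading matrices and the closed-form regression
# vector at the end.
oracleFitPLS <- function(X, y, nlv) {
    xm <- colMeans(X); ym <- mean(y)
    E <- sweep(X, 2, xm, "-")
    f <- y - ym
    W <- NULL; P <- NULL; q <- c()
    for (a in 1:nlv) {
        w <- crossprod(E, f)
        w <- w / sqrt(sum(w^2))
        t <- E %*% w
        p <- crossprod(E, t) / sum(t^2)
        qa <- sum(f * t) / sum(t^2)
        E <- E - t %*% t(p)
        f <- f - qa * t
        W <- cbind(W, w); P <- cbind(P, p); q <- c(q, qa)
    }
    b <- W %*% solve(crossprod(P, W), q)
    list(coef = as.numeric(b), xMeans = xm, yMean = ym)
}

oraclePredict <- function(fit, Xnew) {
    as.numeric(fit$yMean + sweep(Xnew, 2, fit$xMeans, "-") %*% fit$coef)
}

# Brute-force LOOCV: refit with the oracle for every left-out sample.
oracleLOOCV <- function(X, y, nlv) {
    pred <- vapply(seq_len(nrow(X)), function(i) {
        fit <- oracleFitPLS(X[-i, , drop = FALSE], y[-i], nlv)
        oraclePredict(fit, X[i, , drop = FALSE])
    }, numeric(1))
    sqrt(mean((pred - y)^2))
}

# Naive double-loop joint SPXY distance.
oracleJointDistance <- function(X, y) {
    I <- nrow(X)
    dx <- matrix(0, I, I); dy <- matrix(0, I, I)
    for (i in 1:I) for (j in 1:I) {
        dx[i, j] <- sqrt(sum((X[i, ] - X[j, ])^2))
        dy[i, j] <- abs(y[i] - y[j])
    }
    dx / max(dx) + dy / max(dy)
}

# All subimage subsets of size 1..nim as index vectors.
allSubsets <- function(nGenes, nim) {
    out <- list()
    for (k in seq_len(nim))
        out <- c(out, utils::combn(nGenes, k, simplify = FALSE))
    out
}

# Exhaustive best subset under the package's own fitness.
exhaustiveBest <- function(cache, y, config, nim) {
    subsets <- allSubsets(dim(cache)[1], nim)
    fits <- vapply(subsets, function(s) {
        g <- integer(dim(cache)[1]); g[s] <- 1L
        chromosomeFitness(g, cache, y, config)
    }, numeric(1))
    list(subset = subsets[[which.min(fits)]], fitness = min(fits),
         all = fits)
}
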