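# Interval-wise refinement of the winning histogram: iPLS scores each
# contiguous block of histogram bins with its own PLS-LOOCV model; iSPA-PLS
# uses the successive projections algorithm over interval representatives
# to propose minimally collinear interval combinations, each scored by
# PLS-LOOCV.

#' Split feature columns into near-equal contiguous intervals
#'
#' Boundaries are \code{floor(i * J / n)} over feature indices: intervals
#' are half-open, contiguous, cover every column exactly once, and differ
#' in size by at most one.
#'
#' @param nFeatures total feature count J.
#' @param nIntervals number of intervals, \code{1 <= nIntervals <= J}.
#' @return data.frame with columns \code{interval, from, to} (1-based,
#'   inclusive).
#' @export
makeIntervals <- function(nFeatures, nIntervals) {
    nFeatures <- as.integer(nFeatures); nIntervals <- as.integer(nIntervals)
    if (nIntervals < 1L || nIntervals > nFeatures)
        stop("nIntervals must lie in [1, ", nFeatures, "]")
    bounds <- floor(seq(0L, nIntervals) * nFeatures / nIntervals)
    data.frame(interval = seq_len(nIntervals),
               from = bounds[-length(bounds)] + 1L,
               to = bounds[-1L])
}

intervalColumns <- function(partition, intervals) {
    unlist(lapply(intervals, function(i)
        partition$from[i]:partition$to[i]), use.names = FALSE)
}

# LV-selected LOOCV RMSECV of a column subset; NA when degenerate.
intervalScore <- function(X, y, cols, lvMax, scale = FALSE) {
    Xi <- X[, cols, drop = FALSE]
    cap <- min(lvMax, nrow(X) - 2L, ncol(Xi))
    tryCatch(selectLV(Xi, y, cap, scale = scale)[c("nLV", "rmsecvChosen")],
             error = function(e) list(nLV = NA_integer_,
                                      rmsecvChosen = NA_real_))
}

#' Interval PLS (iPLS)
#'
#' Fits one PLS-LOOCV model per interval, on that interval's columns only,
#' and ranks intervals by RMSECV. The full-feature model is included as a
#' baseline. Degenerate intervals (no covariance with y) are recorded as
#' unusable rather than failing the table.
#'
#' @param X numeric matrix, samples x features (or a
#'   \linkS4class{FeatureMatrix}).
#' @param y numeric response; ignored when \code{X} is a FeatureMatrix.
#' @param partition data.frame from [makeIntervals()].
#' @param lvMax latent-variable search ceiling per interval.
#' @param scale autoscaling flag passed to the PLS fits.
#' @return data.frame with one row per interval (columns \code{interval,
#'   from, to, nLV, rmsecv, rank, usable}); the baseline full-model RMSECV
#'   and its LV count are attached as attributes \code{fullRmsecv} and
#'   \code{fullNLV}; the best usable interval index as attribute
#'   \code{best}.
#' @export
ipls <- function(X, y = NULL, partition, lvMax = 5, scale = FALSE) {
    if (is(X, "FeatureMatrix")) { y <- response(X); X <- featureValues(X) }
    X <- as.matrix(X)
    scores <- lapply(seq_len(nrow(partition)), function(i)
        intervalScore(X, y, partition$from[i]:partition$to[i], lvMax,
                      scale))
    tab <- partition
    tab$nLV <- vapply(scores, function(s) as.integer(s$nLV), integer(1))
    tab$rmsecv <- vapply(scores, function(s) s$rmsecvChosen, numeric(1))
    tab$usable <- !is.na(tab$rmsecv)
    tab$rank <- rank(tab$rmsecv, ties.method = "first",
                     na.last = "keep")
    full <- intervalScore(X, y, seq_len(ncol(X)), lvMax, scale)
    attr(tab, "fullRmsecv") <- full$rmsecvChosen
    attr(tab, "fullNLV") <- full$nLV
    attr(tab, "best") <- if (any(tab$usable))
        tab$interval[which.min(tab$rmsecv)] else NA_integer_
    tab
}

#' Interval selection by successive projections (iSPA-PLS)
#'
#' Each interval is represented by its column-mean profile over samples
#' (mean-centered). Starting from every interval in turn, the successive
#' projections algorithm grows a chain by repeatedly adding the interval
#' whose representative has the largest norm orthogonal to the span of the
#' chain so far — a minimally collinear combination. Every chain prefix of
#' size 1..\code{maxIntervals} is scored by PLS-LOOCV on its pooled
#' columns; the global best is returned. Deterministic: ties break toward
#' the lowest interval index, then toward fewer intervals.
#'
#' @inheritParams ipls
#' @param maxIntervals largest interval combination considered.
#' @return list with \code{intervals} (sorted indices of the winning
#'   combination), \code{nLV}, \code{rmsecv}, and \code{candidates}
#'   (data.frame of every scored prefix).
#' @export
ispaPLS <- function(X, y = NULL, partition, maxIntervals = 3, lvMax = 5,
                    scale = FALSE) {
    if (is(X, "FeatureMatrix")) { y <- response(X); X <- featureValues(X) }
    X <- as.matrix(X)
    nInt <- nrow(partition)
    maxIntervals <- min(as.integer(maxIntervals), nInt)
    stopifnot(maxIntervals >= 1L)
    # centered interval representatives, one column per interval
    M <- vapply(seq_len(nInt), function(i)
        rowMeans(X[, partition$from[i]:partition$to[i], drop = FALSE]),
        numeric(nrow(X)))
    M <- sweep(M, 2L, colMeans(M), "-")
    chains <- lapply(seq_len(nInt), function(start) {
        chain <- start
        R <- M          # residuals orthogonal to span of chosen
        for (step in seq_len(maxIntervals - 1L)) {
            v <- R[, chain[length(chain)]]
            vn2 <- sum(v^2)
            if (vn2 < 1e-12) break               # rank exhausted
            R <- R - v %*% crossprod(v, R) / vn2
            norms <- colSums(R^2)
            norms[chain] <- -Inf
            nxt <- which.max(norms)
            if (!is.finite(norms[nxt]) || norms[nxt] < 1e-12) break
            chain <- c(chain, nxt)
        }
        chain
    })
    cand <- list()
    seen <- character(0)
    for (chain in chains) {
        for (len in seq_along(chain)) {
            set <- sort(chain[seq_len(len)])
            key <- paste(set, collapse = ",")
            if (key %in% seen) next
            seen <- c(seen, key)
            sc <- intervalScore(X, y, intervalColumns(partition, set),
                                lvMax, scale)
            cand[[length(cand) + 1L]] <- data.frame(
                intervals = key, size = len,
                nLV = as.integer(sc$nLV), rmsecv = sc$rmsecvChosen)
        }
    }
    cand <- do.call(rbind, cand)
    usable <- which(!is.na(cand$rmsecv))
    if (length(usable) == 0L)
        stop("no usable interval combination (all degenerate)")
    ord <- usable[order(cand$rmsecv[usable], cand$size[usable],
                        cand$intervals[usable])]
    best <- cand[ord[1], ]
    list(intervals = as.integer(strsplit(best$intervals, ",")[[1]]),
         nLV = best$nLV, rmsecv = best$rmsecv, candidates = cand)
}
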