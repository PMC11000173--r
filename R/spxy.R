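# SPXY calibration/prediction splitting: Kennard-Stone selection on a
# joint distance that weights predictor space and response space equally,
# so the calibration set spans both and the prediction set never requires
# extrapolation in y.

#' Joint X-y distance matrix for SPXY
#'
#' \code{d(i,j) = dx(i,j)/max(dx) + dy(i,j)/max(dy)} where \code{dx},
#' \code{dy} are Euclidean distances in predictor and response space.
#'
#' @param X numeric matrix, samples x features.
#' @param y numeric response vector.
#' @return symmetric numeric matrix with zero diagonal.
#' @export
jointDistanceMatrix <- function(X, y) {
    X <- as.matrix(X)
    stopifnot(nrow(X) == length(y), nrow(X) >= 2L)
    dx <- as.matrix(stats::dist(X))
    dy <- as.matrix(stats::dist(matrix(y, ncol = 1)))
    if (max(dx) == 0) stop("all samples identical in X: max distance zero")
    if (max(dy) == 0) stop("all responses identical: max distance zero")
    dx / max(dx) + dy / max(dy)
}

#' SPXY calibration/prediction split
#'
#' Seeds the calibration set with the pair of samples at maximum joint
#' distance, then repeatedly adds the sample whose minimum joint distance
#' to the already-selected set is largest (Kennard-Stone on the joint
#' distance). Deterministic; ties are broken toward the lowest sample
#' index.
#'
#' @param X numeric matrix, samples x features (or a
#'   \linkS4class{FeatureMatrix}).
#' @param y numeric response; ignored when \code{X} is a FeatureMatrix.
#' @param nCal number of calibration samples, \code{2 <= nCal <= I}.
#' @return list with integer vectors \code{calibration} and
#'   \code{prediction} (1-based sample indices, in selection / ascending
#'   order respectively) and counts \code{nCal}, \code{nPred}.
#' @examples
#' spxySplit(matrix(c(0, 1, 2, 10)), c(0, 1, 2, 10), nCal = 3)$calibration
#' @export
spxySplit <- function(X, y = NULL, nCal) {
    if (is(X, "FeatureMatrix")) { y <- response(X); X <- featureValues(X) }
    X <- as.matrix(X)
    I <- nrow(X)
    nCal <- as.integer(nCal)
    if (nCal < 2L || nCal > I)
        stop("nCal must lie in [2, ", I, "]")
    d <- jointDistanceMatrix(X, y)
    # seed: maximum-distance pair, lowest indices on ties
    up <- which(upper.tri(d), arr.ind = TRUE)
    dv <- d[upper.tri(d)]
    best <- up[which.max(dv), ]                 # which.max = first maximum
    sel <- sort(as.integer(best))
    while (length(sel) < nCal) {
        remaining <- setdiff(seq_len(I), sel)
        min_d <- apply(d[remaining, sel, drop = FALSE], 1L, min)
        sel <- c(sel, remaining[which.max(min_d)])
    }
    list(calibration = sel,
         prediction = setdiff(seq_len(I), sel),
         nCal = nCal, nPred = I - nCal)
}
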