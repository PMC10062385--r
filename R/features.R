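# Band features and sparse band selection.
#
# Spectra are reduced to a handful of band intensities (mean SNV intensity
# over +/- halfWidth around each registry band). Discriminative bands are
# then selected by ranking the weights of an L1-regularized linear SVM
# (squared hinge loss + lasso penalty) fitted along a decreasing penalty
# path; the weight magnitude acts as a surrogate for feature relevance and
# the retained set is kept below 10 features.

#' Mean band intensity of a spectrum
#'
#' @param s A [RamanSpectrum-class] at stage `"snv"`.
#' @param center Band center (cm^-1).
#' @param halfWidth Half-width of the integration window (cm^-1).
#' @return Mean SNV intensity over `[center - halfWidth, center + halfWidth]`.
#' @examples
#' ax <- seq(600, 1800)
#' s <- snv(RamanSpectrum(ax, exp(-(ax - 1004)^2 / 18) + 0.001 * ax))
#' bandIntensity(s, 1004)
#' @export
bandIntensity <- function(s, center, halfWidth = 5) {
    stopifnot(is(s, "RamanSpectrum"))
    wn <- s@wavenumber
    if (center - halfWidth < wn[1] || center + halfWidth > wn[length(wn)])
        stop("band ", center, " +/- ", halfWidth,
             " cm-1 lies outside the spectrum axis")
    sel <- wn >= center - halfWidth & wn <= center + halfWidth
    mean(s@intensity[sel])
}

#' Build a band-feature matrix from processed spectra
#'
#' One column per measurement, one row per band: the mean SNV intensity in
#' each band window. Per-bin features (every wavenumber sample as a
#' feature) are available with `perBin = TRUE`.
#'
#' @param x A [RamanExperiment-class], or a list of [RamanSpectrum-class]
#'   objects on a common axis.
#' @param bands Band registry data frame (columns `center`, `halfWidth`,
#'   `name`); default [tableBands()]. Ignored when `perBin = TRUE`.
#' @param perBin If `TRUE`, use raw wavenumber bins as features.
#' @return A [SummarizedExperiment::SummarizedExperiment] with assay
#'   `"features"` (features x measurements), feature metadata in `rowData`
#'   and, when `x` is a [RamanExperiment-class], its `colData` carried over.
#' @export
buildFeatureMatrix <- function(x, bands = tableBands(), perBin = FALSE) {
    if (is(x, "RamanExperiment")) {
        mat <- SummarizedExperiment::assay(x, "snv")
        wn <- SummarizedExperiment::rowData(x)$wavenumber
        cd <- SummarizedExperiment::colData(x)
    } else {
        stopifnot(is.list(x), length(x) > 0)
        wn <- x[[1]]@wavenumber
        for (s in x) {
            if (length(s@wavenumber) != length(wn) ||
                any(s@wavenumber != wn))
                stop("spectra are not on a common wavenumber axis")
        }
        mat <- vapply(x, function(s) s@intensity, numeric(length(wn)))
        if (is.null(colnames(mat)))
            colnames(mat) <- sprintf("s%03d", seq_len(ncol(mat)))
        cd <- S4Vectors::DataFrame(row.names = colnames(mat))
    }
    if (perBin) {
        feat <- mat
        rowdat <- S4Vectors::DataFrame(center = wn, name = as.character(wn))
    } else {
        feat <- matrix(NA_real_, nrow(bands), ncol(mat))
        for (b in seq_len(nrow(bands))) {
            lo <- bands$center[b] - bands$halfWidth[b]
            hi <- bands$center[b] + bands$halfWidth[b]
            if (lo < wn[1] || hi > wn[length(wn)])
                stop("band ", bands$center[b], " lies outside the axis")
            sel <- wn >= lo & wn <= hi
            feat[b, ] <- colMeans(mat[sel, , drop = FALSE])
        }
        rowdat <- S4Vectors::DataFrame(bands)
        rownames(feat) <- bands$name
    }
    if (is.null(colnames(feat)))
        colnames(feat) <- if (nrow(cd) == ncol(feat) &&
                              !is.null(rownames(cd))) rownames(cd)
                          else sprintf("s%03d", seq_len(ncol(feat)))
    SummarizedExperiment::SummarizedExperiment(
        assays = list(features = feat), rowData = rowdat, colData = cd)
}

#' Feature values as a measurements-by-features matrix
#'
#' @param fm Feature matrix from [buildFeatureMatrix()].
#' @return Numeric matrix, one row per measurement, band names as columns.
#' @export
featureValues <- function(fm) {
    t(SummarizedExperiment::assay(fm, "features"))
}

#' Per-class band intensity distribution summary
#'
#' Quartile summary of each band's intensity per tissue class, the tabular
#' analogue of per-band boxplots.
#'
#' @param fm Feature matrix from [buildFeatureMatrix()].
#' @param labels Class label per measurement (defaults to the `label`
#'   column of `colData(fm)`).
#' @return Data frame with columns `band`, `class`, `q1`, `median`, `q3`.
#' @export
bandSummary <- function(fm, labels = SummarizedExperiment::colData(fm)$label) {
    X <- featureValues(fm)
    stopifnot(length(labels) == nrow(X))
    out <- list()
    for (b in colnames(X)) for (cl in unique(labels)) {
        q <- quantile(X[labels == cl, b], c(0.25, 0.5, 0.75), names = FALSE)
        out[[length(out) + 1L]] <- data.frame(
            band = b, class = cl, q1 = q[1], median = q[2], q3 = q[3])
    }
    do.call(rbind, out)
}

# ---- L1-regularized linear SVM (squared hinge + lasso), FISTA solver ----

# Minimizes (1/n) sum_i max(0, 1 - y_i (x_i w + b))^2 + lambda ||w||_1
# over (w, b), bias unpenalized. X must be standardized by the caller.
.l1svmFit <- function(X, y, lambda, w = NULL, b = 0, maxIter = 300,
                      tol = 1e-7) {
    n <- nrow(X)
    p <- ncol(X)
    if (is.null(w)) w <- numeric(p)
    # Lipschitz constant of the smooth part: (2/n) * sigma_max([X 1])^2
    Xb <- cbind(X, 1)
    L <- 2 * (svd(Xb, nu = 0, nv = 0)$d[1])^2 / n
    s <- 1 / L
    zw <- w; zb <- b; t0 <- 1
    obj <- function(w, b) {
        m <- pmax(0, 1 - y * (drop(X %*% w) + b))
        mean(m^2) + lambda * sum(abs(w))
    }
    prev <- obj(w, b)
    for (it in seq_len(maxIter)) {
        m <- pmax(0, 1 - y * (drop(X %*% zw) + zb))
        gw <- -(2 / n) * drop(crossprod(X, y * m))
        gb <- -(2 / n) * sum(y * m)
        wNew <- zw - s * gw
        wNew <- sign(wNew) * pmax(abs(wNew) - s * lambda, 0)
        bNew <- zb - s * gb
        t1 <- (1 + sqrt(1 + 4 * t0^2)) / 2
        zw <- wNew + ((t0 - 1) / t1) * (wNew - w)
        zb <- bNew + ((t0 - 1) / t1) * (bNew - b)
        w <- wNew; b <- bNew; t0 <- t1
        if (it %% 10 == 0) {
            cur <- obj(w, b)
            if (abs(prev - cur) < tol * max(1, abs(prev))) break
            prev <- cur
        }
    }
    list(w = w, b = b)
}

# Fits the full decreasing penalty path with warm starts.
.l1svmPath <- function(X, y, lambdas) {
    fits <- vector("list", length(lambdas))
    w <- NULL; b <- 0
    for (k in seq_along(lambdas)) {
        f <- .l1svmFit(X, y, lambdas[k], w = w, b = b)
        fits[[k]] <- f
        w <- f$w; b <- f$b
    }
    fits
}

.balancedAccuracy <- function(truth, pred) {
    mean(vapply(unique(truth), function(cl)
        mean(pred[truth == cl] == cl), numeric(1)))
}

#' Rank and select features with an L1-regularized linear SVM
#'
#' Fits L1-penalized linear classifiers (squared hinge loss) along a
#' 30-point logarithmic penalty path from the empty model downward, scores
#' every penalty by stratified 5-fold cross-validated balanced accuracy,
#' and selects the strongest penalty whose score comes within
#' `cvTolerance` standard errors of the best (favouring sparsity, in the
#' spirit of the one-standard-error rule). Features with nonzero weight at
#' the selected penalty are retained after discarding those whose absolute
#' weight falls below `weightFloor` times the largest (the weight acting
#' as the relevance surrogate), capped at `maxFeatures` and ranked by
#' absolute weight; weight-magnitude ties are broken toward the lower
#' wavenumber.
#'
#' @param X Numeric matrix, measurements x features (band names as column
#'   names).
#' @param y Two-class label vector (factor or character).
#' @param penaltyPath Optional vector of penalties (decreasing); by default
#'   30 logarithmic points below the smallest penalty zeroing all weights.
#' @param maxFeatures Retain at most this many features (default 9).
#' @param nfolds Cross-validation folds for the penalty choice (default 5).
#' @param seed Integer seed for the fold assignment.
#' @param cvTolerance Sparsity preference in standard-error units
#'   (default 0.5): the strongest penalty scoring within this margin of
#'   the best cross-validated score is selected.
#' @param weightFloor Relative weight floor (default 0.2): retained
#'   features must reach this fraction of the largest absolute weight.
#' @param centers Optional numeric feature positions used for tie-breaks;
#'   defaults to column names parsed as numbers.
#' @return A list of class `"FeatureRanking"`: `ranking` (data frame with
#'   `feature`, `weight`, `rank`, `retained`), `retained` (feature names),
#'   `lambda`, `penaltyPath`, `cvScore` (cross-validated balanced accuracy
#'   at the selected penalty), `trainScore` (training balanced accuracy of
#'   the refitted model).
#' @export
l1RankFeatures <- function(X, y, penaltyPath = NULL, maxFeatures = 9,
                           nfolds = 5, seed = 1, cvTolerance = 0.5,
                           weightFloor = 0.2, centers = NULL) {
    X <- as.matrix(X)
    n <- nrow(X)
    cls <- sort(unique(as.character(y)))
    if (length(cls) != 2)
        stop("exactly two classes are required, got ", length(cls))
    if (n < 10) stop("at least 10 measurements are required")
    yy <- ifelse(as.character(y) == cls[2], 1, -1)
    if (is.null(centers)) {
        centers <- suppressWarnings(as.numeric(colnames(X)))
        if (any(is.na(centers))) centers <- seq_len(ncol(X))
    }
    # standardize columns
    mu <- colMeans(X)
    sdv <- apply(X, 2, sd)
    sdv[sdv == 0] <- 1
    Xs <- sweep(sweep(X, 2, mu), 2, sdv, "/")

    if (is.null(penaltyPath)) {
        lmax <- max(abs(2 * crossprod(Xs, yy) / n)) * 1.05
        penaltyPath <- lmax * 10^seq(0, -3, length.out = 30)
    }
    penaltyPath <- sort(penaltyPath, decreasing = TRUE)

    # stratified CV folds
    folds <- integer(n)
    withr::with_seed(seed, {
        for (cl in cls) {
            idx <- sample(which(as.character(y) == cl))
            folds[idx] <- rep_len(seq_len(nfolds), length(idx))
        }
    })
    scores <- matrix(NA_real_, nfolds, length(penaltyPath))
    for (f in seq_len(nfolds)) {
        tr <- folds != f
        fits <- .l1svmPath(Xs[tr, , drop = FALSE], yy[tr], penaltyPath)
        for (k in seq_along(fits)) {
            pred <- sign(drop(Xs[!tr, , drop = FALSE] %*% fits[[k]]$w) +
                             fits[[k]]$b)
            pred[pred == 0] <- 1
            scores[f, k] <- .balancedAccuracy(yy[!tr], pred)
        }
    }
    meanScore <- colMeans(scores)
    se <- sd(scores[, which.max(meanScore)]) / sqrt(nfolds)
    if (!is.finite(se)) se <- 0
    best <- which(meanScore >= max(meanScore) - cvTolerance * se)[1]

    fullFits <- .l1svmPath(Xs, yy, penaltyPath)
    nzero <- vapply(fullFits, function(f) sum(f$w != 0), integer(1))
    k <- best
    while (k > 1 && nzero[k] > maxFeatures) k <- k - 1
    if (nzero[k] > maxFeatures)
        warning("penalty path never reached <= ", maxFeatures,
                " features; returning the sparsest solution")
    w <- fullFits[[k]]$w
    ord <- order(-abs(w), centers)
    floorVal <- weightFloor * max(abs(w))
    retainedIdx <- ord[abs(w[ord]) > 0 & abs(w[ord]) >= floorVal]
    retainedIdx <- head(retainedIdx, maxFeatures)
    nm <- colnames(X)
    if (is.null(nm)) nm <- sprintf("f%02d", seq_len(ncol(X)))
    ranking <- data.frame(
        feature = nm[ord], weight = w[ord],
        rank = seq_along(ord),
        retained = ord %in% retainedIdx,
        stringsAsFactors = FALSE
    )
    predFull <- sign(drop(Xs %*% w) + fullFits[[k]]$b)
    predFull[predFull == 0] <- 1
    structure(list(
        ranking = ranking,
        retained = nm[sort(retainedIdx)],
        lambda = penaltyPath[k],
        penaltyPath = penaltyPath,
        cvScore = meanScore[k],
        trainScore = .balancedAccuracy(yy, predFull),
        positiveClass = cls[2]
    ), class = "FeatureRanking")
}
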