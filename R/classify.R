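# Binary tissue classification: class-weighted linear SVM with
# patient-grouped five-fold cross-validation, Platt-calibrated posteriors,
# ROC analysis and closest-to-corner operating points.

.MODEL_DEFS <- list(
    A = list(positive = "cancer", keep = c("cancer", "normal", "fat"),
             description = "cancer vs normal+fat"),
    B = list(positive = "cancer", keep = c("cancer", "normal"),
             description = "cancer vs normal"),
    C = list(positive = "cancer", keep = c("cancer", "fat"),
             description = "cancer vs fat"),
    FAT = list(positive = "fat", keep = c("cancer", "normal", "fat"),
               description = "fat vs cancer+normal")
)

#' Model specification for a binary classifier
#'
#' @param model Model id: `"A"` (cancer vs normal+fat), `"B"` (cancer vs
#'   normal), `"C"` (cancer vs fat) or `"FAT"` (fat vs cancer+normal).
#' @param cGrid Grid for the SVM regularization parameter C, within
#'   `[1e-3, 1]`; default 7 logarithmic points.
#' @param gammaGrid Grid of minority-class cost multipliers applied on top
#'   of the inverse-class-frequency baseline weights.
#' @param folds Cross-validation folds (default 5, patient-grouped).
#' @param maxFeatures Cap on the selected feature count (default 9).
#' @param seed Integer seed for fold assignment and feature selection.
#' @return A list of class `"ModelSpec"`.
#' @export
modelSpec <- function(model = c("A", "B", "C", "FAT"),
                      cGrid = 10^seq(-3, 0, length.out = 7),
                      gammaGrid = c(1, 2, 5, 10),
                      folds = 5, maxFeatures = 9, seed = 1) {
    model <- match.arg(model)
    if (length(cGrid) == 0 || length(gammaGrid) == 0)
        stop("hyperparameter grids must be nonempty")
    if (any(cGrid < 1e-3 - 1e-12) || any(cGrid > 1 + 1e-12))
        stop("C grid values must lie within [1e-3, 1]")
    structure(c(list(model = model), .MODEL_DEFS[[model]],
                list(cGrid = cGrid, gammaGrid = gammaGrid, folds = folds,
                     maxFeatures = maxFeatures, seed = seed)),
              class = "ModelSpec")
}

#' Patient-grouped fold assignment
#'
#' Partitions patients (not measurements) into `k` near-equal groups so
#' that all measurements of a patient share a fold and no patient can
#' appear on both sides of a train/test split.
#'
#' @param patientIds Patient identifier per measurement.
#' @param k Number of folds (default 5).
#' @param seed Integer seed.
#' @return Integer fold assignment per measurement, in 1..k.
#' @examples
#' folds <- makeGroupedFolds(rep(sprintf("P%02d", 1:20), each = 3), k = 5)
#' @export
makeGroupedFolds <- function(patientIds, k = 5, seed = 1) {
    patients <- unique(patientIds)
    if (length(patients) < k)
        stop("cannot build ", k, " patient-grouped folds from only ",
             length(patients), " patients")
    shuffled <- withr::with_seed(seed, sample(patients))
    patientFold <- setNames(rep_len(seq_len(k), length(shuffled)), shuffled)
    unname(patientFold[as.character(patientIds)])
}

# Platt-style sigmoid calibration: fits p(f) = 1 / (1 + exp(a f + b)) by
# minimizing cross-entropy against regularized targets, which keeps the fit
# finite on separable training sets.
.plattFit <- function(decision, isPositive) {
    nPos <- sum(isPositive)
    nNeg <- sum(!isPositive)
    t <- ifelse(isPositive, (nPos + 1) / (nPos + 2), 1 / (nNeg + 2))
    nll <- function(par) {
        z <- par[1] * decision + par[2]
        p <- 1 / (1 + exp(z))
        eps <- 1e-12
        -sum(t * log(p + eps) + (1 - t) * log(1 - p + eps))
    }
    fit <- optim(c(-1, 0), nll, method = "BFGS")
    par <- fit$par
    if (par[1] > 0) par <- c(-1e-3, 0)  # enforce monotone-increasing map
    par
}

.plattApply <- function(par, decision) {
    1 / (1 + exp(par[1] * decision + par[2]))
}

#' Train a class-weighted linear SVM with calibrated posteriors
#'
#' Linear-kernel SVM with regularization parameter `C` and per-class
#' misclassification costs: both classes start at inverse-frequency
#' weights and the minority class is further multiplied by `gamma`. A
#' monotone sigmoid posterior calibration is fitted on the training
#' decision values.
#'
#' @param X Numeric matrix, measurements x features.
#' @param y Two-class label vector.
#' @param C Regularization parameter.
#' @param gamma Minority-class cost multiplier (default 1).
#' @param positiveClass Label to treat as positive; default the rarer one.
#' @param seed Unused placeholder for interface stability (the fit is
#'   deterministic); kept so callers can thread seeds uniformly.
#' @return A [TrainedSVM-class].
#' @export
trainWeightedSvm <- function(X, y, C = 1, gamma = 1, positiveClass = NULL,
                             seed = 1) {
    X <- as.matrix(X)
    y <- as.character(y)
    cls <- sort(unique(y))
    if (length(cls) != 2)
        stop("exactly two classes are required, got ", length(cls))
    counts <- table(y)
    if (is.null(positiveClass))
        positiveClass <- names(counts)[which.min(counts)]
    stopifnot(positiveClass %in% cls)
    minority <- names(counts)[which.min(counts)]
    wts <- length(y) / (2 * counts)
    wts[minority] <- wts[minority] * gamma

    mu <- colMeans(X)
    sdv <- apply(X, 2, sd)
    sdv[sdv == 0] <- 1
    Xs <- sweep(sweep(X, 2, mu), 2, sdv, "/")

    yf <- factor(y, levels = c(positiveClass, setdiff(cls, positiveClass)))
    fit <- e1071::svm(Xs, yf, kernel = "linear", cost = C,
                      class.weights = as.numeric(wts) |>
                          setNames(names(wts)),
                      scale = FALSE)
    dv <- drop(attr(predict(fit, Xs, decision.values = TRUE),
                    "decision.values"))
    # orient decision values so larger means more positive-class
    cv <- suppressWarnings(cor(dv, as.numeric(yf == positiveClass)))
    flip <- if (!is.na(cv) && cv < 0) -1 else 1
    dv <- flip * dv
    w <- flip * drop(t(fit$coefs) %*% fit$SV)
    b <- flip * -fit$rho
    cal <- .plattFit(dv, yf == positiveClass)
    new("TrainedSVM", weights = unname(w), bias = unname(b), cost = C,
        classCost = gamma, positiveClass = positiveClass,
        calibration = cal,
        featureNames = colnames(X) %||% sprintf("f%02d", seq_len(ncol(X))),
        fit = fit,
        scaling = list(center = mu, scale = sdv, flip = flip))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Posterior probabilities from a trained SVM
#'
#' @param model A [TrainedSVM-class].
#' @param X Feature matrix on the training feature set.
#' @return Posterior probability of the positive class per row, in [0, 1].
#' @export
svmPosterior <- function(model, X) {
    X <- as.matrix(X)
    Xs <- sweep(sweep(X, 2, model@scaling$center), 2,
                model@scaling$scale, "/")
    dv <- model@scaling$flip *
        drop(attr(predict(model@fit, Xs, decision.values = TRUE),
                  "decision.values"))
    .plattApply(model@calibration, dv)
}

#' Grid search with patient-grouped cross-validation
#'
#' For every (C, gamma) grid point, trains on four patient-grouped folds
#' and evaluates held-out posteriors on the fifth; the grid point with the
#' best mean fold AUC wins. Pooled held-out posteriors at the winning grid
#' point are returned for ROC analysis.
#'
#' @param X Feature matrix, measurements x features.
#' @param y Two-class labels.
#' @param groups Patient id per measurement.
#' @param spec A [modelSpec()].
#' @return List: `bestC`, `bestGamma`, `posteriors` (pooled held-out, in
#'   input order), `report` (one row per fold x grid point), `folds`,
#'   `meanAUC` (winning grid point), `foldAUCs`.
#' @export
gridSearchCv <- function(X, y, groups, spec = modelSpec("A")) {
    X <- as.matrix(X)
    y <- as.character(y)
    folds <- makeGroupedFolds(groups, k = spec$folds, seed = spec$seed)
    grid <- expand.grid(C = spec$cGrid, gamma = spec$gammaGrid,
                        KEEP.OUT.ATTRS = FALSE)
    report <- list()
    pooled <- matrix(NA_real_, nrow(X), nrow(grid))
    aucs <- matrix(NA_real_, spec$folds, nrow(grid))
    for (g in seq_len(nrow(grid))) {
        for (f in seq_len(spec$folds)) {
            tr <- folds != f
            stopifnot(length(intersect(groups[tr], groups[!tr])) == 0)
            if (length(unique(y[tr])) < 2) {
                aucs[f, g] <- NA
                next
            }
            m <- trainWeightedSvm(X[tr, , drop = FALSE], y[tr],
                                  C = grid$C[g], gamma = grid$gamma[g],
                                  positiveClass = spec$positive)
            p <- svmPosterior(m, X[!tr, , drop = FALSE])
            pooled[!tr, g] <- p
            aucs[f, g] <- if (length(unique(y[!tr])) < 2) NA
                else .aucTrapezoid(p, y[!tr] == spec$positive)
            report[[length(report) + 1L]] <- data.frame(
                fold = f, C = grid$C[g], gamma = grid$gamma[g],
                auc = aucs[f, g], nTest = sum(!tr))
        }
    }
    meanAUC <- colMeans(aucs, na.rm = TRUE)
    best <- which.max(meanAUC)  # first maximum: smaller C, then smaller gamma
    list(bestC = grid$C[best], bestGamma = grid$gamma[best],
         posteriors = pooled[, best], report = do.call(rbind, report),
         folds = folds, meanAUC = meanAUC[best], foldAUCs = aucs[, best])
}

# Trapezoidal AUC of posterior p for logical labels (TRUE = positive).
.aucTrapezoid <- function(p, pos) {
    roc <- .rocPoints(p, pos)
    fpr <- c(0, rev(1 - roc$specificity), 1)
    tpr <- c(0, rev(roc$sensitivity), 1)
    ord <- order(fpr, tpr)
    fpr <- fpr[ord]; tpr <- tpr[ord]
    sum(diff(fpr) * (head(tpr, -1) + tpr[-1]) / 2)
}

.rocPoints <- function(p, pos) {
    thresholds <- sort(unique(c(0, 1, p)))
    sens <- spec <- numeric(length(thresholds))
    nPos <- sum(pos); nNeg <- sum(!pos)
    for (i in seq_along(thresholds)) {
        pred <- p >= thresholds[i]
        sens[i] <- sum(pred & pos) / nPos
        spec[i] <- sum(!pred & !pos) / nNeg
    }
    list(thresholds = thresholds, sensitivity = sens, specificity = spec)
}

#' ROC curve from calibrated posteriors
#'
#' Sweeps the decision threshold lambda over every distinct posterior value
#' (plus 0 and 1), assigning the positive label where `p >= lambda`. The
#' AUC is the trapezoidal area, which equals the pairwise concordance
#' probability (ties counted one half).
#'
#' @param posteriors Posterior probabilities in [0, 1].
#' @param y Labels; either logical (TRUE = positive) or a two-class vector
#'   with `positiveClass` naming the positive one.
#' @param positiveClass Positive label when `y` is not logical.
#' @return A [ROCResult-class] (operating point filled in by
#'   [operatingPoint()], which is called internally).
#' @examples
#' r <- rocCurve(c(0.9, 0.8, 0.4, 0.3), c(TRUE, TRUE, FALSE, FALSE))
#' auc(r)  # 1
#' @export
rocCurve <- function(posteriors, y, positiveClass = NULL) {
    if (any(posteriors < 0 | posteriors > 1))
        stop("posteriors must lie in [0, 1]")
    pos <- if (is.logical(y)) y else {
        if (is.null(positiveClass))
            stop("positiveClass is required for non-logical labels")
        as.character(y) == positiveClass
    }
    if (all(pos) || !any(pos))
        stop("both classes must be present to compute a ROC curve")
    pts <- .rocPoints(posteriors, pos)
    aucVal <- .aucTrapezoid(posteriors, pos)
    roc <- new("ROCResult", thresholds = pts$thresholds,
               sensitivity = pts$sensitivity,
               specificity = pts$specificity,
               auc = aucVal, operatingPoint = list(),
               confusion = matrix(0, 2, 2), posteriors = posteriors,
               labels = pos)
    operatingPoint(roc)
}

#' Closest-to-corner operating point
#'
#' Selects the ROC point minimizing the Euclidean distance to the upper
#' left corner (perfect sensitivity and specificity); ties are broken
#' toward the higher sensitivity. The confusion matrix and accuracy at the
#' selected threshold are recomputed from the stored posteriors.
#'
#' @param roc A [ROCResult-class].
#' @return The [ROCResult-class] with `operatingPoint` and `confusion`
#'   filled in.
#' @export
operatingPoint <- function(roc) {
    stopifnot(is(roc, "ROCResult"))
    if (length(roc@thresholds) == 0) stop("empty ROC curve")
    d <- sqrt((1 - roc@specificity)^2 + (1 - roc@sensitivity)^2)
    cand <- which(d <= min(d) + 1e-12)
    best <- cand[which.max(roc@sensitivity[cand])]
    lam <- roc@thresholds[best]
    pred <- roc@posteriors >= lam
    pos <- roc@labels
    confusion <- matrix(
        c(sum(pred & pos), sum(pred & !pos),
          sum(!pred & pos), sum(!pred & !pos)),
        nrow = 2, byrow = TRUE,
        dimnames = list(predicted = c("positive", "negative"),
                        truth = NULL))
    colnames(confusion) <- c("positive", "negative")
    acc <- (confusion[1, 1] + confusion[2, 2]) / length(pos)
    roc@operatingPoint <- list(
        lambda = lam,
        sensitivity = roc@sensitivity[best],
        specificity = roc@specificity[best],
        accuracy = acc
    )
    roc@confusion <- confusion
    validObject(roc)
    roc
}

#' Run one binary classification model end to end
#'
#' Composes sparse band selection ([l1RankFeatures()]), the (C, gamma) grid
#' search with patient-grouped cross-validation ([gridSearchCv()]), ROC
#' analysis of the pooled held-out posteriors and the closest-to-corner
#' operating point.
#'
#' @param dataset A [RamanExperiment-class] with `label` and `patient_id`
#'   in its `colData`, or a feature SummarizedExperiment from
#'   [buildFeatureMatrix()].
#' @param model Model id (`"A"`, `"B"`, `"C"`, `"FAT"`) or a [modelSpec()].
#' @param bands Band registry used for features, default [tableBands()].
#' @param selectFeatures If `FALSE`, skip selection and use all bands.
#' @return A list of class `"ModelReport"`: `model`, `description`,
#'   `retainedBands`, `featureRanking`, `bestC`, `bestGamma`, `roc`
#'   ([ROCResult-class]), `auc`, `operatingPoint`, `confusion`,
#'   `foldAUCs`, `cvReport`, `n`, `classCounts`.
#' @export
runModel <- function(dataset, model = "A", bands = tableBands(),
                     selectFeatures = TRUE) {
    spec <- if (inherits(model, "ModelSpec")) model else modelSpec(model)
    fm <- if (is(dataset, "RamanExperiment"))
        buildFeatureMatrix(dataset, bands = bands) else dataset
    cd <- SummarizedExperiment::colData(fm)
    stopifnot(all(c("label", "patient_id") %in% colnames(cd)))
    keep <- cd$label %in% spec$keep
    X <- featureValues(fm)[keep, , drop = FALSE]
    labels <- as.character(cd$label[keep])
    groups <- as.character(cd$patient_id[keep])
    y <- ifelse(labels == spec$positive, spec$positive,
                paste0("not_", spec$positive))
    if (length(unique(y)) < 2)
        stop("dichotomy '", spec$description,
             "' has a single class in this dataset")

    ranking <- NULL
    if (selectFeatures) {
        ranking <- l1RankFeatures(X, y, maxFeatures = spec$maxFeatures,
                                  seed = spec$seed)
        if (length(ranking$retained) >= 1)
            X <- X[, ranking$retained, drop = FALSE]
    }
    cvfit <- gridSearchCv(X, y, groups, spec)
    roc <- rocCurve(cvfit$posteriors, y == spec$positive)
    structure(list(
        model = spec$model, description = spec$description,
        retainedBands = colnames(X),
        featureRanking = ranking,
        bestC = cvfit$bestC, bestGamma = cvfit$bestGamma,
        roc = roc, auc = roc@auc,
        operatingPoint = roc@operatingPoint,
        confusion = roc@confusion,
        foldAUCs = cvfit$foldAUCs, cvReport = cvfit$report,
        n = nrow(X),
        classCounts = table(labels)
    ), class = "ModelReport")
}

#' Reduced-accumulation re-analysis
#'
#' Truncates every acquisition to its first N accumulations, reruns the
#' full preprocessing pipeline, and retrains the requested models, once
#' per N. Cohort membership (quality gate, labeling, fat screen) is
#' decided once at the largest N — the reference run — and the same
#' retained measurements are re-preprocessed at each smaller N, so the
#' comparison isolates the effect of reduced signal averaging from
#' cohort-composition changes. Quantifies how shorter interrogation times
#' degrade classification performance.
#'
#' @param acquisitions List of [RawAcquisition-class].
#' @param manifest Measurement manifest data frame.
#' @param standard Reference-standard list (see
#'   [generateReferenceStandard()]).
#' @param calibration A [CalibrationModel-class].
#' @param config A [pipelineConfig()].
#' @param nList Accumulation counts to evaluate (default `c(10, 5, 1)`).
#' @param models Model ids to train per N (default `"B"`).
#' @param modelSeed Seed threaded into each [modelSpec()].
#' @return Named list (one element per N) of lists with `n`, `ledger` and
#'   one `"ModelReport"` per model id.
#' @export
accumulationStudy <- function(acquisitions, manifest, standard, calibration,
                              config = pipelineConfig(),
                              nList = c(10, 5, 1), models = "B",
                              modelSeed = 1) {
    avail <- min(vapply(acquisitions, function(a) ncol(a@repeats),
                        integer(1)))
    if (any(nList > avail))
        stop("requested ", max(nList), " accumulations but only ", avail,
             " are available")
    nRef <- max(nList)
    ref <- buildDataset(acquisitions, manifest, standard, calibration,
                        config = config, nAccumulations = nRef)
    refCd <- SummarizedExperiment::colData(ref$experiment)
    retained <- rownames(refCd)
    ids <- manifest$measurement_id
    out <- list()
    for (nAcc in sort(nList, decreasing = TRUE)) {
        if (nAcc == nRef) {
            ds <- ref
        } else {
            spectra <- lapply(acquisitions[match(retained, ids)],
                              runPipeline, standard = standard,
                              calibration = calibration, config = config,
                              nAccumulations = nAcc)
            wn <- spectra[[1]]@wavenumber
            mat <- vapply(spectra, function(s) s@intensity,
                          numeric(length(wn)))
            colnames(mat) <- retained
            ds <- list(experiment = RamanExperiment(mat, wn, refCd),
                       ledger = ref$ledger)
        }
        reports <- lapply(models, function(m)
            runModel(ds$experiment, modelSpec(m, seed = modelSeed)))
        names(reports) <- models
        out[[paste0("N", nAcc)]] <- c(list(n = nAcc, ledger = ds$ledger),
                                      reports)
    }
    out[paste0("N", nList)]
}
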