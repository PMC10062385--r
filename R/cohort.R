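# Histology-composition labeling, fat-consistency screening, and the
# exclusion ledger from raw measurement count to the final dataset.

#' Assign a histology label from cell-composition percentages
#'
#' The 80/80/70 rule: cancer if the cancer-cell percentage is >= 80, else
#' normal if the normal-cell percentage is >= 80, else fat if the
#' adipose-cell percentage is >= 70; otherwise the measurement fits no
#' category and is excluded.
#'
#' @param pctCancer,pctNormal,pctFat Percentages in [0, 100] (vectorized).
#' @return Character vector: `"cancer"`, `"normal"`, `"fat"` or
#'   `"excluded"`.
#' @examples
#' assignLabel(80, 10, 10)   # cancer (boundary is inclusive)
#' assignLabel(10, 15, 70)   # fat
#' assignLabel(50, 30, 20)   # excluded
#' @export
assignLabel <- function(pctCancer, pctNormal, pctFat) {
    p <- cbind(pctCancer, pctNormal, pctFat)
    if (any(p < 0 | p > 100))
        stop("composition percentages must lie in [0, 100]")
    unname(ifelse(p[, 1] >= 80, "cancer",
                  ifelse(p[, 2] >= 80, "normal",
                         ifelse(p[, 3] >= 70, "fat", "excluded"))))
}

#' Fat-consistency screen
#'
#' Adipose tissue has a Raman signature dramatically different from
#' protein-rich tissue (no phenylalanine band at 1004 cm^-1, strong lipid
#' bands). This screen trains a fat-vs-rest classifier on the labeled
#' measurements and flags every record whose predicted fat status
#' contradicts its composition-derived label — the operational form of the
#' suspected-mislabeling exclusion.
#'
#' @param features Feature matrix (measurements x bands).
#' @param labels Composition-derived label per measurement (`"cancer"`,
#'   `"normal"`, `"fat"`).
#' @param patientGroups Patient id per measurement (currently carried for
#'   interface symmetry; the screen trains on all rows).
#' @param C,gamma SVM hyperparameters for the screen model.
#' @return Logical vector: `TRUE` where the spectral signature contradicts
#'   the label; attribute `"predictedFat"` carries the raw predictions.
#' @export
fatConsistencyScreen <- function(features, labels, patientGroups = NULL,
                                 C = 0.1, gamma = 1) {
    X <- as.matrix(features)
    labels <- as.character(labels)
    isFat <- ifelse(labels == "fat", "fat", "not_fat")
    if (length(unique(isFat)) < 2)
        stop("fat screen needs both fat and non-fat measurements")
    model <- trainWeightedSvm(X, isFat, C = C, gamma = gamma,
                              positiveClass = "fat")
    p <- svmPosterior(model, X)
    predictedFat <- p >= 0.5
    flags <- predictedFat != (labels == "fat")
    attr(flags, "predictedFat") <- predictedFat
    flags
}

#' Build the labeled dataset and exclusion ledger from raw acquisitions
#'
#' Runs the full workflow: preprocessing pipeline per acquisition, quality
#' gate, composition-based labeling, and the fat-consistency screen, in
#' that order, recording every exclusion with its reason.
#'
#' @param acquisitions List of [RawAcquisition-class], named by
#'   measurement id.
#' @param manifest Manifest data frame with `measurement_id`,
#'   `patient_id`, `pct_cancer`, `pct_normal`, `pct_fat` columns.
#' @param standard Reference-standard list (see
#'   [generateReferenceStandard()]).
#' @param calibration A [CalibrationModel-class].
#' @param config A [pipelineConfig()].
#' @param nAccumulations Optional truncation of accumulations used.
#' @param fatScreen Run the fat-consistency screen (default `TRUE`).
#' @return List: `experiment` (a [RamanExperiment-class] of retained
#'   measurements), `ledger` (an [ExclusionLedger-class]), `qcReport`
#'   (per-measurement quality table), `exclusions` (data frame of excluded
#'   measurement ids and reasons).
#' @export
buildDataset <- function(acquisitions, manifest, standard, calibration,
                         config = pipelineConfig(), nAccumulations = NULL,
                         fatScreen = TRUE) {
    stopifnot(length(acquisitions) == nrow(manifest))
    ids <- manifest$measurement_id
    spectra <- lapply(acquisitions, runPipeline, standard = standard,
                      calibration = calibration, config = config,
                      nAccumulations = nAccumulations)
    names(spectra) <- ids

    # (1) quality gate
    qc <- qcFilter(spectra, threshold = config$qcThreshold)
    lowQuality <- ids[!qc$report$passed]

    # (2) composition-based labeling
    lab <- assignLabel(manifest$pct_cancer, manifest$pct_normal,
                       manifest$pct_fat)
    noCategory <- setdiff(ids[lab == "excluded"], lowQuality)

    surviving <- setdiff(ids, c(lowQuality, noCategory))
    if (length(surviving) == 0)
        stop("no measurements survive the quality gate and labeling rule")
    labels <- setNames(lab, ids)[surviving]

    # (3) fat-consistency screen on the survivors
    mismatch <- character(0)
    if (fatScreen && length(unique(labels)) > 1 && any(labels == "fat")) {
        fm <- buildFeatureMatrix(spectra[surviving])
        flags <- fatConsistencyScreen(
            featureValues(fm), labels,
            manifest$patient_id[match(surviving, ids)])
        mismatch <- surviving[flags]
    }
    retained <- setdiff(surviving, mismatch)
    if (length(retained) == 0)
        stop("no measurements survive the fat-consistency screen")

    keepIdx <- match(retained, ids)
    wn <- spectra[[retained[1]]]@wavenumber
    mat <- vapply(spectra[retained], function(s) s@intensity,
                  numeric(length(wn)))
    cd <- manifest[keepIdx, , drop = FALSE]
    cd$label <- labels[retained]
    cd$qf <- qc$report$qf[keepIdx]
    rownames(cd) <- retained

    classCounts <- table(factor(cd$label,
                                levels = c("cancer", "normal", "fat")))
    ledger <- new("ExclusionLedger",
        initial = nrow(manifest),
        excluded = c(low_quality = length(lowQuality),
                     no_category = length(noCategory),
                     signature_mismatch = length(mismatch)),
        final = length(retained),
        classCounts = setNames(as.numeric(classCounts),
                               names(classCounts)))

    exclusions <- data.frame(
        measurement_id = c(lowQuality, noCategory, mismatch),
        reason = rep(c("low_quality", "no_category", "signature_mismatch"),
                     c(length(lowQuality), length(noCategory),
                       length(mismatch))),
        stringsAsFactors = FALSE
    )
    list(
        experiment = RamanExperiment(mat, wn, cd),
        ledger = ledger,
        qcReport = qc$report,
        exclusions = exclusions
    )
}
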