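#' @import methods
#' @importClassesFrom SummarizedExperiment SummarizedExperiment
#' @importFrom SummarizedExperiment SummarizedExperiment assay rowData colData
#' @importFrom S4Vectors DataFrame
#' @importFrom stats approx coef glm lm median optim predict quantile rnorm
#'   runif sd setNames var
#' @importFrom utils head read.csv read.delim write.csv
NULL

#' Single Raman spectrum
#'
#' The unit of data flowing through the preprocessing pipeline: a wavenumber
#' axis (cm^-1), one intensity vector, and a tag recording how far along the
#' pipeline the spectrum has travelled.
#'
#' @slot wavenumber Numeric, strictly increasing Raman shifts in cm^-1.
#' @slot intensity Numeric intensity vector, same length as `wavenumber`.
#' @slot stage Character scalar, one of `"raw"`, `"averaged"`,
#'   `"dark_subtracted"`, `"response_corrected"`, `"calibrated"`,
#'   `"baseline_removed"`, `"snv"`.
#' @slot metadata List of free-form provenance entries.
#'
#' @aliases RamanSpectrum-class
#' @exportClass RamanSpectrum
setClass("RamanSpectrum",
    representation(
        wavenumber = "numeric",
        intensity = "numeric",
        stage = "character",
        metadata = "list"
    ),
    prototype(stage = "raw", metadata = list())
)

.PIPELINE_STAGES <- c(
    "raw", "averaged", "dark_subtracted", "response_corrected",
    "calibrated", "baseline_removed", "snv"
)

setValidity("RamanSpectrum", function(object) {
    msg <- NULL
    if (length(object@wavenumber) != length(object@intensity))
        msg <- c(msg, "wavenumber and intensity lengths differ")
    if (length(object@wavenumber) > 1L && any(diff(object@wavenumber) <= 0))
        msg <- c(msg, "wavenumber axis must be strictly increasing")
    if (length(object@stage) != 1L || !object@stage %in% .PIPELINE_STAGES)
        msg <- c(msg, sprintf(
            "stage must be one of: %s", paste(.PIPELINE_STAGES, collapse = ", ")
        ))
    if (is.null(msg)) TRUE else msg
})

#' Construct a RamanSpectrum
#'
#' @param wavenumber Strictly increasing Raman-shift axis (cm^-1).
#' @param intensity Intensity values, same length as `wavenumber`.
#' @param stage Pipeline stage tag (default `"raw"`).
#' @param metadata Optional list of provenance entries.
#' @return A [RamanSpectrum-class] object.
#' @examples
#' s <- RamanSpectrum(600:700, rnorm(101))
#' @export
RamanSpectrum <- function(wavenumber, intensity, stage = "raw",
                          metadata = list()) {
    new("RamanSpectrum", wavenumber = as.numeric(wavenumber),
        intensity = as.numeric(intensity), stage = stage, metadata = metadata)
}

#' Raw probe acquisition at one tissue point
#'
#' Holds the repeat spectra (accumulations) and dark frames measured at a
#' single probed point, with the acquisition settings needed downstream.
#' Spectra are stored in columns (points x repeats), the convention used for
#' assay matrices throughout the package.
#'
#' @slot wavenumber Numeric axis in cm^-1 (or pixel index before calibration).
#' @slot repeats P x N matrix of repeat spectra, one accumulation per column.
#' @slot darks P x K matrix of dark frames (laser off), K >= 1.
#' @slot exposure Exposure time per accumulation, seconds.
#' @slot laserPower Laser power at the tissue surface, mW.
#' @slot metadata List with patient/sample/position identifiers.
#'
#' @aliases RawAcquisition-class
#' @exportClass RawAcquisition
setClass("RawAcquisition",
    representation(
        wavenumber = "numeric",
        repeats = "matrix",
        darks = "matrix",
        exposure = "numeric",
        laserPower = "numeric",
        metadata = "list"
    ),
    prototype(exposure = 1, laserPower = 100, metadata = list())
)

setValidity("RawAcquisition", function(object) {
    msg <- NULL
    p <- length(object@wavenumber)
    if (nrow(object@repeats) != p)
        msg <- c(msg, "repeats must have one row per wavenumber")
    if (ncol(object@repeats) < 1L)
        msg <- c(msg, "at least one accumulation is required")
    if (nrow(object@darks) != p)
        msg <- c(msg, "darks must share the repeats' wavenumber axis")
    if (ncol(object@darks) < 1L)
        msg <- c(msg, "at least one dark frame is required")
    if (length(object@exposure) != 1L || object@exposure <= 0)
        msg <- c(msg, "exposure must be a positive scalar (seconds)")
    if (is.null(msg)) TRUE else msg
})

#' Construct a RawAcquisition
#'
#' @param wavenumber Wavenumber axis (cm^-1).
#' @param repeats P x N matrix of accumulations (columns).
#' @param darks P x K matrix of dark frames (columns).
#' @param exposure Exposure per accumulation in seconds.
#' @param laserPower Laser power in mW.
#' @param metadata List of identifiers (patient, sample, position).
#' @return A [RawAcquisition-class] object.
#' @export
RawAcquisition <- function(wavenumber, repeats, darks, exposure = 1,
                           laserPower = 100, metadata = list()) {
    new("RawAcquisition", wavenumber = as.numeric(wavenumber),
        repeats = as.matrix(repeats), darks = as.matrix(darks),
        exposure = exposure, laserPower = laserPower, metadata = metadata)
}

#' Wavenumber calibration model
#'
#' Low-order polynomial mapping the observed axis to corrected Raman shifts,
#' fitted from reference peaks detected on a polycarbonate spectrum.
#'
#' @slot coefficients Polynomial coefficients, intercept first.
#' @slot degree Polynomial degree (1 or 2).
#' @slot residuals Per-matched-peak residuals (cm^-1) after fitting.
#' @slot matchedPeaks Data frame of detected vs reference peak positions.
#'
#' @aliases CalibrationModel-class
#' @exportClass CalibrationModel
setClass("CalibrationModel",
    representation(
        coefficients = "numeric",
        degree = "numeric",
        residuals = "numeric",
        matchedPeaks = "data.frame"
    )
)

#' Spectral quality report
#'
#' The 0-to-1 quality factor of an SNV-normalized spectrum together with the
#' pass/fail decision at the exclusion gate.
#'
#' @slot qf Quality factor in [0, 1].
#' @slot threshold Gate threshold (default 0.6).
#' @slot passed `TRUE` iff `qf >= threshold`.
#' @slot diagnostics List with `residual_energy` and `total_energy`.
#'
#' @aliases QualityReport-class
#' @exportClass QualityReport
setClass("QualityReport",
    representation(
        qf = "numeric",
        threshold = "numeric",
        passed = "logical",
        diagnostics = "list"
    )
)

setValidity("QualityReport", function(object) {
    msg <- NULL
    if (object@qf < 0 || object@qf > 1)
        msg <- c(msg, "qf must lie in [0, 1]")
    if (!identical(object@passed, object@qf >= object@threshold))
        msg <- c(msg, "passed must equal qf >= threshold")
    if (is.null(msg)) TRUE else msg
})

#' Exclusion ledger
#'
#' Accounting of the path from raw measurement count to the final labeled
#' dataset: how many measurements each exclusion stage removed and why.
#'
#' @slot initial Number of measurements entering the workflow.
#' @slot excluded Named numeric: counts for `low_quality`, `no_category`,
#'   `signature_mismatch`.
#' @slot final Number of retained measurements.
#' @slot classCounts Named numeric: retained counts per tissue class.
#'
#' @aliases ExclusionLedger-class
#' @exportClass ExclusionLedger
setClass("ExclusionLedger",
    representation(
        initial = "numeric",
        excluded = "numeric",
        final = "numeric",
        classCounts = "numeric"
    )
)

setValidity("ExclusionLedger", function(object) {
    msg <- NULL
    if (object@initial != object@final + sum(object@excluded))
        msg <- c(msg, "initial must equal final + sum of exclusions")
    if (sum(object@classCounts) != object@final)
        msg <- c(msg, "class counts must sum to the final count")
    if (is.null(msg)) TRUE else msg
})

#' Trained class-weighted linear SVM
#'
#' Linear decision function with per-class misclassification costs and a
#' Platt-style sigmoid posterior calibration fitted on the training data.
#'
#' @slot weights Linear weights, one per feature (decision-value scale).
#' @slot bias Decision-function intercept.
#' @slot cost Regularization parameter C.
#' @slot classCost Extra misclassification cost gamma on the minority class.
#' @slot positiveClass Label treated as the positive class.
#' @slot calibration Numeric `c(a, b)` of the sigmoid
#'   `p = 1 / (1 + exp(a * f + b))`.
#' @slot featureNames Feature (band) names in training order.
#' @slot fit The underlying `e1071::svm` fit.
#' @slot scaling List with training-column `center` and `scale`.
#'
#' @aliases TrainedSVM-class
#' @exportClass TrainedSVM
setClass("TrainedSVM",
    representation(
        weights = "numeric",
        bias = "numeric",
        cost = "numeric",
        classCost = "numeric",
        positiveClass = "character",
        calibration = "numeric",
        featureNames = "character",
        fit = "ANY",
        scaling = "list"
    )
)

#' ROC analysis result
#'
#' Sensitivity/specificity swept over posterior thresholds, trapezoidal AUC,
#' and the closest-to-corner operating point with its confusion matrix.
#'
#' @slot thresholds Threshold values lambda (includes 0 and 1).
#' @slot sensitivity Sensitivity at each threshold.
#' @slot specificity Specificity at each threshold.
#' @slot auc Area under the curve (trapezoidal).
#' @slot operatingPoint List: `lambda`, `sensitivity`, `specificity`,
#'   `accuracy`.
#' @slot confusion 2 x 2 confusion matrix at the operating point.
#' @slot posteriors The posteriors the curve was computed from.
#' @slot labels Logical vector of true positive-class membership.
#'
#' @aliases ROCResult-class
#' @exportClass ROCResult
setClass("ROCResult",
    representation(
        thresholds = "numeric",
        sensitivity = "numeric",
        specificity = "numeric",
        auc = "numeric",
        operatingPoint = "list",
        confusion = "matrix",
        posteriors = "numeric",
        labels = "logical"
    )
)

setValidity("ROCResult", function(object) {
    msg <- NULL
    if (any(object@sensitivity < 0 | object@sensitivity > 1))
        msg <- c(msg, "sensitivity must lie in [0, 1]")
    if (any(object@specificity < 0 | object@specificity > 1))
        msg <- c(msg, "specificity must lie in [0, 1]")
    if (object@auc < 0 || object@auc > 1)
        msg <- c(msg, "AUC must lie in [0, 1]")
    if (is.null(msg)) TRUE else msg
})

#' Cohort of processed spectra with measurement metadata
#'
#' A [SummarizedExperiment::SummarizedExperiment] subclass holding the
#' SNV-normalized spectra of the retained measurements: one assay
#' (`"snv"`, wavenumber points x measurements), the wavenumber axis in
#' `rowData`, and the measurement manifest (patient, composition
#' percentages, label, quality factor) in `colData`.
#'
#' @aliases RamanExperiment-class
#' @exportClass RamanExperiment
setClass("RamanExperiment", contains = "SummarizedExperiment")

#' Construct a RamanExperiment
#'
#' @param snv P x n matrix of SNV spectra (measurements in columns).
#' @param wavenumber Length-P wavenumber axis (cm^-1).
#' @param colData Data frame of per-measurement metadata.
#' @return A [RamanExperiment-class].
#' @export
RamanExperiment <- function(snv, wavenumber, colData) {
    se <- SummarizedExperiment::SummarizedExperiment(
        assays = list(snv = snv),
        rowData = S4Vectors::DataFrame(wavenumber = wavenumber),
        colData = S4Vectors::DataFrame(colData)
    )
    new("RamanExperiment", se)
}
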