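# Accessor generics and show methods for the core classes.

#' @rdname RamanSpectrum
#' @param object,x A package object.
#' @export
setGeneric("wavenumber", function(x) standardGeneric("wavenumber"))

#' @rdname RamanSpectrum
#' @export
setGeneric("intensity", function(x) standardGeneric("intensity"))

#' @rdname RamanSpectrum
#' @export
setGeneric("stage", function(x) standardGeneric("stage"))

#' @rdname RawAcquisition
#' @param x A [RawAcquisition-class].
#' @export
setGeneric("accumulations", function(x) standardGeneric("accumulations"))

#' @rdname RawAcquisition
#' @export
setGeneric("darkFrames", function(x) standardGeneric("darkFrames"))

#' @rdname RawAcquisition
#' @export
setGeneric("exposureTime", function(x) standardGeneric("exposureTime"))

#' @rdname QualityReport
#' @param x A [QualityReport-class].
#' @export
setGeneric("qualityScore", function(x) standardGeneric("qualityScore"))

#' @rdname ROCResult
#' @param x A [ROCResult-class].
#' @export
setGeneric("auc", function(x) standardGeneric("auc"))

#' @rdname ExclusionLedger
#' @param x An [ExclusionLedger-class].
#' @export
setGeneric("exclusions", function(x) standardGeneric("exclusions"))

#' @rdname RamanSpectrum
#' @export
setMethod("wavenumber", "RamanSpectrum", function(x) x@wavenumber)

#' @rdname RamanSpectrum
#' @export
setMethod("intensity", "RamanSpectrum", function(x) x@intensity)

#' @rdname RamanSpectrum
#' @export
setMethod("stage", "RamanSpectrum", function(x) x@stage)

#' @rdname RawAcquisition
#' @export
setMethod("wavenumber", "RawAcquisition", function(x) x@wavenumber)

#' @rdname RawAcquisition
#' @export
setMethod("accumulations", "RawAcquisition", function(x) x@repeats)

#' @rdname RawAcquisition
#' @export
setMethod("darkFrames", "RawAcquisition", function(x) x@darks)

#' @rdname RawAcquisition
#' @export
setMethod("exposureTime", "RawAcquisition", function(x) x@exposure)

#' @rdname QualityReport
#' @export
setMethod("qualityScore", "QualityReport", function(x) x@qf)

#' @rdname ROCResult
#' @export
setMethod("auc", "ROCResult", function(x) x@auc)

#' @rdname ExclusionLedger
#' @export
setMethod("exclusions", "ExclusionLedger", function(x) x@excluded)

setMethod("show", "RamanSpectrum", function(object) {
    wn <- object@wavenumber
    cat(sprintf(
        "RamanSpectrum: %d points, %.1f-%.1f cm-1, stage '%s'\n",
        length(wn), min(wn), max(wn), object@stage
    ))
})

setMethod("show", "RawAcquisition", function(object) {
    cat(sprintf(
        "RawAcquisition: %d points, %d accumulations, %d dark frame(s), %.2g s exposure\n",
        nrow(object@repeats), ncol(object@repeats), ncol(object@darks),
        object@exposure
    ))
})

setMethod("show", "CalibrationModel", function(object) {
    cat(sprintf(
        "CalibrationModel: degree %d, %d matched peaks, max |residual| %.3f cm-1\n",
        object@degree, nrow(object@matchedPeaks),
        max(abs(object@residuals))
    ))
})

setMethod("show", "QualityReport", function(object) {
    cat(sprintf(
        "QualityReport: qf = %.3f (threshold %.2f) -> %s\n",
        object@qf, object@threshold,
        if (object@passed) "PASS" else "EXCLUDE"
    ))
})

setMethod("show", "ExclusionLedger", function(object) {
    cat(sprintf("ExclusionLedger: %d -> %d measurements\n",
                object@initial, object@final))
    for (r in names(object@excluded))
        cat(sprintf("  excluded %-18s %d\n", r, object@excluded[[r]]))
    cat("  final per class:",
        paste(sprintf("%s=%d", names(object@classCounts),
                      object@classCounts), collapse = ", "), "\n")
})

setMethod("show", "TrainedSVM", function(object) {
    cat(sprintf(
        "TrainedSVM: %d features, C = %.3g, class cost gamma = %.3g, positive class '%s'\n",
        length(object@weights), object@cost, object@classCost,
        object@positiveClass
    ))
})

setMethod("show", "ROCResult", function(object) {
    op <- object@operatingPoint
    cat(sprintf(
        "ROCResult: AUC = %.3f; operating point lambda = %.3f (sens %.3f, spec %.3f, acc %.3f)\n",
        object@auc, op$lambda, op$sensitivity, op$specificity, op$accuracy
    ))
})
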