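# Spectral preprocessing chain: accumulation averaging, dark subtraction,
# instrument-response correction, wavenumber calibration, baseline removal,
# SNV normalization.

.advanceStage <- function(s, newStage, note = NULL) {
    md <- s@metadata
    md$steps <- c(md$steps, newStage)
    if (!is.null(note)) md[[paste0("note_", newStage)]] <- note
    RamanSpectrum(s@wavenumber, s@intensity, stage = newStage, metadata = md)
}

#' Average the repeat spectra of an acquisition
#'
#' Pointwise arithmetic mean over the N accumulations, raising the
#' signal-to-noise ratio by sqrt(N).
#'
#' @param acq A [RawAcquisition-class].
#' @param n Optional number of leading accumulations to use (for
#'   reduced-accumulation studies); default all.
#' @return A [RamanSpectrum-class] at stage `"averaged"`.
#' @examples
#' a <- RawAcquisition(1:3, cbind(c(1, 1, 1), c(3, 3, 3)),
#'                     matrix(0, 3, 1))
#' intensity(averageAccumulations(a))  # 2 2 2
#' @export
averageAccumulations <- function(acq, n = NULL) {
    stopifnot(is(acq, "RawAcquisition"))
    reps <- acq@repeats
    if (!is.null(n)) {
        if (n < 1 || n > ncol(reps))
            stop("requested ", n, " accumulations but only ", ncol(reps),
                 " are available")
        reps <- reps[, seq_len(n), drop = FALSE]
    }
    if (ncol(reps) == 0L) stop("acquisition has no repeat spectra")
    RamanSpectrum(acq@wavenumber, rowMeans(reps), stage = "averaged",
                  metadata = c(acq@metadata,
                               list(steps = "averaged",
                                    n_accumulations = ncol(reps),
                                    exposure = acq@exposure)))
}

#' Subtract averaged dark frames
#'
#' Averages the laser-off dark frames and subtracts them from the averaged
#' signal spectrum.
#'
#' @param s A [RamanSpectrum-class] at stage `"averaged"`.
#' @param darks P x K matrix of dark frames (columns), or a numeric vector.
#' @return A [RamanSpectrum-class] at stage `"dark_subtracted"`.
#' @export
subtractDark <- function(s, darks) {
    stopifnot(is(s, "RamanSpectrum"))
    if (s@stage != "averaged")
        stop("subtractDark expects an 'averaged' spectrum, got '",
             s@stage, "'")
    darks <- as.matrix(darks)
    if (ncol(darks) == 0L) stop("no dark frames supplied")
    if (nrow(darks) != length(s@intensity))
        stop("dark frames have ", nrow(darks),
             " points but the spectrum has ", length(s@intensity))
    out <- s
    out@intensity <- s@intensity - rowMeans(darks)
    .advanceStage(out, "dark_subtracted")
}

#' Correct the wavelength-dependent instrument response
#'
#' Divides the spectrum by the instrument response estimated as the ratio of
#' a measured intensity standard to its certified relative-intensity curve.
#'
#' @param s A [RamanSpectrum-class] at stage `"dark_subtracted"` (earlier
#'   stages are accepted for unit testing).
#' @param standardMeasured Measured standard: [RamanSpectrum-class] or
#'   numeric on the same axis as `s`.
#' @param standardCertified Certified relative-intensity curve (numeric,
#'   same axis), strictly positive.
#' @param responseFloor Smallest admissible response ratio; smaller values
#'   indicate a corrupt standard and are rejected.
#' @return A [RamanSpectrum-class] at stage `"response_corrected"`.
#' @export
correctInstrumentResponse <- function(s, standardMeasured, standardCertified,
                                      responseFloor = 1e-6) {
    stopifnot(is(s, "RamanSpectrum"))
    meas <- if (is(standardMeasured, "RamanSpectrum"))
        standardMeasured@intensity else as.numeric(standardMeasured)
    cert <- as.numeric(standardCertified)
    if (length(meas) != length(s@intensity) ||
        length(cert) != length(s@intensity))
        stop("standard curves must share the spectrum's axis")
    if (any(cert <= 0))
        stop("certified relative-intensity curve must be positive everywhere")
    response <- meas / cert
    if (any(response < responseFloor))
        stop("instrument response ratio fell below the floor (",
             responseFloor, "); standard measurement looks corrupt")
    out <- s
    out@intensity <- s@intensity / response
    .advanceStage(out, "response_corrected")
}

# Local maxima with a prominence above `floor`, refined to sub-sample
# precision by a parabola through the three points around each maximum.
.detectPeaks <- function(x, y, floor) {
    n <- length(y)
    idx <- which(diff(sign(diff(y))) == -2) + 1L
    keep <- logical(length(idx))
    prom <- numeric(length(idx))
    for (k in seq_along(idx)) {
        i <- idx[k]
        # prominence: walk out left/right until a higher point, track minima
        j <- i; lmin <- y[i]
        while (j > 1 && y[j] <= y[i]) { j <- j - 1L; lmin <- min(lmin, y[j]) }
        leftBase <- if (y[j] > y[i]) lmin else min(y[seq_len(i)])
        j <- i; rmin <- y[i]
        while (j < n && y[j] <= y[i]) { j <- j + 1L; rmin <- min(rmin, y[j]) }
        rightBase <- if (y[j] > y[i]) rmin else min(y[i:n])
        prom[k] <- y[i] - max(leftBase, rightBase)
        keep[k] <- prom[k] >= floor
    }
    idx <- idx[keep]
    pos <- vapply(idx, function(i) {
        if (i <= 1L || i >= n) return(x[i])
        y1 <- y[i - 1]; y2 <- y[i]; y3 <- y[i + 1]
        den <- y1 - 2 * y2 + y3
        if (den == 0) return(x[i])
        d <- 0.5 * (y1 - y3) / den
        x[i] + d * (x[i + 1] - x[i])
    }, numeric(1))
    data.frame(position = pos, height = y[idx], prominence = prom[keep])
}

#' Fit a wavenumber calibration from a polycarbonate spectrum
#'
#' Detects peaks in the measured polycarbonate spectrum, matches them to the
#' reference peak table, and fits a least-squares polynomial (default degree
#' 1) mapping observed positions to reference positions.
#'
#' @param polycarbonate A [RamanSpectrum-class] of polycarbonate.
#' @param referencePeaks Reference positions (cm^-1), default
#'   [polycarbonatePeaks()].
#' @param degree Polynomial degree, 1 (default) or 2.
#' @param prominenceFloor Minimum peak prominence as a fraction of the
#'   spectrum's intensity range.
#' @param maxMatchDistance Largest observed-to-reference distance (cm^-1)
#'   still accepted as a match.
#' @return A [CalibrationModel-class].
#' @examples
#' pc <- generatePolycarbonate(defaultAxis(), trueShift = 2)
#' fitCalibration(pc)
#' @export
fitCalibration <- function(polycarbonate,
                           referencePeaks = polycarbonatePeaks(),
                           degree = 1, prominenceFloor = 0.05,
                           maxMatchDistance = 10) {
    stopifnot(is(polycarbonate, "RamanSpectrum"), degree %in% c(1, 2))
    x <- polycarbonate@wavenumber
    y <- polycarbonate@intensity
    pk <- .detectPeaks(x, y, floor = prominenceFloor * diff(range(y)))
    if (nrow(pk) == 0) stop("no peaks detected in the calibration spectrum")
    # nearest-reference matching
    obs <- ref <- numeric(0)
    for (r in referencePeaks) {
        d <- abs(pk$position - r)
        i <- which.min(d)
        if (d[i] <= maxMatchDistance) {
            obs <- c(obs, pk$position[i])
            ref <- c(ref, r)
        }
    }
    if (length(obs) < 3)
        stop("only ", length(obs),
             " reference peaks matched; at least 3 are required")
    fit <- lm(ref ~ poly(obs, degree, raw = TRUE))
    cf <- unname(coef(fit))
    span <- range(x)
    grid <- seq(span[1], span[2], length.out = 200)
    mapped <- .evalPoly(cf, grid)
    if (any(diff(mapped) <= 0))
        stop("fitted calibration mapping is not strictly increasing")
    new("CalibrationModel", coefficients = cf, degree = degree,
        residuals = unname(stats::residuals(fit)),
        matchedPeaks = data.frame(observed = obs, reference = ref))
}

.evalPoly <- function(cf, x) {
    out <- numeric(length(x))
    for (k in seq_along(cf)) out <- out + cf[k] * x^(k - 1)
    out
}

#' Apply a wavenumber calibration and resample to a regular grid
#'
#' Maps the observed axis through the calibration polynomial. By default
#' the intensities are kept on the mapped axis (all spectra of a cohort
#' share one calibration, so the mapped axis is already common and the
#' per-sample noise stays independent); passing `spacing` additionally
#' resamples by linear interpolation onto a regular grid.
#'
#' @param s A [RamanSpectrum-class].
#' @param model A [CalibrationModel-class].
#' @param spacing Optional resampling grid spacing in cm^-1; `NULL`
#'   (default) keeps the mapped axis without interpolation.
#' @param grid Optional explicit target axis (overrides `spacing`).
#' @return A [RamanSpectrum-class] at stage `"calibrated"`.
#' @export
applyCalibration <- function(s, model, spacing = NULL, grid = NULL) {
    stopifnot(is(s, "RamanSpectrum"), is(model, "CalibrationModel"))
    newAxis <- .evalPoly(model@coefficients, s@wavenumber)
    if (any(diff(newAxis) <= 0))
        stop("calibration mapping is not strictly increasing on this axis")
    if (is.null(grid) && !is.null(spacing))
        grid <- seq(ceiling(newAxis[1]), floor(newAxis[length(newAxis)]),
                    by = spacing)
    if (is.null(grid)) {
        yi <- s@intensity
    } else {
        yi <- approx(newAxis, s@intensity, xout = grid)$y
        newAxis <- grid
    }
    RamanSpectrum(newAxis, yi, stage = "calibrated",
                  metadata = c(s@metadata, list(steps = c(
                      s@metadata$steps, "calibrated"))))
}

#' Standard normal variate normalization
#'
#' Centers the spectrum to mean 0 and scales it to unit sample standard
#' deviation, removing multiplicative intensity differences between
#' measurements.
#'
#' @param s A [RamanSpectrum-class] (any stage with nonzero variance).
#' @return A [RamanSpectrum-class] at stage `"snv"` with mean exactly 0 and
#'   sample sd exactly 1.
#' @examples
#' intensity(snv(RamanSpectrum(1:3, c(1, 2, 3))))  # -1 0 1
#' @export
snv <- function(s) {
    stopifnot(is(s, "RamanSpectrum"))
    x <- s@intensity
    sdx <- sd(x)
    if (!is.finite(sdx) || sdx == 0)
        stop("SNV undefined: spectrum has zero variance")
    out <- s
    out@intensity <- (x - mean(x)) / sdx
    .advanceStage(out, "snv")
}

#' Run the full preprocessing pipeline on one acquisition
#'
#' Applies, in order: accumulation averaging, dark subtraction,
#' instrument-response correction, wavenumber calibration with resampling,
#' BubbleFill baseline removal, and SNV normalization. Step provenance is
#' recorded in the spectrum metadata.
#'
#' @param acq A [RawAcquisition-class].
#' @param standard List with `measured` and `certified` (see
#'   [generateReferenceStandard()]); curves must be on the acquisition axis.
#' @param calibration A [CalibrationModel-class] fitted on the same
#'   instrument axis.
#' @param config A [pipelineConfig()].
#' @param nAccumulations Optional truncation of the accumulations used.
#' @return A [RamanSpectrum-class] at stage `"snv"` (or the stage reached if
#'   steps are disabled in `config`).
#' @export
runPipeline <- function(acq, standard, calibration,
                        config = pipelineConfig(), nAccumulations = NULL) {
    step <- function(name, expr) {
        tryCatch(expr, error = function(e)
            stop("pipeline step '", name, "' failed: ", conditionMessage(e),
                 call. = FALSE))
    }
    s <- step("average", averageAccumulations(acq, n = nAccumulations))
    s <- step("dark", subtractDark(s, acq@darks))
    s <- step("response", correctInstrumentResponse(
        s, standard$measured, standard$certified))
    s <- step("calibrate", applyCalibration(
        s, calibration, spacing = config$resampleSpacing))
    if (isTRUE(config$baselineRemoval)) {
        bf <- step("baseline", bubbleFill(
            s, minBubbleWidth = config$minBubbleWidth,
            preSmooth = isTRUE(config$baselinePreSmooth)))
        s <- RamanSpectrum(s@wavenumber, bf$raman, stage = "baseline_removed",
                           metadata = c(s@metadata, list(steps = c(
                               s@metadata$steps, "baseline_removed"))))
    }
    step("snv", snv(s))
}

#' Preprocessing configuration
#'
#' @param resampleSpacing Post-calibration grid spacing in cm^-1, or
#'   `NULL` (default) to keep the calibrated native axis.
#' @param minBubbleWidth Smallest BubbleFill bubble width in cm^-1.
#' @param calibrationDegree Calibration polynomial degree.
#' @param baselineRemoval Whether to run the baseline-removal step.
#' @param baselinePreSmooth Grow bubbles against a lightly smoothed copy
#'   of each spectrum (default `TRUE`): robust for noisy acquisitions,
#'   where the envelope would otherwise hug the lower envelope of the
#'   noise and leave smooth artifacts that inflate the quality factor.
#' @param qcThreshold Quality-factor exclusion gate.
#' @return A list of class `"PipelineConfig"`.
#' @export
pipelineConfig <- function(resampleSpacing = NULL, minBubbleWidth = 50,
                           calibrationDegree = 1, baselineRemoval = TRUE,
                           baselinePreSmooth = TRUE, qcThreshold = 0.6) {
    structure(list(
        resampleSpacing = resampleSpacing,
        minBubbleWidth = minBubbleWidth,
        calibrationDegree = calibrationDegree,
        baselineRemoval = baselineRemoval,
        baselinePreSmooth = baselinePreSmooth,
        qcThreshold = qcThreshold
    ), class = "PipelineConfig")
}
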