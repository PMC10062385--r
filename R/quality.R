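# Spectral quality factor and exclusion gate.
#
# The quality factor scores, between 0 and 1, how much of an SNV-normalized
# spectrum's variance is explained by smooth structure (tissue Raman bands)
# rather than stochastic noise: qf = 1 - ||x - smooth(x)||^2 / ||x - mean||^2
# with a fixed Savitzky-Golay smoother (window 9 samples, polynomial order
# 3). Smooth band-dominated spectra score near 1; white noise scores near
# the fraction of noise variance the smoother reproduces (~0.44), safely
# below the 0.6 gate. The published metric's exact functional form is not
# reproduced in the source literature available here; this smoothing-residual
# form is a reconstruction chosen to be bounded, noise-sensitive, and
# monotone in signal-to-noise ratio.

#' Compute the spectral quality factor
#'
#' @param s A [RamanSpectrum-class] at stage `"snv"`; a
#'   `"baseline_removed"` spectrum is SNV-normalized internally.
#' @param threshold Exclusion gate (default 0.6).
#' @param window Savitzky-Golay window length in samples (odd, default 9).
#' @param order Savitzky-Golay polynomial order (default 3).
#' @return A [QualityReport-class].
#' @examples
#' ax <- seq(600, 1800)
#' s <- snv(RamanSpectrum(ax, exp(-(ax - 1004)^2 / 50) +
#'                            exp(-(ax - 1450)^2 / 80)))
#' qualityFactor(s)
#' @export
qualityFactor <- function(s, threshold = 0.6, window = 9, order = 3) {
    stopifnot(is(s, "RamanSpectrum"))
    if (s@stage == "baseline_removed") s <- snv(s)
    if (s@stage != "snv")
        stop("qualityFactor expects an 'snv' (or 'baseline_removed') ",
             "spectrum, got '", s@stage, "'")
    x <- s@intensity
    if (length(x) < window)
        stop("spectrum (", length(x),
             " points) is shorter than the smoothing window (", window, ")")
    sm <- signal::sgolayfilt(x, p = order, n = window)
    residual <- sum((x - sm)^2)
    total <- sum((x - mean(x))^2)
    qf <- max(0, min(1, 1 - residual / total))
    new("QualityReport", qf = qf, threshold = threshold,
        passed = qf >= threshold,
        diagnostics = list(residual_energy = residual, total_energy = total))
}

#' Partition spectra at the quality gate
#'
#' Spectra with a quality factor strictly below the threshold are excluded;
#' a quality factor exactly at the threshold is kept.
#'
#' @param spectra List of [RamanSpectrum-class] objects.
#' @param threshold Gate value (default 0.6).
#' @param ... Passed to [qualityFactor()].
#' @return List with `kept` and `excluded` (sub-lists of `spectra`) and
#'   `report`, a data frame with one row per spectrum (`id`, `qf`,
#'   `passed`, `reason`).
#' @export
qcFilter <- function(spectra, threshold = 0.6, ...) {
    stopifnot(is.list(spectra))
    reports <- lapply(spectra, qualityFactor, threshold = threshold, ...)
    qf <- vapply(reports, function(r) r@qf, numeric(1))
    passed <- vapply(reports, function(r) r@passed, logical(1))
    ids <- names(spectra)
    if (is.null(ids)) ids <- as.character(seq_along(spectra))
    report <- data.frame(
        id = ids, qf = qf, passed = passed,
        reason = ifelse(passed, "none", "low_quality"),
        stringsAsFactors = FALSE
    )
    list(kept = spectra[passed], excluded = spectra[!passed],
         report = report)
}
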