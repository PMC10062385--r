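# Synthetic acquisition / cohort generator.
#
# Emulates the measurement campaign the analysis assumes: ~20 patients,
# ~390 probed points, N = 10 accumulations plus dark frames per point,
# smooth autofluorescence baselines much larger than the Raman bands,
# patient-level band-amplitude random effects, and planted quality failures
# and label mismatches for exercising the exclusion machinery.

#' Cohort generation settings
#'
#' Bundles every knob of the synthetic cohort generator. The defaults are
#' the study conditions the rest of the package is exercised under: 20
#' patients, 388 measurements, 10 accumulations of 1 s each, and planted
#' failures sized to the canonical exclusion arithmetic (58 low-quality,
#' 58 uncategorizable compositions, 34 label mismatches, leaving 238
#' retained measurements split 87 cancer / 58 normal / 93 fat).
#'
#' @param nPatients Number of patients.
#' @param nMeasurements Total probed points across the cohort.
#' @param classMixture Named proportions over `cancer`, `normal`, `fat`;
#'   must sum to 1.
#' @param accumulations Repeat spectra per point (N, default 10).
#' @param exposure Exposure per accumulation in seconds, within [0.1, 4].
#'   A length-2 vector draws per-measurement exposures uniformly in range.
#' @param noiseSd Additive detector noise sd, counts per pixel per repeat.
#' @param baselineScale Autofluorescence baseline amplitude, counts/s
#'   (much larger than the band amplitudes, as in tissue).
#' @param amplitudeScale Counts/s corresponding to unit band amplitude.
#' @param darkOffset Dark signal, counts/s.
#' @param patientEffectSd SD of the per-patient log-normal band-amplitude
#'   effect (relative).
#' @param measurementJitterSd SD of the per-measurement log-normal
#'   band-amplitude jitter (relative).
#' @param plantedQcFailures Measurements generated noise-swamped so they
#'   fail the quality gate.
#' @param plantedNoCategory Measurements whose composition meets no
#'   labeling threshold.
#' @param plantedLabelMismatches Measurements whose spectral signature
#'   contradicts the composition-derived label (28:6 fat-signature to
#'   fat-composition split at the default count of 34).
#' @param axis Wavenumber axis, default [defaultAxis()].
#' @param lineshape `"gaussian"` (default) or `"lorentzian"` band shapes.
#' @param lipidRealism Extra non-registry lipid bands for the fat class.
#' @param seed Integer seed; a fixed seed reproduces the cohort exactly.
#' @return A list of class `"CohortSpec"`.
#' @examples
#' spec <- cohortSpec(nPatients = 5, nMeasurements = 40,
#'                    plantedQcFailures = 0, plantedNoCategory = 0,
#'                    plantedLabelMismatches = 0)
#' @export
cohortSpec <- function(nPatients = 20,
                       nMeasurements = 388,
                       classMixture = c(cancer = 87, normal = 58,
                                        fat = 93) / 238,
                       accumulations = 10,
                       exposure = 1,
                       noiseSd = 30,
                       baselineScale = 5000,
                       amplitudeScale = 500,
                       darkOffset = 100,
                       patientEffectSd = 0.15,
                       measurementJitterSd = 0.10,
                       plantedQcFailures = 58,
                       plantedNoCategory = 58,
                       plantedLabelMismatches = 34,
                       axis = defaultAxis(),
                       lineshape = "gaussian",
                       lipidRealism = FALSE,
                       seed = 1) {
    spec <- list(
        nPatients = nPatients, nMeasurements = nMeasurements,
        classMixture = classMixture, accumulations = accumulations,
        exposure = exposure, noiseSd = noiseSd,
        baselineScale = baselineScale, amplitudeScale = amplitudeScale,
        darkOffset = darkOffset, patientEffectSd = patientEffectSd,
        measurementJitterSd = measurementJitterSd,
        plantedQcFailures = plantedQcFailures,
        plantedNoCategory = plantedNoCategory,
        plantedLabelMismatches = plantedLabelMismatches,
        axis = axis, lineshape = lineshape, lipidRealism = lipidRealism,
        seed = seed
    )
    class(spec) <- "CohortSpec"
    validateCohortSpec(spec)
    spec
}

#' Validate a CohortSpec
#'
#' @param spec A `"CohortSpec"` list.
#' @return Invisibly `TRUE`; stops with a message otherwise.
#' @export
validateCohortSpec <- function(spec) {
    stopifnot(inherits(spec, "CohortSpec"))
    if (abs(sum(spec$classMixture) - 1) > 1e-6)
        stop("classMixture proportions must sum to 1")
    if (!all(c("cancer", "normal", "fat") %in% names(spec$classMixture)))
        stop("classMixture must name cancer, normal and fat")
    if (spec$accumulations < 1)
        stop("accumulations (N) must be >= 1")
    if (any(spec$exposure < 0.1) || any(spec$exposure > 4))
        stop("exposure must lie within [0.1, 4] seconds")
    if (spec$nPatients < 1 || spec$nMeasurements < 1)
        stop("nPatients and nMeasurements must be positive")
    planted <- spec$plantedQcFailures + spec$plantedNoCategory +
        spec$plantedLabelMismatches
    if (planted > spec$nMeasurements)
        stop("planted failures (", planted,
             ") exceed the number of measurements (", spec$nMeasurements, ")")
    if (any(diff(spec$axis) <= 0))
        stop("wavenumber axis must be strictly increasing")
    invisible(TRUE)
}

# Smooth autofluorescence baseline: broad exponential decay plus a low-order
# polynomial bump, with mildly randomized coefficients. Returned in counts/s
# at unit baselineScale.
.randomBaselineShape <- function(axis) {
    u <- (axis - axis[1]) / (axis[length(axis)] - axis[1])
    tau <- runif(1, 0.35, 0.7)
    a1 <- runif(1, 0.7, 1.3)
    a2 <- runif(1, 0.1, 0.4)
    a3 <- runif(1, -0.15, 0.15)
    a1 * exp(-u / tau) + a2 * (1 - u)^2 + a3 * u * (1 - u) * 4 + 0.05
}

#' Generate one probe acquisition
#'
#' Simulates the repeat spectra and dark frames measured at a single tissue
#' point: Gaussian/Lorentzian band sum for the class (scaled by per-band
#' amplitude effects), plus a smooth autofluorescence baseline, times the
#' exposure, plus dark offset and independent per-repeat Gaussian noise.
#'
#' @param profiles Band profiles from [makeClassProfiles()].
#' @param class Tissue class: `"cancer"`, `"normal"` or `"fat"`.
#' @param patientEffect Per-band amplitude multipliers (length
#'   `nrow(profiles)`) or a scalar; default 1.
#' @param spec A [cohortSpec()].
#' @param seed Integer seed (deterministic output under a fixed seed).
#' @param exposure Optional exposure override in seconds.
#' @param signalScale Extra multiplier on the band amplitudes (used to plant
#'   quality failures); default 1.
#' @param noiseScale Extra multiplier on `noiseSd`; default 1.
#' @param response Optional hidden instrument-response curve on the axis
#'   (e.g. from [generateReferenceStandard()]); the photon signal (bands +
#'   baseline, not the dark offset) is multiplied by it, so the
#'   response-correction step can cancel it exactly. Default: flat.
#' @param metadata List of identifiers copied into the acquisition.
#' @return A [RawAcquisition-class] with `spec$accumulations` repeat columns
#'   and 2 dark frames.
#' @examples
#' spec <- cohortSpec(nMeasurements = 1, plantedQcFailures = 0,
#'                    plantedNoCategory = 0, plantedLabelMismatches = 0)
#' acq <- generateAcquisition(makeClassProfiles(), "cancer", 1, spec, seed = 7)
#' @export
generateAcquisition <- function(profiles, class, patientEffect = 1, spec,
                                seed = 1, exposure = NULL,
                                signalScale = 1, noiseScale = 1,
                                response = NULL, metadata = list()) {
    if (!class %in% c("cancer", "normal", "fat"))
        stop("invalid tissue class '", class,
             "'; expected cancer, normal or fat")
    validateCohortSpec(spec)
    if (length(patientEffect) == 1L)
        patientEffect <- rep(patientEffect, nrow(profiles))
    if (is.null(exposure))
        exposure <- if (length(spec$exposure) == 2L)
            mean(spec$exposure) else spec$exposure[1]
    axis <- spec$axis
    p <- length(axis)
    if (is.null(response)) response <- rep(1, p)
    stopifnot(length(response) == p, all(response > 0))
    withr::with_seed(seed, {
        jitter <- exp(rnorm(nrow(profiles), 0, spec$measurementJitterSd))
        signal <- spec$amplitudeScale * signalScale *
            classSignal(profiles, class, axis,
                        amplitudes = patientEffect * jitter,
                        lineshape = spec$lineshape)
        baseline <- spec$baselineScale * .randomBaselineShape(axis)
        clean <- ((signal + baseline) * response + spec$darkOffset) *
            exposure
        nsd <- spec$noiseSd * noiseScale
        n <- spec$accumulations
        repeats <- matrix(clean, nrow = p, ncol = n) +
            matrix(rnorm(p * n, 0, nsd), nrow = p)
        darks <- matrix(spec$darkOffset * exposure, nrow = p, ncol = 2) +
            matrix(rnorm(p * 2, 0, nsd), nrow = p)
    })
    RawAcquisition(axis, repeats, darks, exposure = exposure,
                   metadata = c(metadata, list(class = class)))
}

# Draw a composition vector (pct cancer, normal, fat) whose only satisfied
# labeling threshold is the intended class's.
.compositionFor <- function(class) {
    thr <- c(cancer = 80, normal = 80, fat = 70)
    if (class == "none") {
        repeat {
            pc <- runif(1, 5, 75)
            pn <- runif(1, 0, min(75, 100 - pc))
            pf <- 100 - pc - pn
            if (pf < 65 && pf >= 0) break
        }
        return(c(cancer = pc, normal = pn, fat = pf))
    }
    main <- runif(1, thr[[class]], 100)
    others <- setdiff(c("cancer", "normal", "fat"), class)
    u <- runif(1)
    rest <- 100 - main
    out <- c(main, rest * u, rest * (1 - u))
    names(out) <- c(class, others)
    out[c("cancer", "normal", "fat")]
}

#' Generate a synthetic measurement cohort
#'
#' Produces the full set of probe acquisitions plus the measurement manifest
#' (patient/sample identity, grid position, composition percentages). Planted
#' quality failures are generated noise-swamped; planted label mismatches
#' carry a spectral signature contradicting their composition-derived label
#' (by default 28 fat-signature spectra with cancer/normal compositions and 6
#' protein-signature spectra with fat compositions); planted no-category
#' records meet none of the 80/80/70 thresholds. All remaining records meet
#' exactly the threshold of the class their spectrum was generated from.
#'
#' The manifest's `true_class` and `planted` columns are generator ground
#' truth for validation; the analysis pipeline never reads them.
#'
#' @param spec A [cohortSpec()].
#' @param profiles Band profiles (default
#'   `makeClassProfiles(spec$lipidRealism)`); pass modified profiles to
#'   generate cohorts with altered class contrasts.
#' @param response Optional hidden instrument-response curve applied to
#'   every acquisition (see [generateAcquisition()]).
#' @return List with elements `acquisitions` (list of
#'   [RawAcquisition-class]) and `manifest` (data frame).
#' @examples
#' spec <- cohortSpec(nPatients = 4, nMeasurements = 20,
#'                    plantedQcFailures = 2, plantedNoCategory = 2,
#'                    plantedLabelMismatches = 2, seed = 11)
#' cohort <- generateCohort(spec)
#' table(cohort$manifest$planted)
#' @export
generateCohort <- function(spec, profiles = NULL, response = NULL) {
    validateCohortSpec(spec)
    if (is.null(profiles)) profiles <- makeClassProfiles(spec$lipidRealism)
    nb <- nrow(profiles)
    nM <- spec$nMeasurements
    nP <- spec$nPatients
    classes <- c("cancer", "normal", "fat")

    withr::with_seed(spec$seed, {
        patientIds <- sprintf("P%02d", seq_len(nP))
        patientEffects <- lapply(seq_len(nP), function(i)
            exp(rnorm(nb, 0, spec$patientEffectSd)))
        names(patientEffects) <- patientIds
        patientOf <- sort(rep_len(seq_len(nP), nM))

        # roles
        role <- rep("none", nM)
        planted <- sample.int(nM, spec$plantedQcFailures +
                                  spec$plantedNoCategory +
                                  spec$plantedLabelMismatches)
        i0 <- 0
        take <- function(k) planted[seq_len(k) + i0]
        role[take(spec$plantedQcFailures)] <- "low_quality"
        i0 <- i0 + spec$plantedQcFailures
        role[take(spec$plantedNoCategory)] <- "no_category"
        i0 <- i0 + spec$plantedNoCategory
        role[take(spec$plantedLabelMismatches)] <- "mismatch"

        # spectral (signature) classes: clean records follow the mixture
        # exactly, planted records are drawn from it
        clean <- which(role == "none")
        nClean <- length(clean)
        cnt <- floor(spec$classMixture * nClean)
        rem <- nClean - sum(cnt)
        if (rem > 0) {
            frac <- spec$classMixture * nClean - cnt
            add <- order(frac, decreasing = TRUE)[seq_len(rem)]
            cnt[add] <- cnt[add] + 1
        }
        trueClass <- character(nM)
        trueClass[clean] <- sample(rep(classes, times = cnt[classes]))
        other <- which(role != "none")
        if (length(other))
            trueClass[other] <- sample(classes, length(other), replace = TRUE,
                                       prob = spec$classMixture[classes])

        # mismatches: fat signature under protein composition and vice versa
        # (28:6 split at the default count, proportionally otherwise)
        mism <- which(role == "mismatch")
        compClass <- trueClass
        if (length(mism)) {
            nFatSig <- round(length(mism) * 28 / 34)
            fatSig <- mism[seq_len(nFatSig)]
            protSig <- setdiff(mism, fatSig)
            trueClass[fatSig] <- "fat"
            compClass[fatSig] <- sample(c("cancer", "normal"), length(fatSig),
                                        replace = TRUE)
            trueClass[protSig] <- sample(c("cancer", "normal"),
                                         length(protSig), replace = TRUE)
            compClass[protSig] <- "fat"
        }
        compClass[role == "no_category"] <- "none"

        comp <- t(vapply(compClass, .compositionFor, numeric(3)))

        exposures <- if (length(spec$exposure) == 2L)
            runif(nM, spec$exposure[1], spec$exposure[2])
        else rep(spec$exposure[1], nM)

        seeds <- sample.int(.Machine$integer.max - 1, nM)
        posx <- runif(nM, 0, 20)
        posy <- runif(nM, 0, 20)

        manifest <- data.frame(
            measurement_id = sprintf("M%03d", seq_len(nM)),
            patient_id = patientIds[patientOf],
            sample_id = sprintf("%s-S%d", patientIds[patientOf],
                                1 + seq_len(nM) %% 2),
            pos_x = posx, pos_y = posy, circle_diameter = 3,
            exposure = exposures,
            pct_cancer = comp[, "cancer"], pct_normal = comp[, "normal"],
            pct_fat = comp[, "fat"],
            true_class = trueClass, planted = role,
            stringsAsFactors = FALSE
        )

        acquisitions <- lapply(seq_len(nM), function(i) {
            lowq <- role[i] == "low_quality"
            generateAcquisition(
                profiles, trueClass[i],
                patientEffect = patientEffects[[patientOf[i]]],
                spec = spec, seed = seeds[i], exposure = exposures[i],
                signalScale = if (lowq) 0.02 else 1,
                noiseScale = if (lowq) 25 else 1,
                response = response,
                metadata = list(
                    measurement_id = manifest$measurement_id[i],
                    patient_id = manifest$patient_id[i],
                    sample_id = manifest$sample_id[i]
                )
            )
        })
        names(acquisitions) <- manifest$measurement_id
    })
    list(acquisitions = acquisitions, manifest = manifest)
}

#' Generate a luminescence reference-standard pair
#'
#' Emulates the certified relative-intensity curve of a NIST-style Raman
#' intensity standard and its measurement through a hidden instrument
#' response: `measured = certified * response * (1 + noise)`. The hidden
#' response is returned so oracle tests can verify the correction.
#'
#' @param axis Wavenumber axis (cm^-1).
#' @param seed Integer seed.
#' @param noiseSd Relative measurement noise sd (default 0.002).
#' @param flatResponse If `TRUE` the hidden response is identically 1.
#' @return List with `measured` ([RamanSpectrum-class]), `certified`
#'   (numeric curve on `axis`) and `response` (the hidden curve).
#' @examples
#' std <- generateReferenceStandard(defaultAxis(), seed = 3)
#' @export
generateReferenceStandard <- function(axis, seed = 1, noiseSd = 0.002,
                                      flatResponse = FALSE) {
    stopifnot(all(diff(axis) > 0))
    u <- (axis - axis[1]) / (axis[length(axis)] - axis[1])
    certified <- 0.4 + exp(-((u - 0.45) / 0.45)^2)
    response <- if (flatResponse) rep(1, length(axis))
        else 0.55 + 0.45 * exp(-((u - 0.25) / 0.55)^2)
    measured <- withr::with_seed(seed,
        certified * response * (1 + rnorm(length(axis), 0, noiseSd)))
    list(
        measured = RamanSpectrum(axis, measured, stage = "raw",
                                 metadata = list(kind = "reference_standard")),
        certified = certified,
        response = response
    )
}

#' Reference peak positions of polycarbonate
#'
#' The peak table the wavenumber calibration matches against.
#'
#' @return Numeric vector of Raman shifts (cm^-1).
#' @export
polycarbonatePeaks <- function() {
    c(635, 705, 768, 829, 888, 1113, 1177, 1235, 1603)
}

#' Generate a polycarbonate calibration spectrum
#'
#' Produces a spectrum whose peaks sit at the [polycarbonatePeaks()]
#' positions displaced by a planted shift (or a planted affine map), for
#' exercising wavenumber-calibration recovery.
#'
#' @param axis Wavenumber axis the spectrum is sampled on.
#' @param trueShift Planted displacement in cm^-1: observed peak maxima sit
#'   at `reference + trueShift`.
#' @param affine Optional planted correction map `c(intercept, slope)` such
#'   that `reference = intercept + slope * observed`; overrides `trueShift`.
#' @param seed Integer seed.
#' @param noiseSd Additive noise sd relative to the strongest peak.
#' @return A [RamanSpectrum-class].
#' @examples
#' pc <- generatePolycarbonate(defaultAxis(), trueShift = 2, seed = 5)
#' @export
generatePolycarbonate <- function(axis, trueShift = 0, affine = NULL,
                                  seed = 1, noiseSd = 0.003) {
    stopifnot(all(diff(axis) > 0))
    span <- axis[length(axis)] - axis[1]
    if (is.null(affine)) {
        if (abs(trueShift) > 0.05 * span)
            stop("trueShift must be small relative to the axis span")
        affine <- c(-trueShift, 1)
    }
    ref <- polycarbonatePeaks()
    obs <- (ref - affine[1]) / affine[2]
    keep <- obs > axis[1] + 10 & obs < axis[length(axis)] - 10
    obs <- obs[keep]
    amp <- c(0.6, 0.9, 0.5, 0.55, 1.0, 0.7, 0.8, 0.6, 0.95)[keep]
    y <- numeric(length(axis))
    for (i in seq_along(obs)) {
        sdv <- 8 / (2 * sqrt(2 * log(2)))
        y <- y + amp[i] * exp(-((axis - obs[i])^2) / (2 * sdv^2))
    }
    u <- (axis - axis[1]) / span
    y <- y + 0.05 * (1 - u)   # mild sloping background
    y <- withr::with_seed(seed, y + rnorm(length(axis), 0, noiseSd))
    RamanSpectrum(axis, y, stage = "raw",
                  metadata = list(kind = "polycarbonate",
                                  planted_affine = affine))
}
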