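# Shared fixtures: all synthetic, generated in code at test time.

# Small cohort plus its reference material and calibration, sized for fast
# unit tests.
smallCohort <- function(seed = 42, nPatients = 10, nMeasurements = 80,
                        plantedQcFailures = 8, plantedNoCategory = 8,
                        plantedLabelMismatches = 6, ...) {
    spec <- cohortSpec(
        nPatients = nPatients, nMeasurements = nMeasurements,
        plantedQcFailures = plantedQcFailures,
        plantedNoCategory = plantedNoCategory,
        plantedLabelMismatches = plantedLabelMismatches,
        seed = seed, ...
    )
    std <- generateReferenceStandard(spec$axis, seed = seed)
    cohort <- generateCohort(spec, response = std$response)
    cal <- fitCalibration(generatePolycarbonate(spec$axis, seed = seed))
    list(spec = spec, cohort = cohort, standard = std, calibration = cal)
}

# Feature-level planted-signal fixture: iid standard-normal band features
# with a mean shift of `delta` SD at the planted bands for one class.
plantedFeatureFixture <- function(planted, seed, delta = 2, n = 75) {
    centers <- tableBands()$center
    withr::with_seed(seed, {
        X <- matrix(rnorm(2 * n * length(centers)), 2 * n, length(centers))
        y <- rep(c("g1", "g2"), each = n)
        for (b in which(centers %in% planted))
            X[y == "g2", b] <- X[y == "g2", b] + delta
        colnames(X) <- centers
        list(X = X, y = y)
    })
}

# Spectrum-level two-class fixture whose class difference is confined to
# the planted bands (amplitude ratio r), with per-band jitter and pixel
# noise; returns band features.
plantedSpectrumFixture <- function(planted, seed, r = 0.7, jitterSd = 0.12,
                                   noiseSd = 0.03, n = 50) {
    prof <- makeClassProfiles()
    ax <- defaultAxis()
    centers <- prof$center
    withr::with_seed(seed, {
        X <- matrix(NA_real_, 2 * n, length(centers))
        y <- rep(c("g1", "g2"), each = n)
        for (i in seq_len(2 * n)) {
            amp <- rep(1, length(centers))
            if (y[i] == "g2") amp[centers %in% planted] <- r
            p2 <- prof
            p2$cancer <- amp * exp(rnorm(length(centers), 0, jitterSd))
            sig <- classSignal(p2, "cancer", ax)
            sp <- snv(RamanSpectrum(ax, sig + rnorm(length(ax), 0, noiseSd)))
            X[i, ] <- vapply(centers, function(b) bandIntensity(sp, b),
                             numeric(1))
        }
        colnames(X) <- centers
        list(X = X, y = y)
    })
}

# Independent AUC oracle: brute-force pairwise concordance, ties counted
# one half.
aucConcordance <- function(p, pos) {
    pp <- p[pos]
    pn <- p[!pos]
    tot <- 0
    for (a in pp) tot <- tot + sum(a > pn) + 0.5 * sum(a == pn)
    tot / (length(pp) * length(pn))
}

# A clean noiseless tissue-like SNV spectrum.
cleanTissueSpectrum <- function(class = "cancer", ax = defaultAxis()) {
    snv(RamanSpectrum(ax, classSignal(makeClassProfiles(), class, ax)))
}
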