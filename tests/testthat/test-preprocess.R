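test_that("accumulation averaging is the pointwise arithmetic mean", {
    ax <- c(100, 101)
    acq <- RawAcquisition(ax, cbind(c(1, 3), c(3, 1)), matrix(0, 2, 1))
    avg <- averageAccumulations(acq)
    expect_equal(intensity(avg), c(2, 2))
    expect_identical(stage(avg), "averaged")

    # identical repeats pass through unchanged
    v <- rnorm(5)
    acq10 <- RawAcquisition(1:5, matrix(v, 5, 10), matrix(0, 5, 1))
    expect_equal(intensity(averageAccumulations(acq10)), v)

    # truncation to fewer accumulations
    expect_equal(intensity(averageAccumulations(acq, n = 1)), c(1, 3))
    expect_error(averageAccumulations(acq, n = 7), "only 2")

    # noise reduction ~ sigma / sqrt(N)
    sds <- withr::with_seed(8, vapply(1:100, function(i) {
        reps <- matrix(rnorm(10 * 50, sd = 2), 50, 10)
        sd(intensity(averageAccumulations(
            RawAcquisition(1:50, reps, matrix(0, 50, 1)))))
    }, numeric(1)))
    expect_lt(abs(mean(sds) - 2 / sqrt(10)) / (2 / sqrt(10)), 0.15)
})

test_that("dark subtraction removes the averaged dark frames", {
    s <- averageAccumulations(
        RawAcquisition(1:2, matrix(5, 2, 3), matrix(0, 2, 1)))
    out <- subtractDark(s, cbind(c(1, 1), c(3, 3)))
    expect_equal(intensity(out), c(3, 3))
    expect_identical(stage(out), "dark_subtracted")
    expect_equal(intensity(subtractDark(s, matrix(0, 2, 2))), c(5, 5))
    expect_error(subtractDark(s, matrix(0, 3, 2)), "points")
    expect_error(subtractDark(out, matrix(0, 2, 1)), "averaged")

    # generator's known dark offset is removed to within noise
    spec <- cohortSpec(nPatients = 2, nMeasurements = 2,
                       plantedQcFailures = 0, plantedNoCategory = 0,
                       plantedLabelMismatches = 0,
                       noiseSd = 1, baselineScale = 0, amplitudeScale = 0,
                       darkOffset = 250)
    acq <- generateAcquisition(makeClassProfiles(), "normal", 1, spec,
                               seed = 6)
    ds <- subtractDark(averageAccumulations(acq), darkFrames(acq))
    expect_lt(abs(mean(intensity(ds))), 1)
})

test_that("instrument-response correction divides out the hidden response", {
    ax <- defaultAxis()
    std <- generateReferenceStandard(ax, seed = 3, noiseSd = 0)
    truth <- classSignal(makeClassProfiles(), "cancer", ax) + 1
    observed <- truth * std$response
    s <- RamanSpectrum(ax, observed, stage = "dark_subtracted")
    out <- correctInstrumentResponse(s, std$measured, std$certified)
    expect_identical(stage(out), "response_corrected")
    expect_lt(max(abs(intensity(out) - truth) / truth), 0.02)

    # flat response leaves the spectrum unchanged
    flat <- generateReferenceStandard(ax, seed = 3, noiseSd = 0,
                                      flatResponse = TRUE)
    out2 <- correctInstrumentResponse(s, flat$measured, flat$certified)
    expect_equal(intensity(out2), observed, tolerance = 1e-12)

    expect_error(correctInstrumentResponse(s, std$measured,
                                           -std$certified),
                 "positive")
    expect_error(correctInstrumentResponse(
        s, RamanSpectrum(ax, rep(1e-9, length(ax))),
        std$certified, responseFloor = 1e-6), "floor")
})

test_that("wavenumber calibration recovers planted shifts and affine maps", {
    ax <- defaultAxis()
    # identity: mapping close to identity, residuals small
    cal0 <- fitCalibration(generatePolycarbonate(ax, trueShift = 0,
                                                 seed = 1))
    expect_lt(max(abs(cal0@residuals)), 0.5)
    expect_lt(abs(cal0@coefficients[1]), 0.5)
    expect_lt(abs(cal0@coefficients[2] - 1), 0.002)

    # planted +2 cm^-1 shift: recovered offset -2 +/- 0.2
    cal2 <- fitCalibration(generatePolycarbonate(ax, trueShift = 2,
                                                 seed = 1))
    shiftHat <- mean(cal2@matchedPeaks$observed -
                     cal2@matchedPeaks$reference)
    expect_lt(abs(shiftHat - 2), 0.2)

    # planted affine map recovered within 5% slope / 0.3 offset
    cal3 <- fitCalibration(generatePolycarbonate(
        ax, affine = c(1, 1.001), seed = 1))
    expect_lt(abs(cal3@coefficients[2] - 1.001) / 1.001, 0.05)
    expect_lt(abs(cal3@coefficients[1] - 1), 0.3)

    # applying the fitted model restores reference peak positions
    pc <- generatePolycarbonate(ax, trueShift = 2, seed = 1)
    corr <- applyCalibration(pc, cal2)
    y <- intensity(corr)
    axc <- wavenumber(corr)
    for (r in polycarbonatePeaks()) {
        if (r < min(axc) + 15 || r > max(axc) - 15) next
        sel <- which(abs(axc - r) < 6)
        expect_lt(abs(axc[sel[which.max(y[sel])]] - r),
                  mean(diff(axc)) / 2 + 0.5)
    }

    expect_error(fitCalibration(
        RamanSpectrum(ax, rep(0, length(ax)))), "peak")
})

test_that("SNV centers and scales exactly", {
    expect_equal(intensity(snv(RamanSpectrum(1:3, c(1, 2, 3)))),
                 c(-1, 0, 1))
    s <- snv(RamanSpectrum(1:200, rnorm(200)))
    expect_lt(abs(mean(intensity(s))), 1e-10)
    expect_lt(abs(sd(intensity(s)) - 1), 1e-10)
    expect_identical(stage(s), "snv")
    # affine invariance
    x <- withr::with_seed(5, rnorm(100))
    s1 <- snv(RamanSpectrum(1:100, x))
    s2 <- snv(RamanSpectrum(1:100, 3.7 * x + 42))
    expect_equal(intensity(s1), intensity(s2), tolerance = 1e-12)
    expect_error(snv(RamanSpectrum(1:4, rep(2, 4))), "variance")
})

test_that("the full pipeline reproduces the known band signal", {
    spec <- cohortSpec(nPatients = 2, nMeasurements = 2,
                       plantedQcFailures = 0, plantedNoCategory = 0,
                       plantedLabelMismatches = 0,
                       noiseSd = 0, measurementJitterSd = 0)
    prof <- makeClassProfiles()
    std <- generateReferenceStandard(spec$axis, seed = 13, noiseSd = 0)
    acq <- generateAcquisition(prof, "cancer", 1, spec, seed = 13,
                               response = std$response)
    cal <- fitCalibration(generatePolycarbonate(spec$axis, seed = 13))

    # noise-free input: envelope pre-smoothing is unnecessary, disable it
    cfgExact <- pipelineConfig(baselinePreSmooth = FALSE)
    out <- runPipeline(acq, std, cal, config = cfgExact)
    expect_identical(stage(out), "snv")
    truth <- classSignal(prof, "cancer", wavenumber(out))
    expect_gt(cor(intensity(out), intensity(snv(RamanSpectrum(
        wavenumber(out), truth)))), 0.99)
    # the noise-robust default stays close to the truth as well
    outDefault <- runPipeline(acq, std, cal)
    expect_gt(cor(intensity(outDefault), intensity(snv(RamanSpectrum(
        wavenumber(outDefault), truth)))), 0.97)

    # determinism
    out2 <- runPipeline(acq, std, cal, config = cfgExact)
    expect_identical(intensity(out), intensity(out2))

    # equivariance to positive scaling of the raw input (SNV terminal step)
    acqScaled <- RawAcquisition(wavenumber(acq),
                                accumulations(acq) * 7,
                                darkFrames(acq) * 7,
                                exposure = exposureTime(acq))
    out3 <- runPipeline(acqScaled, std, cal, config = cfgExact)
    expect_equal(intensity(out3), intensity(out), tolerance = 1e-8)

    # step errors carry the step name
    badStd <- list(measured = std$measured, certified = -std$certified)
    expect_error(runPipeline(acq, badStd, cal), "response")
})

test_that("disabling baseline removal leaves the baseline dominant", {
    spec <- cohortSpec(nPatients = 2, nMeasurements = 2,
                       plantedQcFailures = 0, plantedNoCategory = 0,
                       plantedLabelMismatches = 0,
                       noiseSd = 0, amplitudeScale = 0)
    acq <- generateAcquisition(makeClassProfiles(), "normal", 1, spec,
                               seed = 31)
    std <- generateReferenceStandard(spec$axis, seed = 31, noiseSd = 0,
                                     flatResponse = TRUE)
    cal <- fitCalibration(generatePolycarbonate(spec$axis, seed = 31))
    out <- runPipeline(acq, std, cal,
                       config = pipelineConfig(baselineRemoval = FALSE))
    expect_identical(stage(out), "snv")
    # pure-baseline input: without step (5) the output is the (normalized)
    # baseline itself
    baselineOnly <- subtractDark(averageAccumulations(acq),
                                 darkFrames(acq))
    expect_gt(cor(intensity(out), intensity(baselineOnly)), 0.9)
})
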