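test_that("class profiles encode the expected band structure", {
    prof <- makeClassProfiles()
    expect_setequal(prof$center,
                    c(760, 785, 940, 1004, 1129, 1159, 1176, 1208, 1246,
                      1266, 1302, 1600))
    expect_false(any(duplicated(prof$center)))
    expect_true(all(prof[, c("cancer", "normal", "fat")] >= 0))
    expect_true(all(prof$fwhm > 0))
    p1004 <- prof[prof$center == 1004, ]
    # fat carries no phenylalanine; cancer more than normal
    expect_identical(p1004$fat, 0)
    expect_gt(p1004$cancer, p1004$normal)
    # fat dominates the lipid bands, normal the collagen band
    for (b in c(1129, 1302)) {
        row <- prof[prof$center == b, ]
        expect_true(row$fat > row$cancer && row$fat > row$normal)
    }
    p940 <- prof[prof$center == 940, ]
    expect_gt(p940$normal, p940$cancer)
})

test_that("acquisition generation honors the noise model", {
    prof <- makeClassProfiles()
    spec <- cohortSpec(nPatients = 2, nMeasurements = 4,
                       plantedQcFailures = 0, plantedNoCategory = 0,
                       plantedLabelMismatches = 0,
                       noiseSd = 0, baselineScale = 0, darkOffset = 0,
                       amplitudeScale = 1, measurementJitterSd = 0)
    # zero-noise case: every repeat equals the pure band sum
    acq <- generateAcquisition(prof, "cancer", 1, spec, seed = 3)
    truth <- classSignal(prof, "cancer", spec$axis)
    for (j in seq_len(ncol(accumulations(acq))))
        expect_equal(accumulations(acq)[, j], truth, tolerance = 1e-12)

    # determinism under a fixed seed
    a1 <- generateAcquisition(prof, "normal", 1, spec, seed = 11)
    a2 <- generateAcquisition(prof, "normal", 1, spec, seed = 11)
    expect_identical(accumulations(a1), accumulations(a2))
    expect_identical(darkFrames(a1), darkFrames(a2))

    # invalid class rejected
    expect_error(generateAcquisition(prof, "bone", 1, spec, seed = 1),
                 "invalid tissue class")

    # per-pixel noise sd across many repeats matches the specification
    specN <- cohortSpec(nPatients = 2, nMeasurements = 4,
                        plantedQcFailures = 0, plantedNoCategory = 0,
                        plantedLabelMismatches = 0,
                        accumulations = 200, noiseSd = 12,
                        measurementJitterSd = 0)
    acqN <- generateAcquisition(prof, "fat", 1, specN, seed = 5)
    sds <- apply(accumulations(acqN), 1, sd)
    expect_lt(abs(mean(sds) - 12) / 12, 0.1)
})

test_that("cohorts are deterministic and respect the planting counts", {
    spec <- cohortSpec(nPatients = 5, nMeasurements = 40,
                       plantedQcFailures = 4, plantedNoCategory = 5,
                       plantedLabelMismatches = 6, seed = 9)
    c1 <- generateCohort(spec)
    c2 <- generateCohort(spec)
    expect_identical(c1$manifest, c2$manifest)
    expect_identical(accumulations(c1$acquisitions[[17]]),
                     accumulations(c2$acquisitions[[17]]))
    expect_equal(sum(c1$manifest$planted == "low_quality"), 4)
    expect_equal(sum(c1$manifest$planted == "no_category"), 5)
    expect_equal(sum(c1$manifest$planted == "mismatch"), 6)
    # mismatches: spectral class contradicts the composition label
    mm <- c1$manifest[c1$manifest$planted == "mismatch", ]
    lab <- assignLabel(mm$pct_cancer, mm$pct_normal, mm$pct_fat)
    expect_true(all((lab == "fat") != (mm$true_class == "fat")))
})

test_that("non-planted compositions satisfy exactly their class threshold", {
    spec <- cohortSpec(nPatients = 5, nMeasurements = 60,
                       plantedQcFailures = 0, plantedNoCategory = 0,
                       plantedLabelMismatches = 0, seed = 21)
    man <- generateCohort(spec)$manifest
    lab <- assignLabel(man$pct_cancer, man$pct_normal, man$pct_fat)
    expect_identical(lab, man$true_class)
    # at most one threshold can be met since percentages sum to 100
    met <- (man$pct_cancer >= 80) + (man$pct_normal >= 80) +
        (man$pct_fat >= 70)
    expect_true(all(met == 1))
})

test_that("infeasible cohort specifications are rejected", {
    expect_error(cohortSpec(nMeasurements = 10, plantedQcFailures = 20),
                 "exceed")
    expect_error(cohortSpec(exposure = 9), "exposure")
    expect_error(cohortSpec(classMixture = c(cancer = 0.5, normal = 0.2,
                                             fat = 0.2)),
                 "sum to 1")
})

test_that("reference standard exposes a recoverable instrument response", {
    ax <- defaultAxis()
    # identity response, zero noise: measured equals certified
    flat <- generateReferenceStandard(ax, seed = 2, noiseSd = 0,
                                      flatResponse = TRUE)
    expect_equal(intensity(flat$measured), flat$certified, tolerance = 1e-12)
    std <- generateReferenceStandard(ax, seed = 2, noiseSd = 0)
    expect_true(all(std$certified > 0))
    # hidden response recovered as measured / certified
    rec <- intensity(std$measured) / std$certified
    expect_lt(max(abs(rec - std$response) / std$response), 0.01)
})

test_that("polycarbonate peaks appear at the planted positions", {
    ax <- defaultAxis()
    pc0 <- generatePolycarbonate(ax, trueShift = 0, seed = 4)
    expect_identical(intensity(pc0),
                     intensity(generatePolycarbonate(ax, trueShift = 0,
                                                     seed = 4)))
    spacing <- mean(diff(ax))
    refs <- polycarbonatePeaks()
    for (shift in c(0, 2)) {
        pc <- generatePolycarbonate(ax, trueShift = shift, seed = 4)
        y <- intensity(pc)
        for (r in refs) {
            if (r + shift < min(ax) + 15 || r + shift > max(ax) - 15) next
            sel <- which(abs(ax - (r + shift)) < 6)
            peakAt <- ax[sel[which.max(y[sel])]]
            expect_lt(abs(peakAt - (r + shift)), spacing / 2 + 1e-9)
        }
    }
})

test_that("a wider phenylalanine contrast never hurts downstream separation",
{
    # monotone separability: doubling the cancer-normal amplitude gap at
    # 1004 cm^-1 does not decrease the feature-level AUC (averaged over
    # seeds)
    gapAuc <- function(gapScale, seeds) {
        mean(vapply(seeds, function(s) {
            prof <- makeClassProfiles()
            i <- prof$center == 1004
            prof$normal[i] <- prof$cancer[i] -
                gapScale * (prof$cancer[i] - makeClassProfiles()$normal[i])
            ax <- defaultAxis()
            withr::with_seed(s, {
                n <- 30
                feat <- numeric(2 * n)
                y <- rep(c(TRUE, FALSE), each = n)
                for (k in seq_len(2 * n)) {
                    cls <- if (y[k]) "cancer" else "normal"
                    jit <- exp(rnorm(nrow(prof), 0, 0.15))
                    p2 <- prof
                    p2[[cls]] <- p2[[cls]] * jit
                    sp <- snv(RamanSpectrum(ax,
                        classSignal(p2, cls, ax) +
                        rnorm(length(ax), 0, 0.03)))
                    feat[k] <- bandIntensity(sp, 1004)
                }
                aucConcordance(feat, y)
            })
        }, numeric(1)))
    }
    seeds <- 1:10
    expect_gte(gapAuc(2, seeds) + 1e-9, gapAuc(1, seeds))
})
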