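#' Fingerprint-region band registry
#'
#' The Raman bands used throughout the package, with their tentative
#' biomolecular assignments and the binary classification models each band
#' feeds (A: cancer vs normal+fat; B: cancer vs normal; C: cancer vs fat).
#' Ranged centers (937-942, 1301-1304) are stored at a single representative
#' wavenumber; the 1159 cm^-1 protein band is also reported in the literature
#' at 1155/1157 cm^-1 (stored under its `aliases`).
#'
#' @param halfWidth Half-width (cm^-1) of the integration window used when a
#'   band is turned into a feature; default 5, comfortably above the
#'   1.8 cm^-1 spectral resolution.
#' @return A data frame with columns `center`, `halfWidth`, `name`,
#'   `assignment`, `models`, `aliases`.
#' @examples
#' tableBands()
#' @export
tableBands <- function(halfWidth = 5) {
    data.frame(
        center = c(760, 785, 940, 1004, 1129, 1159, 1176, 1208, 1246, 1266,
                   1302, 1600),
        halfWidth = halfWidth,
        name = c("760", "785", "940", "1004", "1129", "1159", "1176",
                 "1208", "1246", "1266", "1302", "1600"),
        assignment = c(
            "tryptophan ring breathing (proteins)",
            "cytosine/uracil ring breathing (DNA/RNA)",
            "C-C stretching (collagen)",
            "phenylalanine symmetric ring breathing (proteins)",
            "acyl backbone (lipids)",
            "C-C/C-N stretching (proteins)",
            "C-H bending tyrosine/cytosine/guanine (DNA/RNA)",
            "DNA/RNA base ring breathing, phenylalanine",
            "amide III (proteins)",
            "amide III (proteins)",
            "CH2/CH3 twisting (lipids)",
            "C=C phenylalanine (proteins)"
        ),
        models = c("", "", "A,B", "A,B,C", "B", "B", "", "", "", "", "C", ""),
        aliases = c("", "", "937-942", "", "", "1155,1157", "", "", "", "",
                    "1301-1304", ""),
        stringsAsFactors = FALSE
    )
}

#' Band sets used by the binary classification models
#'
#' @param model One of `"A"`, `"B"`, `"C"`.
#' @return Numeric vector of band centers (cm^-1).
#' @examples
#' modelBands("A")  # 940 and 1004
#' @export
modelBands <- function(model = c("A", "B", "C")) {
    model <- match.arg(model)
    switch(model,
        A = c(940, 1004),
        B = c(940, 1004, 1129, 1159),
        C = c(1004, 1302)
    )
}

#' Default per-class band profiles for the spectrum generator
#'
#' Returns one row per registry band with a Gaussian line-shape width and a
#' non-negative relative amplitude per tissue class. The defaults encode the
#' qualitative class contrasts the classifier is expected to recover:
#' cancer shows the strongest phenylalanine band at 1004 cm^-1, normal tissue
#' none-the-less carries it; pure fat lacks phenylalanine entirely (amplitude
#' exactly 0 at 1004 cm^-1) and dominates the lipid bands at 1129 and
#' 1301-1304 cm^-1; normal tissue dominates the 940 cm^-1 collagen band.
#'
#' @param lipidRealism If `TRUE`, add extra generic lipid intensity to the
#'   fat class beyond the registry bands (a realism knob, off by default).
#' @return Data frame with columns `center`, `fwhm`, `cancer`, `normal`,
#'   `fat`.
#' @examples
#' prof <- makeClassProfiles()
#' prof[prof$center == 1004, ]
#' @export
makeClassProfiles <- function(lipidRealism = FALSE) {
    prof <- data.frame(
        center = c(760, 785, 940, 1004, 1129, 1159, 1176, 1208, 1246, 1266,
                   1302, 1600),
        fwhm = c(12, 12, 16, 10, 12, 12, 12, 12, 16, 16, 14, 14),
        #        cancer normal fat
        cancer = c(0.30, 0.35, 0.50, 1.00, 0.35, 0.40, 0.30, 0.30, 0.45,
                   0.45, 0.40, 0.50),
        normal = c(0.20, 0.20, 0.90, 0.55, 0.20, 0.25, 0.18, 0.20, 0.35,
                   0.35, 0.25, 0.30),
        fat    = c(0.05, 0.05, 0.05, 0.00, 1.00, 0.05, 0.05, 0.05, 0.10,
                   0.10, 1.20, 0.10)
    )
    if (lipidRealism) {
        extra <- data.frame(
            center = c(1080, 1440), fwhm = c(18, 22),
            cancer = c(0.05, 0.10), normal = c(0.05, 0.10),
            fat = c(0.8, 1.5)
        )
        extra <- extra[extra$center <= 1800 & extra$center >= 600, ]
        prof <- rbind(prof, extra)
    }
    prof
}

#' Evaluate a band-profile mixture on a wavenumber axis
#'
#' Sums the class's bands as Gaussian (default) or Lorentzian lines.
#'
#' @param profiles Data frame from [makeClassProfiles()].
#' @param class One of `"cancer"`, `"normal"`, `"fat"`.
#' @param axis Wavenumber axis (cm^-1).
#' @param amplitudes Optional per-band amplitude multipliers (length
#'   `nrow(profiles)`), e.g. patient or measurement effects.
#' @param lineshape `"gaussian"` or `"lorentzian"`.
#' @return Numeric vector of relative intensities on `axis`.
#' @export
classSignal <- function(profiles, class, axis, amplitudes = NULL,
                        lineshape = c("gaussian", "lorentzian")) {
    lineshape <- match.arg(lineshape)
    if (!class %in% c("cancer", "normal", "fat"))
        stop("class must be one of 'cancer', 'normal', 'fat', got '",
             class, "'")
    amp <- profiles[[class]]
    if (!is.null(amplitudes)) {
        stopifnot(length(amplitudes) == nrow(profiles))
        amp <- amp * amplitudes
    }
    out <- numeric(length(axis))
    for (b in seq_len(nrow(profiles))) {
        if (amp[b] == 0) next
        if (lineshape == "gaussian") {
            sdv <- profiles$fwhm[b] / (2 * sqrt(2 * log(2)))
            out <- out + amp[b] * exp(-((axis - profiles$center[b])^2) /
                                          (2 * sdv^2))
        } else {
            hw <- profiles$fwhm[b] / 2
            out <- out + amp[b] * hw^2 / ((axis - profiles$center[b])^2 + hw^2)
        }
    }
    out
}

#' Default fingerprint wavenumber axis
#'
#' Spans 600 to 1800 cm^-1 at the instrument's average spectral resolution.
#'
#' @param from,to Axis limits in cm^-1.
#' @param by Sample spacing in cm^-1 (default 1.8, the average resolution).
#' @return Strictly increasing numeric axis.
#' @export
defaultAxis <- function(from = 600, to = 1800, by = 1.8) {
    stopifnot(by > 0, to > from)
    seq(from, to, by = by)
}
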