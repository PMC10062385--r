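# Laser-exposure dosimetry for hazard evaluation: average irradiance over
# a limiting aperture, and the ANSI skin maximum permissible exposure for
# long continuous-wave exposure in the near infrared.

#' Average irradiance over a limiting aperture
#'
#' @param powerMw Delivered optical power in milliwatts.
#' @param apertureDiameterMm Limiting-aperture diameter in millimetres
#'   (3.5 mm is the standard skin hazard aperture).
#' @return Irradiance in W/cm^2.
#' @examples
#' irradiance(100, 3.5)   # ~1.04 W/cm^2
#' irradiance(100, 0.5)   # ~50.9 W/cm^2 at the actual probe spot
#' @export
irradiance <- function(powerMw, apertureDiameterMm) {
    if (any(powerMw <= 0) || any(apertureDiameterMm <= 0))
        stop("power and aperture diameter must be positive")
    (powerMw / 1000) / (pi * (apertureDiameterMm / 10 / 2)^2)
}

#' Skin MPE for long continuous-wave near-infrared exposure
#'
#' Maximum permissible exposure for skin, continuous wave, exposure
#' duration longer than 10 s, in the 700-1050 nm band:
#' `MPE = 0.2 * C_A` W/cm^2 with `C_A = 10^(2 (lambda - 700) / 1000)`.
#' Shorter exposures follow a different (time-dependent) rule and are
#' rejected.
#'
#' @param wavelengthNm Wavelength in nm, within [700, 1050].
#' @param durationS Total exposure duration in seconds; must exceed 10.
#' @return MPE in W/cm^2.
#' @examples
#' mpeSkinCw(785, 40)   # ~0.296, the 0.3 W/cm^2 limit
#' @export
mpeSkinCw <- function(wavelengthNm, durationS) {
    if (any(durationS <= 10))
        stop("this rule covers continuous exposure longer than 10 s")
    if (any(wavelengthNm < 700 | wavelengthNm > 1050))
        stop("wavelength must lie in [700, 1050] nm for this MPE formula")
    ca <- 10^(2 * (wavelengthNm - 700) / 1000)
    0.2 * ca
}

#' Dosimetry summary table
#'
#' Irradiance at the hazard-evaluation aperture and at the probe spot,
#' against the long-exposure skin MPE.
#'
#' @param powerMw Delivered power, mW.
#' @param spotDiameterMm Probe spot diameter, mm.
#' @param apertureDiameterMm Limiting aperture for hazard evaluation, mm.
#' @param wavelengthNm Laser wavelength, nm.
#' @param durationS Total exposure duration, s (> 10).
#' @return Data frame with one row per quantity (`quantity`, `value`,
#'   `unit`).
#' @export
dosimetryTable <- function(powerMw = 100, spotDiameterMm = 0.5,
                           apertureDiameterMm = 3.5, wavelengthNm = 785,
                           durationS = 40) {
    data.frame(
        quantity = c("irradiance_at_aperture", "irradiance_at_spot",
                     "mpe_skin_cw"),
        value = c(irradiance(powerMw, apertureDiameterMm),
                  irradiance(powerMw, spotDiameterMm),
                  mpeSkinCw(wavelengthNm, durationS)),
        unit = "W/cm^2",
        stringsAsFactors = FALSE
    )
}
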