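#' Photon unit constants
#'
#' Conversion constants used throughout the dose bookkeeping.
#' `photons_per_umol` is Avogadro-scaled photon count per micromole
#' (6.022e17 photons umol^-1); `A2_per_m2` is the exact area identity
#' 1 m^2 = 1e20 Angstrom^2; their ratio gives the working conversion
#' 1 umol photons m^-2 s^-1 = 6.022e-3 quanta A^-2 s^-1, which pairs
#' naturally with absorption cross sections expressed in A^2 quanta^-1.
#'
#' @format Named numeric constants.
#' @name photon_units
NULL

#' @rdname photon_units
#' @export
photons_per_umol <- 6.022e17

#' @rdname photon_units
#' @export
A2_per_m2 <- 1e20

#' @rdname photon_units
#' @export
quanta_A2_per_umol <- photons_per_umol / A2_per_m2

#' Convert irradiance to photon dose
#'
#' @param intensity irradiance in umol photons m^-2 s^-1.
#' @param duration_s exposure duration in seconds.
#' @return `incident_photons_m2()`: photons m^-2; `incident_quanta_A2()`:
#'   quanta Angstrom^-2.
#' @examples
#' incident_quanta_A2(1, 1)  # 6.022e-3
#' @export
incident_photons_m2 <- function(intensity, duration_s) {
  stopifnot(all(intensity >= 0), all(duration_s > 0))
  intensity * duration_s * photons_per_umol
}

#' @rdname incident_photons_m2
#' @export
incident_quanta_A2 <- function(intensity, duration_s) {
  incident_photons_m2(intensity, duration_s) / A2_per_m2
}

#' @rdname incident_photons_m2
#' @param photons_m2 dose in photons m^-2.
#' @export
photons_m2_to_quanta_A2 <- function(photons_m2) photons_m2 / A2_per_m2

#' @rdname incident_photons_m2
#' @param quanta_A2 dose in quanta Angstrom^-2.
#' @export
quanta_A2_to_photons_m2 <- function(quanta_A2) quanta_A2 * A2_per_m2
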