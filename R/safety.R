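#' ANSI Z136.1 laser-safety calculations for OR-PAM imaging
#'
#' Small calculator reproducing the maximum-permissible-exposure (MPE) chain
#' for pulsed 532 nm ocular and scleral exposure: single-pulse MPE from the
#' angular-subtense correction factor, the repetitive-pulse n^(-1/4)
#' reduction, aperture-limited pulse energies, and safety margins. The
#' correction factor `C_E` and the single-pulse skin MPE are inputs (their
#' derivation needs the full ANSI angular-subtense tables).
#'
#' @name laser_safety
NULL

#' Single-pulse ocular MPE
#'
#' `MPE_SP = 5.0 * C_E * 1e-7` J/cm^2 (pulsed visible, extended source).
#'
#' @param C_E unitless extended-source correction factor (267 for NA 0.1).
#' @return MPE in J/cm^2.
#' @export
mpe_single_pulse_ocular <- function(C_E) {
  if (C_E <= 0) stop("C_E must be positive")
  5.0 * C_E * 1e-7
}

#' Repetitive-pulse MPE
#'
#' `MPE_RP = n^(-0.25) * MPE_SP`.
#'
#' @param mpe_sp single-pulse MPE (any fluence unit).
#' @param n number of pulses delivered to the site, >= 1.
#' @return repetitive-pulse MPE in the units of `mpe_sp`.
#' @export
mpe_repetitive <- function(mpe_sp, n) {
  if (any(n < 1)) stop("pulse count must be >= 1")
  mpe_sp * n^(-0.25)
}

#' Maximum permissible pulse energy through an aperture
#'
#' Fluence limit times aperture area, `MPE * pi * (d/2)^2`, with the
#' diameter converted to cm.
#'
#' @param mpe_rp fluence limit, J/cm^2.
#' @param aperture_diameter aperture (pupil or spot) diameter.
#' @param units diameter units, `"mm"` or `"um"`.
#' @return energy, J.
#' @export
max_pulse_energy <- function(mpe_rp, aperture_diameter,
                             units = c("mm", "um")) {
  units <- match.arg(units)
  if (aperture_diameter < 0) stop("aperture diameter must be >= 0")
  d_cm <- aperture_diameter * switch(units, mm = 0.1, um = 1e-4)
  mpe_rp * pi * (d_cm / 2)^2
}

#' Repetitive pulse count within one irradiated spot
#'
#' With scan steps of `step_size`, a spot of diameter `spot_diameter`
#' receives `floor(spot_diameter / step_size)` pulses.
#'
#' @param spot_diameter irradiated spot diameter, um.
#' @param step_size scan step, um.
#' @return integer pulse count.
#' @export
pulses_in_spot <- function(spot_diameter, step_size) {
  if (spot_diameter <= 0 || step_size <= 0)
    stop("spot diameter and step size must be positive")
  as.integer(floor(spot_diameter / step_size))
}

#' Safety margin
#'
#' Ratio of the permissible pulse energy to the energy actually used.
#'
#' @param permissible permissible energy, J.
#' @param used energy used, J; > 0.
#' @return unitless ratio.
#' @export
safety_margin <- function(permissible, used) {
  if (used <= 0) stop("used energy must be positive")
  permissible / used
}

#' Full safety report for an exposure configuration
#'
#' Chains the ocular and scleral MPE calculations and compares both
#' permissible pulse energies against the energy in use.
#'
#' @param C_E extended-source correction factor. Default 267 (NA 0.1).
#' @param n_total total pulses in a scan. Default `1200 * 600`.
#' @param pupil_diameter_mm human pupil diameter, mm. Default 7.
#' @param mpe_sp_skin_mJ single-pulse skin MPE, mJ/cm^2. Default 20.
#' @param spot_diameter_um irradiated scleral spot, um. Default 106.
#' @param step_size_um scan step, um. Default 2.5.
#' @param pulse_energy_J pulse energy in use, J. Default 120e-9.
#' @return list of all intermediate and final quantities (class
#'   `safety_report`).
#' @export
safety_report <- function(C_E = 267, n_total = 1200 * 600,
                          pupil_diameter_mm = 7, mpe_sp_skin_mJ = 20,
                          spot_diameter_um = 106, step_size_um = 2.5,
                          pulse_energy_J = 120e-9) {
  if (n_total < 1) stop("n_total must be >= 1")
  mpe_sp <- mpe_single_pulse_ocular(C_E)
  mpe_rp <- mpe_repetitive(mpe_sp, n_total)
  ocular_energy <- max_pulse_energy(mpe_rp, pupil_diameter_mm, "mm")
  n_spot <- pulses_in_spot(spot_diameter_um, step_size_um)
  mpe_rp_skin_mJ <- mpe_repetitive(mpe_sp_skin_mJ, n_spot)
  scleral_energy <- max_pulse_energy(mpe_rp_skin_mJ * 1e-3,
                                     spot_diameter_um, "um")
  structure(list(
    C_E = C_E, n_total = n_total,
    mpe_sp_ocular_J_cm2 = mpe_sp,
    mpe_rp_ocular_J_cm2 = mpe_rp,
    ocular_max_pulse_energy_J = ocular_energy,
    ocular_margin = safety_margin(ocular_energy, pulse_energy_J),
    pulses_in_spot = n_spot,
    mpe_rp_scleral_mJ_cm2 = mpe_rp_skin_mJ,
    scleral_max_pulse_energy_J = scleral_energy,
    scleral_margin = safety_margin(scleral_energy, pulse_energy_J),
    pulse_energy_J = pulse_energy_J
  ), class = "safety_report")
}

#' @export
print.safety_report <- function(x, ...) {
  cat("<safety_report> ANSI Z136.1 maximum permissible exposure\n")
  cat(sprintf("  ocular:  MPE_SP %.3g J/cm^2, MPE_RP(n=%g) %.2g J/cm^2\n",
              x$mpe_sp_ocular_J_cm2, x$n_total, x$mpe_rp_ocular_J_cm2))
  cat(sprintf("           max pulse energy %.2g J (margin %.1fx vs %.3g J)\n",
              x$ocular_max_pulse_energy_J, x$ocular_margin,
              x$pulse_energy_J))
  cat(sprintf("  scleral: n_spot %d, MPE_RP %.2g mJ/cm^2, max energy %.2g J (margin %.1fx)\n",
              x$pulses_in_spot, x$mpe_rp_scleral_mJ_cm2,
              x$scleral_max_pulse_energy_J, x$scleral_margin))
  invisible(x)
}
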