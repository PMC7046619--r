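# Closed-form Cherenkov physics: thresholds, Compton electron spectra
# (Klein-Nishina), Frank-Tamm photon yield along CSDA slowing, and the
# per-medium light-yield-per-dose factor used by the forward imaging model.

ELECTRON_REST_KEV <- 511.0
FINE_STRUCTURE <- 1 / 137.035999

#' Construct an optical medium
#'
#' @param name Medium identifier.
#' @param refractive_index Refractive index n in the visible band (n > 1).
#' @param density Mass density, g/cm^3.
#' @return A `medium` object.
#' @export
medium <- function(name, refractive_index, density = 1.0) {
  if (refractive_index <= 1) {
    stop("refractive index must exceed 1 for Cherenkov emission")
  }
  if (density <= 0) stop("density must be positive (g/cm^3)")
  structure(list(name = name, refractive_index = refractive_index,
                 density = density), class = "medium")
}

#' Water and catheter-plastic media
#'
#' Default media: water (n = 1.33) and catheter plastic (n = 1.59). These
#' indices place the Cherenkov thresholds at 264.1 keV and 146.3 keV
#' respectively.
#'
#' @return A [medium()].
#' @export
water_medium <- function() medium("water", 1.33, 1.0)

#' @rdname water_medium
#' @export
catheter_medium <- function() medium("catheter plastic", 1.59, 1.19)

#' Cherenkov emission threshold
#'
#' Kinetic energy at which an electron's speed equals the phase velocity of
#' light in the medium:
#' \deqn{T_{thr} = m_e c^2 (1/\sqrt{1 - n^{-2}} - 1)}
#' with \eqn{m_e c^2} = 511.0 keV.
#'
#' @param med A [medium()].
#' @return Threshold kinetic energy, keV.
#' @export
cherenkov_threshold <- function(med) {
  n <- med$refractive_index
  ELECTRON_REST_KEV * (1 / sqrt(1 - n^-2) - 1)
}

#' Maximum Compton electron energy
#'
#' Kinematic maximum (backscatter edge) of the Compton electron energy for an
#' incident photon of energy E: \eqn{T_{max} = 2E^2 / (m_e c^2 + 2E)}.
#'
#' @param photon_energy Photon energy, keV (vectorised).
#' @return Maximum electron kinetic energy, keV.
#' @export
compton_tmax <- function(photon_energy) {
  if (any(photon_energy <= 0)) stop("photon energy must be positive (keV)")
  2 * photon_energy^2 / (ELECTRON_REST_KEV + 2 * photon_energy)
}

# Klein-Nishina differential cross-section in electron energy T for photon
# energy E, in units of pi re^2 / (me c^2). Zero outside [0, T_max].
kn_dsigma_dT <- function(T, E) {
  kap <- E / ELECTRON_REST_KEV
  s <- T / E
  out <- (1 / (ELECTRON_REST_KEV * kap^2)) *
    (2 + s^2 / (kap^2 * (1 - s)^2) + s / (1 - s) * (s - 2 / kap))
  out[T < 0 | T > compton_tmax(E)] <- 0
  out
}

# Klein-Nishina total cross-section in units of 2 pi re^2
kn_sigma_total <- function(E) {
  k <- E / ELECTRON_REST_KEV
  (1 + k) / k^2 * (2 * (1 + k) / (1 + 2 * k) - log(1 + 2 * k) / k) +
    log(1 + 2 * k) / (2 * k) - (1 + 3 * k) / (1 + 2 * k)^2
}

# per-line interaction weight: Klein-Nishina total cross-section relative to
# the Thomson limit (dimensionless, < 1 in this energy range)
kn_interaction_weight <- function(E) {
  kn_sigma_total(E) / (4 / 3)  # sigma_Thomson = (8/3) pi re^2 = 2 pi re^2 * 4/3
}

#' Compton electron energy spectrum for a gamma line
#'
#' Klein-Nishina differential cross-section in electron energy, normalised so
#' that the integral over [0, T_max] equals `line$intensity` times the line's
#' interaction weight (Klein-Nishina total cross-section relative to the
#' Thomson cross-section).
#'
#' @param line A [gamma_line()].
#' @param grid Electron kinetic-energy grid, keV, within [0, T_max]; energies
#'   beyond T_max are clipped to zero density with a warning.
#' @return An `electron_spectrum`: list with `energies` (keV) and `density`
#'   (electrons per decay per keV).
#' @export
compton_electron_spectrum <- function(line, grid = NULL) {
  tmax <- compton_tmax(line$energy)
  if (is.null(grid)) grid <- seq(0, tmax, length.out = 512)
  if (any(grid > tmax + 1e-9)) {
    warning("energy grid exceeds the Compton maximum; clipping to zero")
  }
  raw <- kn_dsigma_dT(grid, line$energy)
  # normalise by the analytic total cross-section in the same re^2 units:
  # integral of kn_dsigma_dT over T is 2 * kn_sigma_total (both per pi re^2)
  total <- 2 * kn_sigma_total(line$energy)
  dens <- raw / total * line$intensity * kn_interaction_weight(line$energy)
  structure(list(energies = grid, density = dens,
                 line = line, tmax = tmax),
            class = "electron_spectrum")
}

#' CSDA electron range (Katz-Penfold)
#'
#' Empirical continuous-slowing-down range
#' \deqn{R[g/cm^2] = 0.412\, T^{1.265 - 0.0954 \ln T}} (T in MeV, valid up to
#' 2.5 MeV), divided by the medium density to give a length.
#'
#' @param T0 Initial electron kinetic energy, keV (vectorised).
#' @param med A [medium()].
#' @return Range in mm.
#' @export
csda_range <- function(T0, med = water_medium()) {
  if (any(T0 <= 0)) stop("electron energy must be positive (keV)")
  if (any(T0 > 2500)) stop("Katz-Penfold range unsupported above 2.5 MeV")
  t_mev <- T0 / 1000
  r_gcm2 <- 0.412 * t_mev^(1.265 - 0.0954 * log(t_mev))
  r_gcm2 / med$density * 10  # cm -> mm
}

#' Frank-Tamm Cherenkov emission rate at a given electron energy
#'
#' Photons per mm of path for an electron of kinetic energy `T` in the
#' wavelength band: \eqn{2\pi\alpha (1/\lambda_1 - 1/\lambda_2)
#' (1 - 1/(\beta^2 n^2))}, zero below the Cherenkov threshold. In the
#' saturated limit \eqn{\beta = 1} in water over 400-700 nm this is 21.35
#' photons/mm.
#'
#' @param T Electron kinetic energy, keV (vectorised).
#' @param med A [medium()].
#' @param band Wavelength interval, nm.
#' @return Photons per mm.
#' @export
franktamm_rate <- function(T, med = water_medium(), band = c(400, 700)) {
  if (band[1] >= band[2]) stop("wavelength band must be increasing (nm)")
  n <- med$refractive_index
  band_mm <- 2 * pi * FINE_STRUCTURE *
    (1 / (band[1] * 1e-6) - 1 / (band[2] * 1e-6))
  beta2 <- 1 - (ELECTRON_REST_KEV / (T + ELECTRON_REST_KEV))^2
  pmax(0, band_mm * (1 - 1 / (beta2 * n^2)))
}

#' Frank-Tamm Cherenkov photon yield of a slowing electron
#'
#' Integrates the Frank-Tamm spectral yield
#' \deqn{d^2N/dx\,d\lambda = 2\pi\alpha/\lambda^2 (1 - 1/(\beta^2 n^2))}
#' over the wavelength band and along the electron's continuous slowing from
#' `T0` down to the Cherenkov threshold, using the Katz-Penfold range with a
#' linear energy-versus-residual-range profile.
#'
#' @param T0 Initial electron kinetic energy, keV.
#' @param med A [medium()].
#' @param band Wavelength interval in nm, within [300, 900].
#' @return Photons emitted per electron (0 below threshold).
#' @export
franktamm_yield <- function(T0, med = water_medium(), band = c(400, 700)) {
  if (band[1] >= band[2]) stop("wavelength band must be increasing (nm)")
  if (band[1] < 300 || band[2] > 900) stop("band must lie within 300-900 nm")
  if (T0 < 0) stop("T0 must be non-negative (keV)")
  thr <- cherenkov_threshold(med)
  if (T0 <= thr) return(0)
  # linear T(x): x from 0 to R(T0) maps to T from T0 to 0, so dx = R/T0 dT
  R <- csda_range(T0, med)
  (R / T0) * stats::integrate(franktamm_rate, thr, T0, med = med,
                              band = band, rel.tol = 1e-8)$value
}

#' Relative Cherenkov light yield per unit dose for a medium
#'
#' Line-intensity-weighted sum over the source's gamma lines of the
#' interaction weight times the mean Frank-Tamm photon yield over each line's
#' Compton electron spectrum. Only lines whose Compton maximum exceeds the
#' medium's Cherenkov threshold contribute. The scale is relative (photons
#' per decay-weighted interaction); absolute optical calibration is carried
#' by the camera gain.
#'
#' @param spec A [source_spec()] with a gamma line table.
#' @param med A [medium()].
#' @param band Wavelength band, nm.
#' @return Relative photons per unit dose (dimensionless scale).
#' @export
light_yield_per_dose <- function(spec, med = water_medium(),
                                 band = c(400, 700)) {
  if (length(spec$lines) == 0) stop("source spec has an empty gamma line table")
  thr <- cherenkov_threshold(med)
  total <- 0
  for (line in spec$lines) {
    tmax <- compton_tmax(line$energy)
    if (tmax <= thr) next
    sp <- compton_electron_spectrum(line)
    w <- sp$density            # already intensity x interaction weight per keV
    yl <- vapply(sp$energies, franktamm_yield, numeric(1), med = med, band = band)
    total <- total + sum(w * yl) * mean(diff(sp$energies))
  }
  total
}
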