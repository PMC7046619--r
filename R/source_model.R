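#' Construct a gamma emission line
#'
#' @param energy Photon energy in keV.
#' @param intensity Emission probability per decay (a summed line table may
#'   exceed 1 per decay for a cascade emitter such as Ir-192).
#' @return A `gamma_line` object.
#' @export
gamma_line <- function(energy, intensity) {
  stopifnot(is.numeric(energy), is.numeric(intensity))
  if (energy <= 0) stop("gamma line energy must be positive (keV)")
  if (intensity <= 0 || intensity > 3) {
    stop("gamma line intensity must lie in (0, 3] per decay")
  }
  structure(list(energy = energy, intensity = intensity),
            class = "gamma_line")
}

#' Construct a TG-43 source specification
#'
#' Holds the TG-43 dosimetry parameters of a sealed HDR source: air-kerma
#' strength \eqn{S_K} (U = cGy cm^2/h), dose-rate constant \eqn{\Lambda}
#' (cGy/h/U), radial dose function \eqn{g(r)} as polynomial coefficients in
#' r (cm), a 1D anisotropy factor \eqn{\phi_{an}}, the half-life, and the
#' gamma emission line table.
#'
#' @param name Source model identifier.
#' @param half_life Half-life in days.
#' @param air_kerma_strength \eqn{S_K} in U.
#' @param dose_rate_constant \eqn{\Lambda} in cGy/h/U.
#' @param radial_dose_coeffs Polynomial coefficients `c0..ck` of g(r), r in cm.
#'   Renormalised at construction so that g(1 cm) = 1 exactly.
#' @param radial_dose_r_range Two-element vector (cm): r is clamped to this
#'   interval before evaluating the polynomial.
#' @param anisotropy 1D anisotropy factor: a single number in (0, 1.2] or a
#'   function of r (mm).
#' @param active_length,diameter Source dimensions in mm.
#' @param lines List of [gamma_line()] objects.
#' @param strength_date Calendar day index at which `air_kerma_strength` holds.
#' @param air_kerma_rate_constant \eqn{\Gamma} in U per GBq, used by
#'   [air_kerma_to_activity()].
#' @param capsule_beta_transmission Fraction of decay electrons escaping the
#'   capsule (plumbing constant for the near-source beta component).
#' @param beta_dose_fraction Escaped-beta dose as a fraction of gamma dose.
#' @param beta_endpoint Beta spectrum endpoint energy, keV.
#' @return A `source_spec` object.
#' @export
source_spec <- function(name,
                        half_life,
                        air_kerma_strength,
                        dose_rate_constant = 1.109,
                        radial_dose_coeffs = c(1),
                        radial_dose_r_range = c(0.25, 10),
                        anisotropy = 1,
                        active_length = 3.5,
                        diameter = 0.9,
                        lines = list(),
                        strength_date = 0,
                        air_kerma_rate_constant = 110,
                        capsule_beta_transmission = 3e-4,
                        beta_dose_fraction = 5e-4,
                        beta_endpoint = 675) {
  if (half_life <= 0) stop("half_life must be positive (days)")
  if (air_kerma_strength <= 0) stop("air_kerma_strength must be positive (U)")
  if (dose_rate_constant <= 0) stop("dose_rate_constant must be positive")
  g1 <- sum(radial_dose_coeffs * 1^(seq_along(radial_dose_coeffs) - 1))
  if (g1 <= 0) stop("radial dose polynomial must be positive at r = 1 cm")
  radial_dose_coeffs <- radial_dose_coeffs / g1  # enforce g(1 cm) = 1
  if (is.numeric(anisotropy)) {
    if (anisotropy <= 0 || anisotropy > 1.2) {
      stop("anisotropy factor must lie in (0, 1.2]")
    }
  } else if (!is.function(anisotropy)) {
    stop("anisotropy must be a number or a function of r (mm)")
  }
  structure(list(
    name = name,
    half_life = half_life,
    air_kerma_strength = air_kerma_strength,
    dose_rate_constant = dose_rate_constant,
    radial_dose_coeffs = radial_dose_coeffs,
    radial_dose_r_range = radial_dose_r_range,
    anisotropy = anisotropy,
    active_length = active_length,
    diameter = diameter,
    lines = lines,
    strength_date = strength_date,
    air_kerma_rate_constant = air_kerma_rate_constant,
    capsule_beta_transmission = capsule_beta_transmission,
    beta_dose_fraction = beta_dose_fraction,
    beta_endpoint = beta_endpoint
  ), class = "source_spec")
}

#' @export
print.source_spec <- function(x, ...) {
  cat(sprintf("<source_spec %s>  S_K = %g U, Lambda = %g cGy/h/U, T1/2 = %g d, %d gamma lines\n",
              x$name, x$air_kerma_strength, x$dose_rate_constant,
              x$half_life, length(x$lines)))
  invisible(x)
}

#' Load a source specification from YAML
#'
#' Reads a source parameter file in the layout of the bundled
#' `mhdr_v2.yaml` (see `system.file("extdata", "mhdr_v2.yaml",
#' package = "cherenkovqa")`).
#'
#' @param path Path to the YAML file.
#' @return A [source_spec()].
#' @export
read_source_spec <- function(path) {
  y <- yaml::read_yaml(path)
  source_spec(
    name = y$name,
    half_life = y$half_life_days,
    air_kerma_strength = y$air_kerma_strength_U,
    dose_rate_constant = y$dose_rate_constant_cGy_per_hU,
    radial_dose_coeffs = as.numeric(y$radial_dose_coeffs),
    radial_dose_r_range = as.numeric(y$radial_dose_r_range_cm),
    anisotropy = y$anisotropy_factor,
    active_length = y$active_length_mm,
    diameter = y$diameter_mm,
    lines = lapply(y$gamma_lines, function(l) gamma_line(l$energy, l$intensity)),
    strength_date = y$strength_date,
    air_kerma_rate_constant = y$air_kerma_rate_constant_U_per_GBq,
    capsule_beta_transmission = y$capsule_beta_transmission,
    beta_dose_fraction = y$beta_dose_fraction,
    beta_endpoint = y$beta_endpoint_keV
  )
}

#' The bundled Ir-192 mHDR-v2 source
#'
#' Convenience constructor for the bundled Nucletron mHDR-v2 parameter set
#' (half-life 73.83 days, Lambda = 1.109 cGy/h/U, principal gamma lines).
#'
#' @param air_kerma_strength Optional override of S_K (U); default is the
#'   bundled 32,800 U.
#' @return A [source_spec()].
#' @export
ir192_hdr_source <- function(air_kerma_strength = NULL) {
  spec <- read_source_spec(system.file("extdata", "mhdr_v2.yaml",
                                       package = "cherenkovqa"))
  if (!is.null(air_kerma_strength)) {
    stopifnot(air_kerma_strength > 0)
    spec$air_kerma_strength <- air_kerma_strength
  }
  spec
}

#' Construct a dwell sequence
#'
#' @param positions Dwell positions in mm along the source-movement (x) axis.
#' @param times Dwell times in seconds, recycled to the length of `positions`.
#' @return A `dwell_sequence` object (data frame with `position`, `time`).
#' @export
dwell_sequence <- function(positions, times) {
  if (length(positions) < 1) stop("dwell sequence must contain at least one dwell")
  if (any(!is.finite(positions))) stop("dwell positions must be finite")
  times <- rep_len(times, length(positions))
  if (any(times <= 0)) stop("dwell times must be positive")
  structure(data.frame(position = positions, time = times),
            class = c("dwell_sequence", "data.frame"))
}

# radial dose function g(r); r in mm, polynomial argument in cm, clamped to the
# fitted range so the high-order terms never extrapolate
radial_dose <- function(spec, r_mm) {
  r_cm <- pmin(pmax(r_mm / 10, spec$radial_dose_r_range[1]),
               spec$radial_dose_r_range[2])
  k <- seq_along(spec$radial_dose_coeffs) - 1
  out <- 0
  for (i in seq_along(k)) out <- out + spec$radial_dose_coeffs[i] * r_cm^k[i]
  out
}

anisotropy_at <- function(spec, r_mm) {
  if (is.function(spec$anisotropy)) spec$anisotropy(r_mm) else spec$anisotropy
}

#' TG-43 point-source dose rate
#'
#' Evaluates the 1D point-source TG-43 dose rate
#' \deqn{\dot D(r) = S_K \Lambda (r_0/r)^2 g(r) \phi_{an}(r)}
#' with reference distance \eqn{r_0} = 10 mm, converted to Gy/min. The result
#' is cylindrically symmetric about the source long axis (it depends on the
#' distance r only).
#'
#' @param spec A [source_spec()].
#' @param r Distance from the source centre, mm (vectorised).
#' @param theta Polar angle in degrees from the source long axis. Ignored by
#'   the point-source form; accepted for interface compatibility.
#' @return Dose rate in Gy/min.
#' @export
dose_rate_point <- function(spec, r, theta = 90) {
  if (any(r <= 0)) stop("r must be positive (mm)")
  if (any(r <= 0.05)) stop("r = ", min(r), " mm is inside the source")
  d_cgy_h <- spec$air_kerma_strength * spec$dose_rate_constant *
    (10 / r)^2 * radial_dose(spec, r) * anisotropy_at(spec, r)
  d_cgy_h / 100 / 60  # cGy/h -> Gy/min
}

#' Dwell time delivering a target dose
#'
#' @param spec A [source_spec()].
#' @param target_dose Dose to deliver, Gy.
#' @param r Distance of the dose point from the source centre, mm.
#' @return Dwell time in seconds such that time x dose rate = target dose.
#' @export
dwell_time_for_dose <- function(spec, target_dose, r = 10) {
  if (any(target_dose <= 0)) stop("target_dose must be positive (Gy)")
  target_dose / dose_rate_point(spec, r) * 60
}

#' Radioactive decay factor
#'
#' @param spec A [source_spec()].
#' @param elapsed Days since the strength date.
#' @return `2^(-elapsed / half_life)`, dimensionless.
#' @export
decay_factor <- function(spec, elapsed) {
  if (any(elapsed < 0)) stop("elapsed must be non-negative (days)")
  2^(-elapsed / spec$half_life)
}

#' Convert air-kerma strength to activity
#'
#' Divides by the source's bundled air-kerma rate constant Gamma
#' (default 110 U/GBq).
#'
#' @param s_k Air-kerma strength, U.
#' @param spec Optional [source_spec()] carrying Gamma; the bundled Ir-192
#'   value is used when omitted.
#' @return Activity in GBq.
#' @export
air_kerma_to_activity <- function(s_k, spec = NULL) {
  if (any(s_k <= 0)) stop("air-kerma strength must be positive (U)")
  gamma <- if (is.null(spec)) 110 else spec$air_kerma_rate_constant
  s_k / gamma
}

#' Dose grid from a dwell sequence
#'
#' Superposes per-dwell TG-43 point-source fields, weighted by dwell time, on
#' a regular voxel-centred grid. Axes: x = source-movement axis, y = vertical
#' in-image axis, z = camera (projection) axis; origin is the source-centre
#' frame.
#'
#' @param spec A [source_spec()].
#' @param dwells A [dwell_sequence()].
#' @param x,y,z Voxel-centre coordinates along each axis, mm (regular spacing).
#' @return A `dose_grid`: 3D array (Gy) with attributes `x`, `y`, `z`.
#' @export
dose_grid <- function(spec, dwells,
                      x = seq(-25, 25, by = 1),
                      y = seq(-25, 25, by = 1),
                      z = seq(-49.5, 49.5, by = 1)) {
  if (!inherits(dwells, "dwell_sequence") || nrow(dwells) == 0) {
    stop("dwells must be a non-empty dwell_sequence")
  }
  vals <- array(0, dim = c(length(x), length(y), length(z)))
  yz2 <- outer(y^2, z^2, "+")          # |y,z| part, shared across dwells
  for (i in seq_len(nrow(dwells))) {
    dx2 <- (x - dwells$position[i])^2
    for (ix in seq_along(x)) {
      r <- sqrt(dx2[ix] + yz2)
      vals[ix, , ] <- vals[ix, , ] +
        dose_rate_point(spec, r) * dwells$time[i] / 60
    }
  }
  structure(vals, x = x, y = y, z = z, class = c("dose_grid", "array"))
}

#' Accumulate a dose grid along the camera axis
#'
#' Sums z-slices spanning +/- thickness/2 about the source plane, emulating
#' light projected through a water slab in front of the source. The result is
#' an accumulated dose map in Gy x slices.
#'
#' @param grid A [dose_grid()].
#' @param thickness Slab thickness, mm.
#' @return 2D matrix (x by y) with attributes `x`, `y`.
#' @export
project_dose <- function(grid, thickness = 100) {
  z <- attr(grid, "z")
  dz <- if (length(z) > 1) mean(diff(z)) else 1
  if (thickness > (max(z) - min(z)) + dz) {
    stop("projection thickness exceeds the grid z-extent")
  }
  keep <- abs(z) <= thickness / 2
  proj <- apply(unclass(grid)[, , keep, drop = FALSE], c(1, 2), sum)
  structure(proj, x = attr(grid, "x"), y = attr(grid, "y"))
}

#' Export a dose grid as flat CSV
#'
#' @param grid A [dose_grid()].
#' @param path Output CSV path (columns x, y, z, dose).
#' @export
write_dose_grid_csv <- function(grid, path) {
  x <- attr(grid, "x"); y <- attr(grid, "y"); z <- attr(grid, "z")
  df <- expand.grid(x = x, y = y, z = z)
  df$dose <- as.vector(unclass(grid))
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}
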