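# Processing chain from raw image pairs to calibrated dose profiles:
# background subtraction, radius-2 disc median filter, 1-pixel profile
# extraction, dose-linearity calibration at the 10-mm reference point,
# normalisation.

#' Subtract a background image
#'
#' Elementwise difference in a signed representation; negatives are preserved
#' so noise statistics stay unbiased.
#'
#' @param light,background `light_image`s of identical geometry.
#' @return A signed `light_image`.
#' @export
subtract_background <- function(light, background) {
  if (!identical(dim(light), dim(background))) {
    stop("light and background images have different dimensions")
  }
  if (!isTRUE(all.equal(attr(light, "pixel_pitch"),
                        attr(background, "pixel_pitch")))) {
    stop("light and background images have different pixel pitch")
  }
  light_image(unclass(light) - unclass(background),
              attr(light, "pixel_pitch"), attr(light, "metadata"))
}

# offsets of the Euclidean disc of given pixel radius (ImageJ convention);
# radius 2 gives the 13-pixel neighbourhood
disc_offsets <- function(radius) {
  d <- expand.grid(dy = -radius:radius, dx = -radius:radius)
  d[d$dx^2 + d$dy^2 <= radius^2 + 1e-9, ]
}

# reflect-pad a matrix by `pad` pixels on every side (mirror about the edge
# pixel, without repeating it: ..., 3, 2 | 1 ... n | n-1, n-2, ...)
reflect_pad <- function(m, pad) {
  n <- nrow(m); p <- ncol(m)
  ri <- c((pad + 1):2, 1:n, (n - 1):(n - pad))
  ci <- c((pad + 1):2, 1:p, (p - 1):(p - pad))
  m[ri, ci]
}

#' Disc median filter
#'
#' Replaces each pixel by the median over the Euclidean disc of the given
#' pixel radius (13 pixels at radius 2), with reflection padding at the
#' edges.
#'
#' @param image A `light_image` or plain matrix.
#' @param radius_px Disc radius in pixels (default 2).
#' @return Filtered image of the same class.
#' @export
median_filter <- function(image, radius_px = 2) {
  radius_px <- as.integer(radius_px)
  if (radius_px < 0) stop("radius must be a non-negative integer")
  if (radius_px == 0) return(image)
  m <- unclass(image)
  n <- nrow(m); p <- ncol(m)
  padded <- reflect_pad(m, radius_px)
  off <- disc_offsets(radius_px)
  k <- nrow(off)
  stacked <- matrix(0, nrow = n * p, ncol = k)
  for (j in seq_len(k)) {
    stacked[, j] <- padded[(radius_px + off$dy[j]) + 1:n,
                           (radius_px + off$dx[j]) + 1:p]
  }
  # median of k values per row via one global order: for odd k it is the
  # ((k+1)/2)-th order statistic
  if (k %% 2 == 1) {
    srt <- matrix(stacked[order(row(stacked), stacked)],
                  nrow = n * p, byrow = TRUE)
    med <- srt[, (k + 1) / 2]
  } else {
    srt <- matrix(stacked[order(row(stacked), stacked)],
                  nrow = n * p, byrow = TRUE)
    med <- (srt[, k / 2] + srt[, k / 2 + 1]) / 2
  }
  out <- matrix(med, nrow = n)
  if (inherits(image, "light_image")) {
    light_image(out, attr(image, "pixel_pitch"), attr(image, "metadata"))
  } else out
}

#' Construct a profile
#'
#' @param positions Sample positions, mm, strictly increasing and uniform.
#' @param values Sample values (counts or Gy).
#' @param axis `"parallel"` (along source movement) or `"perpendicular"`.
#' @param units Value units label.
#' @param width_px Number of averaged pixel lines.
#' @return A `profile` object.
#' @export
profile <- function(positions, values, axis = "perpendicular",
                    units = "counts", width_px = 1L) {
  stopifnot(length(positions) == length(values))
  if (any(diff(positions) <= 0)) stop("positions must be strictly increasing")
  if (any(!is.finite(values))) stop("profile values must be finite")
  structure(list(positions = positions, values = values, axis = axis,
                 units = units, width_px = as.integer(width_px)),
            class = "profile")
}

#' @export
print.profile <- function(x, ...) {
  cat(sprintf("<profile %s, %d samples, %.3g..%.3g mm, units %s>\n",
              x$axis, length(x$positions), min(x$positions),
              max(x$positions), x$units))
  invisible(x)
}

#' Extract a 1-pixel intensity profile
#'
#' Samples the pixel row (parallel axis) or column (perpendicular axis)
#' nearest the line `through`; `width_px > 1` averages that many adjacent
#' lines centred on it. Positions are pixel centres in mm relative to
#' `origin` (the image centre before localization, the located source centre
#' after).
#'
#' @param image A `light_image` (or matrix plus `pixel_pitch`).
#' @param axis `"parallel"` or `"perpendicular"`.
#' @param through Perpendicular coordinate of the line, mm from image centre.
#' @param width_px Averaging width in pixel lines.
#' @param origin Position subtracted from the sampled coordinates, mm.
#' @param pixel_pitch Override when `image` is a bare matrix.
#' @return A [profile()].
#' @export
extract_profile <- function(image, axis = c("perpendicular", "parallel"),
                            through = 0, width_px = 1L, origin = 0,
                            pixel_pitch = attr(image, "pixel_pitch")) {
  axis <- match.arg(axis)
  m <- unclass(image)
  xs <- (seq_len(ncol(m)) - (ncol(m) + 1) / 2) * pixel_pitch
  ys <- (seq_len(nrow(m)) - (nrow(m) + 1) / 2) * pixel_pitch
  half <- (as.integer(width_px) - 1L) %/% 2L
  if (axis == "parallel") {
    centre <- which.min(abs(ys - through))
    rows <- max(1, centre - half):min(nrow(m), centre + half)
    if (abs(ys[centre] - through) > pixel_pitch) {
      stop("profile line lies outside the image")
    }
    vals <- colMeans(m[rows, , drop = FALSE])
    profile(xs - origin, vals, axis = "parallel", width_px = width_px)
  } else {
    centre <- which.min(abs(xs - through))
    if (abs(xs[centre] - through) > pixel_pitch) {
      stop("profile line lies outside the image")
    }
    cols <- max(1, centre - half):min(ncol(m), centre + half)
    vals <- rowMeans(m[, cols, drop = FALSE])
    profile(ys - origin, vals, axis = "perpendicular", width_px = width_px)
  }
}

# linear interpolation of a profile at arbitrary positions
profile_value_at <- function(prof, at) {
  stats::approx(prof$positions, prof$values, xout = at, rule = 1)$y
}

#' Fit the dose-linearity calibration
#'
#' Ordinary least-squares fit of light intensity against delivered dose; the
#' slope (counts per Gy at the reference point) is the calibration factor.
#'
#' @param doses Delivered reference-point doses, Gy (>= 3 values spanning a
#'   range).
#' @param intensities Measured intensities, counts.
#' @param r_ref Reference distance the intensities were read at, mm.
#' @return A `calibration_factor`: list with `slope`, `intercept`, `r_ref`,
#'   `fit_r2`.
#' @export
fit_linearity <- function(doses, intensities, r_ref = 10) {
  if (length(doses) < 3) stop("need at least 3 dose levels")
  if (stats::var(doses) == 0) stop("doses have zero variance")
  fit <- stats::lm(intensities ~ doses)
  # summary.lm warns on numerically perfect fits; those are fine here
  r2 <- suppressWarnings(summary(fit)$r.squared)
  structure(list(slope = unname(stats::coef(fit)[2]),
                 intercept = unname(stats::coef(fit)[1]),
                 r_ref = r_ref,
                 fit_r2 = r2),
            class = "calibration_factor")
}

#' Calibrate a profile to absolute dose
#'
#' Subtracts the fit intercept (residual background) and divides by the
#' slope; values become Gy.
#'
#' @param prof A [profile()] in counts.
#' @param cal A `calibration_factor` from [fit_linearity()].
#' @return A [profile()] in Gy.
#' @export
calibrate_profile <- function(prof, cal) {
  if (cal$slope <= 0) stop("calibration slope must be positive")
  profile(prof$positions, (prof$values - cal$intercept) / cal$slope,
          axis = prof$axis, units = "Gy", width_px = prof$width_px)
}

#' Normalise a profile at a reference distance
#'
#' Divides by the (linearly interpolated) value at `at` mm on the positive
#' side, making the profile 1.0 there. Idempotent and scale-invariant.
#'
#' @param prof A [profile()].
#' @param at Normalisation distance, mm (default the 10-mm reference point).
#' @return A relative [profile()].
#' @export
normalise_profile <- function(prof, at = 10) {
  v <- profile_value_at(prof, at)
  if (is.na(v)) stop("profile does not cover the normalisation point")
  if (v <= 0) stop("non-positive value at the normalisation point")
  profile(prof$positions, prof$values / v, axis = prof$axis,
          units = "relative", width_px = prof$width_px)
}

#' Export a profile as CSV
#'
#' Two columns (position_mm, value) with a header comment naming the axis and
#' units.
#'
#' @param prof A [profile()].
#' @param path Output path.
#' @param slope Optional calibration slope recorded in the header.
#' @export
write_profile_csv <- function(prof, path, slope = NA) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# axis=%s units=%s width_px=%d calibration_slope=%s",
                     prof$axis, prof$units, prof$width_px,
                     format(slope)), con)
  utils::write.csv(data.frame(position_mm = prof$positions,
                              value = prof$values),
                   con, row.names = FALSE)
  invisible(path)
}
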