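# QA quantities: FWHM-midpoint source localization, dwell intervals,
# source-strength tracking and half-life fitting, repeatability, dose-rate
# independence, and profile-versus-reference agreement.

#' Locate the source by the FWHM midpoint
#'
#' Finds the global maximum of a peaked profile, locates the half-maximum
#' crossing on each flank by linear interpolation between the bracketing
#' samples, and reports the midpoint of the two crossings — the conventional
#' sub-pixel source-position estimator.
#'
#' @param prof A [profile()] with a dominant peak.
#' @param min_snr Required peak height in units of the background spread
#'   (median absolute deviation of the profile tails).
#' @return A `source_fix`: list with `position` (mm), `fwhm` (mm),
#'   `peak_value`, `intensity_at_midpoint`.
#' @export
locate_source <- function(prof, min_snr = 5) {
  v <- prof$values
  p <- prof$positions
  i_max <- which.max(v)
  peak <- v[i_max]
  tails <- v[p < p[i_max] - 20 | p > p[i_max] + 20]
  noise <- if (length(tails) > 10) stats::mad(tails) else 0
  if (noise > 0 && peak < min_snr * noise) {
    stop("no source detected: peak below ", min_snr, " x background spread")
  }
  half <- peak / 2
  # left flank: last sample below half before the peak
  left_idx <- which(v[seq_len(i_max)] < half)
  if (length(left_idx) == 0) stop("left flank never crosses half-maximum")
  l <- max(left_idx)
  x_left <- p[l] + (half - v[l]) / (v[l + 1] - v[l]) * (p[l + 1] - p[l])
  # right flank: first sample below half after the peak
  right_idx <- which(v[i_max:length(v)] < half)
  if (length(right_idx) == 0) stop("right flank never crosses half-maximum")
  r <- i_max + min(right_idx) - 1
  x_right <- p[r - 1] +
    (half - v[r - 1]) / (v[r] - v[r - 1]) * (p[r] - p[r - 1])
  pos <- (x_left + x_right) / 2
  structure(list(position = pos, fwhm = x_right - x_left, peak_value = peak,
                 intensity_at_midpoint = profile_value_at(prof, pos)),
            class = "source_fix")
}

#' Distance between two located dwell positions
#'
#' @param fix1,fix2 `source_fix` objects from separately exposed single-dwell
#'   images.
#' @return Interval in mm (symmetric in argument order).
#' @export
measure_interval <- function(fix1, fix2) {
  abs(fix2$position - fix1$position)
}

#' Spatial resolution of repeated position measurements
#'
#' @param fixes List of `source_fix`es of the same preset position.
#' @return Sample standard deviation (n - 1) of the positions, mm.
#' @export
position_resolution <- function(fixes) {
  if (length(fixes) < 2) stop("need at least 2 repeated fixes")
  stats::sd(vapply(fixes, function(f) f$position, numeric(1)))
}

#' Source strength as light intensity at the FWHM midpoint
#'
#' @param prof A [profile()].
#' @param fix A `source_fix` for the same profile.
#' @return Interpolated intensity at the midpoint position.
#' @export
source_strength <- function(prof, fix) {
  v <- profile_value_at(prof, fix$position)
  if (is.na(v)) stop("fix position lies outside the profile")
  v
}

#' Fit a half-life to a strength series
#'
#' Least-squares fit of \eqn{I(t) = I_0 2^{-t/T}}. The default is log-linear
#' ordinary least squares (variance-stabilising for multiplicative noise); a
#' nonlinear fit on the original scale is available.
#'
#' @param days Measurement days.
#' @param strengths Positive intensities.
#' @param method `"loglinear"` (default) or `"nls"`.
#' @return List with `half_life` (days), `se` (standard error, days), `i0`.
#' @export
fit_half_life <- function(days, strengths, method = c("loglinear", "nls")) {
  method <- match.arg(method)
  if (length(days) < 3) stop("need at least 3 time points")
  if (any(strengths <= 0)) stop("strengths must be positive for the decay fit")
  if (method == "loglinear") {
    fit <- stats::lm(log(strengths) ~ days)
    b <- stats::coef(fit)[2]
    if (b >= -1e-12) {
      warning("no decay detected: non-negative slope")
      return(list(half_life = Inf, se = NA_real_,
                  i0 = exp(stats::coef(fit)[1])))
    }
    # summary.lm warns on numerically perfect fits; harmless here
    se_b <- suppressWarnings(summary(fit)$coefficients[2, 2])
    t_half <- -log(2) / b
    list(half_life = unname(t_half),
         se = unname(log(2) * se_b / b^2),  # delta method
         i0 = unname(exp(stats::coef(fit)[1])))
  } else {
    start <- list(i0 = max(strengths), th = (max(days) - min(days)) / 2 + 1)
    # scaleOffset keeps the relative-offset criterion defined on
    # zero-residual (noiseless) series
    fit <- stats::nls(strengths ~ i0 * 2^(-days / th), start = start,
                      control = stats::nls.control(maxiter = 100,
                                                   scaleOffset = 1))
    cf <- summary(fit)$coefficients
    list(half_life = unname(cf["th", "Estimate"]),
         se = unname(cf["th", "Std. Error"]),
         i0 = unname(cf["i0", "Estimate"]))
  }
}

#' Dose-rate independence of the light intensity
#'
#' Same delivered dose measured at different dose rates (source strengths):
#' reports the maximum deviation of any group mean from the grand mean.
#'
#' @param strengths_by_rate Named list of intensity vectors, one per dose
#'   rate.
#' @return Maximum absolute percent deviation from the grand mean.
#' @export
dose_rate_independence <- function(strengths_by_rate) {
  if (length(strengths_by_rate) < 2) stop("need at least 2 dose-rate groups")
  grand <- mean(unlist(strengths_by_rate))
  means <- vapply(strengths_by_rate, mean, numeric(1))
  max(abs(means / grand - 1)) * 100
}

#' Repeatability of repeated intensity readings
#'
#' Percent coefficient of variation, `100 x sd / mean`, per dose level.
#'
#' @param intensities_by_dose Named list of repeated readings per dose.
#' @return Named numeric vector of percent repeatability.
#' @export
repeatability <- function(intensities_by_dose) {
  vapply(intensities_by_dose, function(v) {
    if (length(v) < 2) stop("need at least 2 repeats per dose")
    m <- mean(v)
    if (m == 0) stop("zero mean intensity")
    100 * stats::sd(v) / m
  }, numeric(1))
}

#' Compare a measured profile with a reference dose profile
#'
#' Resamples the reference onto the measured positions by linear
#' interpolation and reports per-point percent differences (reference in the
#' denominator) over the radial region, pooling both sides of the peak.
#'
#' @param measured,reference [profile()]s on consistent scales (both Gy or
#'   both normalised at the same point).
#' @param region Two-element radial interval `(r_min, r_max)` in mm.
#' @return An `agreement_stats`: `region`, `mean_abs_pct_diff`,
#'   `max_abs_pct_diff`, `diffs` (per-point, signed), `positions`.
#' @export
compare_profiles <- function(measured, reference, region = c(7, 30)) {
  if (region[1] >= region[2]) stop("region must satisfy r_min < r_max")
  sel <- abs(measured$positions) > region[1] &
    abs(measured$positions) < region[2]
  pos <- measured$positions[sel]
  if (length(pos) == 0) stop("profiles have no support in the region")
  ref <- stats::approx(reference$positions, reference$values,
                       xout = pos, rule = 1)$y
  if (any(is.na(ref))) stop("reference does not cover the comparison region")
  if (any(ref == 0)) stop("reference is zero inside the comparison region")
  diffs <- 100 * (measured$values[sel] - ref) / ref
  structure(list(region = region,
                 mean_abs_pct_diff = mean(abs(diffs)),
                 max_abs_pct_diff = max(abs(diffs)),
                 diffs = diffs, positions = pos),
            class = "agreement_stats")
}

#' @export
print.agreement_stats <- function(x, ...) {
  cat(sprintf("<agreement %g-%g mm: mean |%%diff| = %.2f%%, max = %.2f%%>\n",
              x$region[1], x$region[2], x$mean_abs_pct_diff,
              x$max_abs_pct_diff))
  invisible(x)
}
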