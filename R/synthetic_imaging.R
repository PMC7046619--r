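# Synthetic camera-image generator: renders dwell sequences into 16-bit
# greyscale images with the statistical structure the analysis assumes —
# emission proportional to dose projected through a 100-mm water slab,
# optional catheter light, background offset, Poisson shot noise.

#' Construct a camera model
#'
#' Defaults mirror the QA camera: 772 x 580 pixels at 0.17 mm/pixel, 16-bit.
#' The gain is counts per unit projected emission (Gy x slices); its default
#' puts the peak of a 6-Gy reference-dose single dwell near 3e4 counts, using
#' most of the 16-bit dynamic range.
#'
#' @param width,height Sensor size in pixels.
#' @param pixel_pitch Image scale, mm per pixel.
#' @param gain Counts per unit projected emission.
#' @param offset Mean background level, counts.
#' @param read_noise_sd Gaussian read noise, counts.
#' @param psf_sigma Optical point-spread sigma, mm (0 = ideal optics).
#' @param seed Base RNG seed; per-image streams are derived from it.
#' @param bit_depth Bits per pixel (16).
#' @return A `camera_model` object.
#' @export
camera_model <- function(width = 772, height = 580, pixel_pitch = 0.17,
                         gain = 5.37, offset = 100, read_noise_sd = 2,
                         psf_sigma = 0, seed = 20200227L, bit_depth = 16) {
  if (pixel_pitch <= 0) stop("pixel_pitch must be positive (mm)")
  if (gain <= 0) stop("gain must be positive")
  if (offset < 0 || offset >= 2^bit_depth) stop("offset outside sensor range")
  structure(list(width = as.integer(width), height = as.integer(height),
                 pixel_pitch = pixel_pitch, gain = gain, offset = offset,
                 read_noise_sd = read_noise_sd, psf_sigma = psf_sigma,
                 seed = as.integer(seed), bit_depth = as.integer(bit_depth)),
            class = "camera_model")
}

# pixel-centre coordinates, mm, origin at the image centre
camera_axes <- function(camera) {
  list(x = (seq_len(camera$width) - (camera$width + 1) / 2) * camera$pixel_pitch,
       y = (seq_len(camera$height) - (camera$height + 1) / 2) * camera$pixel_pitch)
}

# run expr with a private RNG stream, restoring the caller's state
with_local_seed <- function(seed, expr) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_seed) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

# projected emission as a function of in-plane radius rho (mm): the TG-43
# point dose summed over 1-mm z-slices at half-integer offsets spanning the
# slab. Returns an interpolator built on a fine radial grid.
projected_radial_lookup <- function(spec, thickness = 100, slice = 1,
                                    rho_max = 170) {
  z <- seq(-(thickness - slice) / 2, (thickness - slice) / 2, by = slice)
  rho <- c(seq(0, 5, by = 0.02), seq(5.05, rho_max, by = 0.05))
  r <- sqrt(outer(rho^2, z^2, "+"))
  p <- rowSums(matrix(dose_rate_point(spec, r), nrow = length(rho)))
  stats::approxfun(rho, p, rule = 2)
}

#' Render the emission scene for a dwell sequence
#'
#' Produces the noiseless projected-emission components on the sensor grid.
#' The water component is the TG-43 dose field projected through a water slab
#' (default 100 mm at 1-mm slices), times the dwell time; the optional
#' catheter component is a coupling-factor-scaled copy of the water emission
#' confined to a stripe along the source-movement axis. Fidelity LEVEL A is
#' light proportional to dose; LEVEL B adds a near-source beta-excess term
#' blurred over the escaped-electron CSDA range.
#'
#' @param spec A [source_spec()].
#' @param dwells A [dwell_sequence()]; positions must lie inside the field of
#'   view.
#' @param camera A [camera_model()].
#' @param include_catheter Add the catheter-light component.
#' @param catheter_coupling Catheter light relative to water light at the same
#'   position. Uncovered catheters are typically observed about twice as
#'   bright as water; the factor mixes emission physics with optical coupling
#'   of the catheter, so it is configuration rather than prediction.
#' @param catheter_halfwidth Stripe half-width, mm.
#' @param level Fidelity level, `"A"` (light proportional to dose, default) or
#'   `"B"` (adds the beta/near-source excess).
#' @param beta_excess LEVEL B only: beta light as a fraction of total water
#'   light, concentrated near the source.
#' @param thickness Projection slab thickness, mm.
#' @return A `scene_components` list: `water_emission`, `catheter_emission`
#'   (height x width matrices, Gy x slices units), `include_catheter`,
#'   `pixel_pitch`, `dwells`.
#' @export
render_emission <- function(spec, dwells, camera = camera_model(),
                            include_catheter = FALSE,
                            catheter_coupling = 2.0,
                            catheter_halfwidth = 1.0,
                            level = c("A", "B"),
                            beta_excess = 0.05,
                            thickness = 100) {
  level <- match.arg(level)
  ax <- camera_axes(camera)
  if (any(dwells$position < min(ax$x) | dwells$position > max(ax$x))) {
    stop("dwell position outside the camera field of view")
  }
  lookup <- projected_radial_lookup(spec, thickness = thickness)
  water <- matrix(0, nrow = camera$height, ncol = camera$width)
  y2 <- ax$y^2
  for (i in seq_len(nrow(dwells))) {
    dx2 <- (ax$x - dwells$position[i])^2
    rho <- sqrt(outer(y2, dx2, "+"))
    water <- water +
      matrix(lookup(rho), nrow = camera$height) * (dwells$time[i] / 60)
  }
  if (level == "B") {
    # escaped-beta near-source excess, Gaussian over the CSDA range of the
    # beta endpoint; amplitude a configurable fraction of the water light
    r_beta <- csda_range(spec$beta_endpoint, water_medium())
    excess <- matrix(0, nrow = camera$height, ncol = camera$width)
    for (i in seq_len(nrow(dwells))) {
      dx2 <- (ax$x - dwells$position[i])^2
      rho2 <- outer(y2, dx2, "+")
      kern <- exp(-rho2 / (2 * r_beta^2))
      excess <- excess + kern / sum(kern) * (dwells$time[i] / 60)
    }
    water <- water + beta_excess * sum(water) * excess / sum(excess * 1)
  }
  catheter <- matrix(0, nrow = camera$height, ncol = camera$width)
  if (include_catheter) {
    stripe <- abs(ax$y) < catheter_halfwidth
    catheter[stripe, ] <- catheter_coupling * water[stripe, ]
  }
  structure(list(water_emission = water, catheter_emission = catheter,
                 include_catheter = include_catheter,
                 pixel_pitch = camera$pixel_pitch, dwells = dwells),
            class = "scene_components")
}

# separable Gaussian blur, reflection padding; sigma in mm
gaussian_blur <- function(m, sigma_mm, pixel_pitch) {
  sigma <- sigma_mm / pixel_pitch
  if (sigma <= 0) return(m)
  half <- max(1L, ceiling(3 * sigma))
  k <- stats::dnorm(-half:half, sd = sigma)
  k <- k / sum(k)
  conv1 <- function(v) {
    n <- length(v)
    padded <- c(v[half:1], v, v[n:(n - half + 1)])
    stats::filter(padded, k, sides = 2)[(half + 1):(half + n)]
  }
  m <- apply(m, 2, conv1)
  t(apply(m, 1, conv1))
}

#' Expose a scene to the camera
#'
#' Converts projected emission to sensor counts:
#' `clip(round(Poisson(gain x emission x exposure) + offset + read noise),
#' 0, 2^16 - 1)`. With `noise = FALSE` the expectation
#' `gain x emission x exposure + offset` is returned unrounded (signed
#' intermediate convention; quantisation happens on TIFF export). A Gaussian
#' PSF of `psf_sigma` is applied to the emission before sampling when set.
#'
#' @param scene A `scene_components` from [render_emission()].
#' @param camera A [camera_model()].
#' @param exposure Relative exposure factor (1 = the rendered dwell times).
#' @param noise Draw Poisson + read noise (default) or return the noiseless
#'   expectation.
#' @param seed RNG seed for this image; defaults to the camera's base seed.
#' @return A `light_image`: counts matrix with `pixel_pitch` and `metadata`
#'   attributes (dwells, exposure, seed, saturation flag).
#' @export
expose <- function(scene, camera = camera_model(), exposure = 1,
                   noise = TRUE, seed = camera$seed) {
  if (exposure <= 0) stop("exposure must be positive")
  emission <- scene$water_emission + scene$catheter_emission
  if (camera$psf_sigma > 0) {
    emission <- gaussian_blur(emission, camera$psf_sigma, camera$pixel_pitch)
  }
  lambda <- camera$gain * emission * exposure
  maxc <- 2^camera$bit_depth - 1
  if (noise) {
    counts <- with_local_seed(seed, {
      n <- length(lambda)
      matrix(stats::rpois(n, lambda) +
               stats::rnorm(n, sd = camera$read_noise_sd),
             nrow = nrow(lambda)) + camera$offset
    })
    counts <- pmin(pmax(round(counts), 0), maxc)
  } else {
    counts <- lambda + camera$offset
  }
  saturated <- mean(counts >= maxc) > 0.01
  if (saturated) warning("more than 1% of pixels saturated")
  light_image(counts, camera$pixel_pitch,
              metadata = list(dwells = scene$dwells, exposure = exposure,
                              seed = seed, noise = noise,
                              saturated = saturated))
}

#' Construct a light image
#'
#' @param counts Height x width matrix of pixel values.
#' @param pixel_pitch mm per pixel.
#' @param metadata List of acquisition metadata.
#' @return A `light_image` (matrix with attributes).
#' @export
light_image <- function(counts, pixel_pitch, metadata = list()) {
  structure(counts, pixel_pitch = pixel_pitch, metadata = metadata,
            class = c("light_image", "matrix", "array"))
}

#' @export
print.light_image <- function(x, ...) {
  cat(sprintf("<light_image %d x %d px, %.2f mm/px, range [%.0f, %.0f]>\n",
              ncol(x), nrow(x), attr(x, "pixel_pitch"), min(x), max(x)))
  invisible(x)
}

#' Background (no-irradiation) image
#'
#' Exposes an all-zero scene: offset plus read noise only.
#'
#' @inheritParams expose
#' @param camera A [camera_model()].
#' @return A `light_image`.
#' @export
background_image <- function(camera = camera_model(), exposure = 1,
                             noise = TRUE, seed = camera$seed + 1L) {
  zero <- matrix(0, nrow = camera$height, ncol = camera$width)
  scene <- structure(list(water_emission = zero, catheter_emission = zero,
                          include_catheter = FALSE,
                          pixel_pitch = camera$pixel_pitch,
                          dwells = NULL),
                     class = "scene_components")
  expose(scene, camera, exposure = exposure, noise = noise, seed = seed)
}

#' Write / read a 16-bit greyscale TIFF with JSON sidecar
#'
#' Writes baseline uncompressed 16-bit greyscale TIFF; the pixel pitch and
#' acquisition metadata travel in a `<path>.json` sidecar. Counts are rounded
#' and clipped to [0, 65535] on export.
#'
#' @param image A `light_image`.
#' @param path Output TIFF path.
#' @return `path`, invisibly.
#' @export
write_tiff <- function(image, path) {
  counts <- pmin(pmax(round(unclass(image)), 0), 65535)
  tiff::writeTIFF(counts / 65535, path, bits.per.sample = 16,
                  compression = "none")
  meta <- attr(image, "metadata")
  sidecar <- list(pixel_pitch_mm = attr(image, "pixel_pitch"),
                  width = ncol(image), height = nrow(image),
                  exposure = meta$exposure, seed = meta$seed,
                  dwell_positions_mm = meta$dwells$position,
                  dwell_times_s = meta$dwells$time)
  jsonlite::write_json(sidecar, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA, null = "null")
  invisible(path)
}

#' @rdname write_tiff
#' @param default_pitch Pixel pitch to assume when no sidecar exists, mm.
#' @return `read_tiff`: a `light_image` with integer counts.
#' @export
read_tiff <- function(path, default_pitch = 0.17) {
  raw <- tiff::readTIFF(path, as.is = TRUE, info = TRUE, all = FALSE)
  bps <- attr(raw, "bits.per.sample")
  if (!is.null(bps) && bps != 16) {
    stop("expected a 16-bit greyscale TIFF, got ", bps, " bits per sample")
  }
  if (length(dim(raw)) == 3 && dim(raw)[3] > 1) {
    stop("expected a single-channel greyscale TIFF, got ",
         dim(raw)[3], " channels")
  }
  if (length(dim(raw)) == 3) raw <- raw[, , 1]
  sidecar_path <- paste0(path, ".json")
  pitch <- default_pitch
  meta <- list()
  if (file.exists(sidecar_path)) {
    sc <- jsonlite::read_json(sidecar_path, simplifyVector = TRUE)
    pitch <- sc$pixel_pitch_mm
    meta <- sc
  }
  light_image(matrix(as.numeric(raw), nrow = nrow(raw)), pitch, meta)
}

#' Simulate a source-strength decay series
#'
#' Renders the same dwell on a sequence of calendar days, scaling the emission
#' by the radioactive decay factor; each image gets an independent noise
#' stream derived from the camera seed.
#'
#' @param spec A [source_spec()].
#' @param camera A [camera_model()].
#' @param days Ascending day indices since the strength date.
#' @param dwell_time Dwell time in seconds (the protocol uses a fixed time so
#'   the light tracks source strength).
#' @param position Dwell position, mm.
#' @param noise Passed to [expose()].
#' @return List of `light_image`s, one per day.
#' @export
decay_series <- function(spec, camera = camera_model(), days,
                         dwell_time = 240, position = 0, noise = TRUE) {
  if (length(days) == 0) return(list())
  if (is.unsorted(days)) stop("days must be sorted ascending")
  scene <- render_emission(spec, dwell_sequence(position, dwell_time), camera)
  lapply(seq_along(days), function(i) {
    s <- scene
    f <- decay_factor(spec, days[i])
    s$water_emission <- s$water_emission * f
    s$catheter_emission <- s$catheter_emission * f
    expose(s, camera, noise = noise, seed = camera$seed + 1000L + i)
  })
}
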