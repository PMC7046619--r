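# Shared fixtures: an idealised point source (g = 1, phi_an = 1) whose dose
# field is exactly inverse-square, and a small camera that keeps image tests
# fast while preserving the 0.17 mm/px scale.

toy_source <- function(s_k = 32800, lines = NULL) {
  if (is.null(lines)) {
    lines <- list(gamma_line(316.51, 0.83), gamma_line(468.07, 0.48),
                  gamma_line(612.46, 0.053))
  }
  source_spec("toy-point", half_life = 73.83, air_kerma_strength = s_k,
              dose_rate_constant = 1.109, radial_dose_coeffs = c(1),
              anisotropy = 1, lines = lines)
}

small_camera <- function(...) {
  camera_model(width = 240, height = 240, ...)
}

# noiseless analysed parallel profile for a single dwell on a small camera
small_dwell_profile <- function(spec, position = 0, dose = 6,
                                camera = small_camera(), noise = FALSE,
                                seed = camera$seed) {
  dw <- dwell_sequence(position, dwell_time_for_dose(spec, dose))
  sc <- render_emission(spec, dw, camera)
  img <- expose(sc, camera, noise = noise, seed = seed)
  bg <- background_image(camera, noise = noise, seed = seed + 1L)
  filt <- median_filter(subtract_background(img, bg), 2)
  extract_profile(filt, "parallel", through = 0)
}
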