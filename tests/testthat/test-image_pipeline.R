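test_that("background subtraction is signed and unbiased", {
  cam <- small_camera()
  a <- background_image(cam, seed = 1)
  b <- background_image(cam, seed = 2)
  expect_true(all(subtract_background(a, a) == 0))
  c100 <- light_image(matrix(200, 10, 10), 0.17)
  c200 <- light_image(matrix(100, 10, 10), 0.17)
  expect_true(all(subtract_background(c100, c200) == 100))
  diffm <- subtract_background(a, b)
  expect_true(any(diffm < 0))  # negatives preserved
  se <- sd(diffm) / sqrt(length(diffm))
  expect_lt(abs(mean(diffm)), 3 * se)
  expect_error(subtract_background(a, c100), "dimensions")
})

test_that("disc median filter matches the brute-force oracle exactly", {
  set.seed(42)
  m <- matrix(sample(0:1000, 400, replace = TRUE), 20, 20)
  filt <- median_filter(m, 2)
  # oracle: per-pixel sorted neighbourhood over the radius-2 disc with
  # reflection padding, written independently of the vectorised path
  oracle <- m
  for (i in 1:20) for (j in 1:20) {
    vals <- c()
    for (dy in -2:2) for (dx in -2:2) {
      if (dx^2 + dy^2 > 4) next
      ii <- i + dy; jj <- j + dx
      if (ii < 1) ii <- 2 - ii
      if (ii > 20) ii <- 2 * 20 - ii
      if (jj < 1) jj <- 2 - jj
      if (jj > 20) jj <- 2 * 20 - jj
      vals <- c(vals, m[ii, jj])
    }
    oracle[i, j] <- median(vals)
  }
  expect_equal(dim(filt), dim(oracle))
  expect_true(all(filt == oracle))
})

test_that("median filter preserves constants and removes impulses", {
  const <- matrix(7, 15, 15)
  expect_identical(median_filter(const, 2), const)
  imp <- matrix(0, 15, 15); imp[8, 8] <- 1e6
  expect_true(all(median_filter(imp, 2) == 0))
  expect_identical(median_filter(imp, 0), imp)
  expect_error(median_filter(imp, -1), "non-negative")
  # the radius-2 disc holds 13 pixels
  expect_equal(nrow(cherenkovqa:::disc_offsets(2)), 13)
})

test_that("profile extraction: geometry, spacing, symmetry", {
  cam <- small_camera()
  const <- light_image(matrix(5, cam$height, cam$width), cam$pixel_pitch)
  p <- extract_profile(const, "parallel", through = 0)
  expect_true(all(p$values == 5))
  expect_equal(unique(round(diff(p$positions), 10)), 0.17)
  expect_equal(length(p$positions), cam$width)
  # perpendicular profile of a noiseless on-axis dwell is symmetric
  spec <- toy_source()
  sc <- render_emission(spec, dwell_sequence(0, 60), cam)
  img <- expose(sc, cam, noise = FALSE)
  pp <- extract_profile(img, "perpendicular", through = 0)
  half <- length(pp$values) %/% 2
  expect_equal(pp$values[1:half], rev(pp$values)[1:half], tolerance = 1e-9)
  expect_error(extract_profile(const, "parallel", through = 1e4),
               "outside")
  # width_px > 1 averages adjacent lines: rows vary 1..10, so a 3-row
  # average centred on row 5 gives 5 everywhere
  m <- matrix(rep(1:10, times = 10), 10, 10)
  img2 <- light_image(m, 1)
  p1 <- extract_profile(img2, "parallel", through = 0, width_px = 3)
  expect_true(all(p1$values == 5))
})

test_that("dose linearity fit recovers exact lines and validates input", {
  d <- c(0.3, 1, 3, 10, 20)
  cal <- fit_linearity(d, 5 * d + 2)
  expect_equal(cal$slope, 5, tolerance = 1e-12)
  expect_equal(cal$intercept, 2, tolerance = 1e-12)
  expect_equal(cal$fit_r2, 1.0, tolerance = 1e-12)
  expect_error(fit_linearity(c(1, 2), c(1, 2)), "3 dose levels")
  expect_error(fit_linearity(c(1, 1, 1), c(1, 2, 3)), "variance")
})

test_that("noiseless synthetic dose series is linear by construction", {
  spec <- toy_source()
  cam <- small_camera()
  doses <- c(0.3, 1, 3, 6, 12, 20)
  base <- render_emission(spec,
                          dwell_sequence(0, dwell_time_for_dose(spec, 6)),
                          cam)
  ints <- vapply(doses, function(d) {
    s <- base
    s$water_emission <- s$water_emission * d / 6
    img <- expose(s, cam, noise = FALSE)
    bg <- background_image(cam, noise = FALSE)
    prof <- extract_profile(subtract_background(img, bg), "perpendicular",
                            through = 0)
    cherenkovqa:::profile_value_at(prof, 10)
  }, numeric(1))
  cal <- fit_linearity(doses, ints)
  expect_gt(cal$fit_r2, 0.9999)
  expect_gt(cal$slope, 0)
})

test_that("calibration divides by the slope and round-trips", {
  p <- profile(1:20, rep(4, 20))
  cal <- structure(list(slope = 2, intercept = 0, r_ref = 10, fit_r2 = 1),
                   class = "calibration_factor")
  pg <- calibrate_profile(p, cal)
  expect_true(all(pg$values == 2))
  expect_equal(pg$units, "Gy")
  expect_equal(pg$values * cal$slope + cal$intercept, p$values,
               tolerance = 1e-12)
  cal$slope <- -1
  expect_error(calibrate_profile(p, cal), "positive")
})

test_that("normalisation pins r = 10 mm to 1 and is idempotent, scale-free", {
  pos <- seq(-30, 30, by = 0.17)
  p <- profile(pos, 1000 / (abs(pos) + 1))
  n1 <- normalise_profile(p)
  expect_equal(cherenkovqa:::profile_value_at(n1, 10), 1.0, tolerance = 1e-12)
  n2 <- normalise_profile(n1)
  expect_equal(n2$values, n1$values, tolerance = 1e-12)
  p7 <- profile(pos, 7000 / (abs(pos) + 1))
  expect_equal(normalise_profile(p7)$values, n1$values, tolerance = 1e-12)
  short <- profile(seq(0, 5, 0.17), seq(1, 2, length.out = 30))
  expect_error(normalise_profile(short), "cover")
})

test_that("pipeline is linear in the signal on smooth fields", {
  spec <- toy_source()
  cam <- small_camera()
  base <- render_emission(spec,
                          dwell_sequence(0, dwell_time_for_dose(spec, 6)),
                          cam)
  run <- function(alpha) {
    s <- base
    s$water_emission <- s$water_emission * alpha
    img <- expose(s, cam, noise = FALSE)
    bg <- background_image(cam, noise = FALSE)
    filt <- median_filter(subtract_background(img, bg), 2)
    extract_profile(filt, "perpendicular", through = 0)$values
  }
  v1 <- run(1)
  keep <- abs(v1) > 1  # avoid 0/0 far in the tails
  for (alpha in c(0.5, 2)) {
    va <- run(alpha)
    expect_lt(max(abs(va[keep] / v1[keep] - alpha) / alpha), 0.005)
  }
})

test_that("profile CSV export writes a labelled two-column table", {
  p <- profile(seq(-2, 2, 0.17)[1:20], 1:20, axis = "parallel")
  path <- tempfile(fileext = ".csv")
  write_profile_csv(p, path, slope = 123.4)
  lines <- readLines(path)
  expect_match(lines[1], "axis=parallel")
  expect_match(lines[1], "123.4")
  df <- read.csv(path, comment.char = "#")
  expect_equal(df$value, 1:20)
  unlink(path)
})
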