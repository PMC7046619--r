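triangle_profile <- function(centre = 0, height = 100, halfwidth = 5,
                             span = 30, pitch = 0.17) {
  # grid chosen so 0 (and 20-px multiples) fall exactly on a sample
  pos <- (-round(span / pitch):round(span / pitch)) * pitch
  vals <- pmax(0, height * (1 - abs(pos - centre) / halfwidth))
  profile(pos, vals, axis = "parallel")
}

test_that("FWHM-midpoint localization is exact on symmetric peaks", {
  fix <- locate_source(triangle_profile(0))
  expect_equal(fix$position, 0, tolerance = 1e-9)
  expect_equal(fix$fwhm, 5, tolerance = 1e-9)
  # translation equivariance: +3.4 mm = 20 px
  fix2 <- locate_source(triangle_profile(3.4))
  expect_equal(fix2$position, 3.4, tolerance = 1e-9)
  # reflection antisymmetry
  p <- triangle_profile(2.3)
  refl <- profile(rev(-p$positions), rev(p$values), axis = "parallel")
  expect_equal(locate_source(refl)$position, -2.3, tolerance = 1e-9)
  expect_error(locate_source(profile(seq(-30, 30, 0.17),
                                     rep(1, length(seq(-30, 30, 0.17))))),
               "half-maximum")
})

test_that("localization stays translation-equivariant on synthetic images", {
  spec <- toy_source()
  cam <- small_camera()
  for (preset in c(-5, 0, 5.1)) {
    prof <- small_dwell_profile(spec, position = preset, camera = cam)
    fix <- locate_source(prof)
    expect_lt(abs(fix$position - preset), 0.01)
  }
})

test_that("intervals difference positions symmetrically", {
  f1 <- locate_source(triangle_profile(-20))
  f2 <- locate_source(triangle_profile(20))
  expect_equal(measure_interval(f1, f2), 40, tolerance = 1e-9)
  expect_equal(measure_interval(f2, f1), measure_interval(f1, f2))
  g1 <- locate_source(triangle_profile(-1.25))
  g2 <- locate_source(triangle_profile(1.25))
  expect_equal(measure_interval(g1, g2), 2.5, tolerance = 1e-9)
})

test_that("position resolution is the n-1 standard deviation", {
  f <- function(p) list(position = p)
  expect_equal(position_resolution(list(f(0), f(0))), 0)
  expect_equal(position_resolution(list(f(0), f(0.2))), 0.1414, tolerance = 1e-3)
  expect_error(position_resolution(list(f(1))), "at least 2")
})

test_that("source strength reads the midpoint intensity and scales", {
  p <- triangle_profile(0)
  fix <- locate_source(p)
  expect_equal(source_strength(p, fix), 100, tolerance = 1e-9)
  p2 <- profile(p$positions, 2 * p$values, axis = "parallel")
  expect_equal(source_strength(p2, locate_source(p2)), 200, tolerance = 1e-9)
  far <- list(position = 1e4)
  expect_error(source_strength(p, far), "outside")
})

test_that("half-life fit recovers exact series and flags non-decay", {
  days <- seq(0, 180, by = 15)
  s <- 1000 * 2^(-days / 73.83)
  fit <- fit_half_life(days, s)
  expect_equal(fit$half_life, 73.83, tolerance = 1e-6)
  # two-half-life construction
  fit2 <- fit_half_life(c(0, 73.83, 147.66), c(1, 0.5, 0.25))
  expect_equal(fit2$half_life, 73.83, tolerance = 1e-6)
  expect_warning(out <- fit_half_life(days, rep(5, length(days))),
                 "no decay")
  expect_identical(out$half_life, Inf)
  expect_error(fit_half_life(days, c(-1, s[-1])), "positive")
  # nonlinear route agrees on clean data
  fit3 <- fit_half_life(days, s, method = "nls")
  expect_equal(fit3$half_life, 73.83, tolerance = 1e-4)
})

test_that("half-life fit has small bias under multiplicative noise", {
  days <- seq(0, 165, by = 15)  # 12 time points
  set.seed(101)
  est <- replicate(200, {
    s <- 1000 * 2^(-days / 73.83) * exp(rnorm(length(days), sd = 0.05))
    fit_half_life(days, s)$half_life
  })
  expect_lt(abs(mean(est) / 73.83 - 1), 0.005)
})

test_that("dose-rate independence measures group deviations", {
  expect_equal(dose_rate_independence(list(a = c(1, 1), b = c(1, 1))), 0)
  expect_equal(dose_rate_independence(list(a = 99, b = 101)), 1,
               tolerance = 1e-9)
  expect_error(dose_rate_independence(list(a = 1)), "2 dose-rate groups")
})

test_that("same dose at different dose rates reads within the 3% tolerance", {
  # same 10-Gy delivery with dwell times spanning 91-206 s, i.e. different
  # source strengths; intensity should not depend on the rate
  cam <- small_camera()
  base_spec <- toy_source()
  t10 <- dwell_time_for_dose(base_spec, 10)
  groups <- lapply(seq_along(c(91, 140, 206)), function(i) {
    t_dwell <- c(91, 140, 206)[i]
    spec_i <- toy_source(s_k = 32800 * t10 / t_dwell)
    scene <- render_emission(spec_i, dwell_sequence(0, t_dwell), cam)
    vapply(1:2, function(k) {
      cherenkovqa:::intensity_at_ref(scene, cam, seed = 70L * i + k)
    }, numeric(1))
  })
  names(groups) <- paste0("rate", 1:3)
  expect_lt(dose_rate_independence(groups), 3)
})

test_that("repeatability is the percent coefficient of variation", {
  expect_equal(unname(repeatability(list(d = c(5, 5, 5)))), 0)
  expect_equal(unname(repeatability(list(d = c(98, 102, 100, 100)))), 1.63,
               tolerance = 0.005)
  expect_error(repeatability(list(d = 5)), "2 repeats")
  expect_error(repeatability(list(d = c(-1, 1))), "zero mean")
})

test_that("profile comparison: identity, scaling, rescale invariance", {
  pos <- seq(-35, 35, by = 0.17)
  ref <- profile(pos, 1000 / (abs(pos) + 1)^1.5)
  st <- compare_profiles(ref, ref)
  expect_equal(st$mean_abs_pct_diff, 0)
  expect_equal(st$max_abs_pct_diff, 0)
  m5 <- profile(pos, 1.05 * ref$values)
  st5 <- compare_profiles(m5, ref)
  expect_equal(st5$mean_abs_pct_diff, 5, tolerance = 1e-9)
  # common rescaling of both leaves the stats unchanged
  m <- profile(pos, ref$values * (1 + 0.03 * sin(pos)))
  a <- compare_profiles(m, ref)
  b <- compare_profiles(profile(pos, 7 * m$values),
                        profile(pos, 7 * ref$values))
  expect_equal(a$mean_abs_pct_diff, b$mean_abs_pct_diff, tolerance = 1e-12)
  expect_true(a$mean_abs_pct_diff <= a$max_abs_pct_diff)
  expect_error(compare_profiles(m, ref, region = c(30, 7)), "r_min < r_max")
  short <- profile(seq(0, 5, 0.17), rep(1, 30))
  expect_error(compare_profiles(short, ref), "no support")
})

test_that("metrics are pure functions of their inputs", {
  p <- triangle_profile(1.7)
  expect_identical(locate_source(p), locate_source(p))
  days <- seq(0, 90, 15); s <- 2^(-days / 70)
  expect_identical(fit_half_life(days, s), fit_half_life(days, s))
})
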