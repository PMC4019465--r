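test_that("landmarks fall at the widest point and the arc-farthest station", {
  # cone: OA at the wide end, tail at the apex
  cone <- profile_from(seq(0, 600, 10), seq(0, 600, 10) / 5)
  lm <- locate_landmarks(cone)
  expect_equal(lm$oa_index, nrow(cone$stations))
  expect_equal(lm$tail_index, 1L)

  # wineglass with its maximum at x = 0.97
  s <- seq(0, 100, 1)
  w <- 120 * exp(-((s / 100 - 0.97) / 0.1)^2)
  wg <- profile_from(s, w)
  lm2 <- locate_landmarks(wg)
  expect_equal(wg$stations$x[lm2$oa_index], 0.97)
  expect_equal(lm2$tail_index, 1L)

  # constant profile: endpoints selected
  cyl <- profile_from(seq(0, 100, 10), rep(40, 11))
  lm3 <- locate_landmarks(cyl)
  expect_setequal(c(lm3$oa_index, lm3$tail_index), c(1L, 11L))
})

test_that("shape factor reproduces closed-form station profiles", {
  x <- seq(0, 1, 0.01)
  # w = x^2: trapezoidal integral 1/3 against right-trapezoid 1/2
  sf2 <- compute_shape_factor(profile_from(x * 600, 120 * x^2, L = 600))
  expect_equal(sf2$shape_factor, 2 / 3, tolerance = 1e-3)
  # w = sqrt(x): 2/3 over 1/2, a convex bulge above 1
  sfr <- compute_shape_factor(profile_from(x * 600, 120 * sqrt(x), L = 600))
  expect_equal(sfr$shape_factor, 4 / 3, tolerance = 2e-3)
  # linear and constant profiles are exactly 1
  expect_equal(compute_shape_factor(profile_from(x * 600, 120 * x,
                                                 L = 600))$shape_factor, 1)
  expect_equal(compute_shape_factor(profile_from(x * 600, rep(80, length(x)),
                                                 L = 600))$shape_factor, 1)
})

test_that("the shape factor is invariant to using normalized arc positions", {
  x <- seq(0, 1, 0.01)
  w <- 120 * (0.15 + 0.85 * x^3)
  sf_px <- compute_shape_factor(profile_from(x * 600, w, L = 600))
  sf_norm <- compute_shape_factor(profile_from(x, w, L = 1))
  expect_equal(sf_px$shape_factor, sf_norm$shape_factor, tolerance = 1e-12)
})

test_that("degenerate profiles cannot form a shape factor", {
  expect_error(compute_shape_factor(profile_from(c(0, 10, 20), c(0, 0, 0))),
               "zero reference trapezoid")
  expect_error(locate_landmarks(profile_from(c(0, 10), c(1, 2))),
               "3 stations")
})

test_that("raster pipeline matches the analytic oracle across noise-free families", {
  # straight-sided limits through the full default pipeline
  expect_equal(sf_of(render_cell("cone", length_px = 600, max_width_px = 120)),
               1, tolerance = 0.02)
  expect_equal(sf_of(render_cell("cylinder", length_px = 600,
                                 max_width_px = 120)),
               1, tolerance = 0.02)
  # concave taper against the closed form, measured without denoising
  r <- render_cell("power_taper", 2, length_px = 600, max_width_px = 120)
  sf <- sf_of(r, smooth_rounds = 0)
  expect_lt(sf, 1)
  expect_equal(sf, 2 / 3, tolerance = 0.03)
})

test_that("pipeline shape factor decreases in the taper exponent", {
  sfs <- vapply(c(0.5, 1, 2, 3), function(p) {
    sf_of(render_cell("power_taper", p, length_px = 400, max_width_px = 80),
          smooth_rounds = 0)
  }, 0)
  expect_true(all(diff(sfs) < 0))
})

test_that("the sign of SF - 1 matches the curvature of the width profile", {
  # convex w (concave taper) stays at or below 1; concave w above 1
  concave_taper <- sf_of(render_cell("power_taper", 3, length_px = 400,
                                     max_width_px = 80), smooth_rounds = 0)
  expect_lte(concave_taper, 1 + 0.02)
  bulge <- sf_of(render_cell("bulge", length_px = 400, max_width_px = 80),
                 smooth_rounds = 0)
  expect_gte(bulge, 1 - 0.02)
})
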