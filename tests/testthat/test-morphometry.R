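test_that("trace_outline area conventions hold on squares and disks", {
  g <- matrix(FALSE, 20, 20); g[6:15, 6:15] <- TRUE # 10 x 10 square
  ct <- trace_outline(binary_mask(g))
  expect_gte(ct$area, 81)
  expect_lte(ct$area, 100)

  n <- 121; cx <- 61
  d <- outer(seq_len(n) - cx, seq_len(n) - cx, function(i, j) sqrt(i^2 + j^2))
  ct2 <- trace_outline(binary_mask(d <= 50))
  expect_equal(ct2$area, pi * 50^2, tolerance = 0.01)
})

test_that("trace_outline rejects degenerate or unclean masks", {
  g <- matrix(FALSE, 10, 10); g[5, 5] <- TRUE
  expect_error(trace_outline(binary_mask(g)), "degenerate|clean")
  g2 <- matrix(FALSE, 30, 30); g2[5:10, 5:10] <- TRUE; g2[20:25, 20:25] <- TRUE
  expect_error(trace_outline(binary_mask(g2)), "clean_mask")
})

test_that("midline of a straight capsule lies on its symmetry axis", {
  r <- render_cell("cylinder", length_px = 400, max_width_px = 60)
  m <- clean_mask(binarize(r$image))
  ml <- extract_midline(m)
  y_true <- mean(r$truth$midline_points$y)
  mid <- ml$curve[ml$curve$s > 30 & ml$curve$s < ml$L - 30, ]
  expect_lt(sqrt(mean((mid$y - y_true)^2)), 1)
  # length recovered within 5 percent after endpoint extension
  expect_lt(abs(ml$L - 400) / 400, 0.05)
})

test_that("midline follows a rotated axis", {
  r <- render_cell("cylinder", length_px = 400, max_width_px = 60,
                   rotation_deg = 30)
  m <- clean_mask(binarize(r$image))
  ml <- extract_midline(m)
  # distance from interior curve samples to the known axis line
  p0 <- c(r$truth$midline_points$x[1], r$truth$midline_points$y[1])
  u <- c(cos(30 * pi / 180), sin(30 * pi / 180))
  mid <- ml$curve[ml$curve$s > 40 & ml$curve$s < ml$L - 40, ]
  d <- (mid$x - p0[1]) * (-u[2]) + (mid$y - p0[2]) * u[1]
  expect_lt(sqrt(mean(d^2)), 1)
  expect_lt(abs(ml$L - 400) / 400, 0.05)
})

test_that("the longest skeleton limb pair wins over side branches", {
  g <- matrix(FALSE, 140, 260)
  g[60:80, 20:240] <- TRUE   # long bar
  g[80:125, 115:135] <- TRUE # shorter stem hanging off the middle
  m <- clean_mask(binary_mask(g))
  ml <- extract_midline(m, trace_outline(m))
  ends_x <- c(ml$curve$x[1], ml$curve$x[nrow(ml$curve)])
  ends_y <- c(ml$curve$y[1], ml$curve$y[nrow(ml$curve)])
  # both endpoints at the bar tips, not down the stem
  expect_true(all(abs(ends_y - 69) < 8))
  expect_lt(min(ends_x), 25)
  expect_gt(max(ends_x), 235)
})

test_that("extract_midline warns on low elongation", {
  g <- matrix(FALSE, 70, 80); g[10:54, 10:69] <- TRUE # ratio ~1.3
  expect_warning(extract_midline(clean_mask(binary_mask(g))), "elongation")
})

test_that("station layout follows the 10 px contract", {
  # midline of length 200 at step 10: 21 stations before end-cap drops
  ml <- straight_midline(200, x0 = 10, y0 = 30)
  ct <- rect_contour(5, 215, 9.5, 50.5)
  wp <- measure_widths(ml, ct, step_px = 10)
  expect_equal(nrow(wp$stations) + nrow(wp$dropped), 21)
  expect_equal(unique(round(diff(wp$stations$s))), 10)
  # rectangle chords: all interior stations report the full height
  expect_true(all(abs(wp$stations$w - 41) <= 1))
})

test_that("measured widths track ground truth along a cone", {
  r <- render_cell("cone", length_px = 600, max_width_px = 120)
  a <- analyze_cell(r$image, smooth_rounds = 0)
  st <- a$profile$stations
  w_true <- 120 * st$x
  keep <- st$x > 0.05 & st$x < 0.95
  fit <- stats::lm(st$w[keep] ~ w_true[keep])
  expect_gte(summary(fit)$r.squared, 0.99)
  expect_gt(coef(fit)[2], 0.95)
  expect_lt(coef(fit)[2], 1.05)
})

test_that("profiles are rotation-invariant and scale-covariant", {
  a0 <- analyze_cell(render_cell("wineglass", length_px = 400,
                                 max_width_px = 80)$image)
  a30 <- analyze_cell(render_cell("wineglass", length_px = 400,
                                  max_width_px = 80,
                                  rotation_deg = 30)$image)
  xi <- seq(0.1, 0.9, by = 0.05)
  w0 <- stats::approx(a0$profile$stations$x, a0$profile$stations$w, xi)$y
  w30 <- stats::approx(a30$profile$stations$x, a30$profile$stations$w, xi)$y
  expect_lt(max(abs(w0 - w30)), 2)

  a2x <- analyze_cell(render_cell("wineglass", length_px = 800,
                                  max_width_px = 160)$image)
  expect_equal(a2x$profile$L / a0$profile$L, 2, tolerance = 0.02)
  w2x <- stats::approx(a2x$profile$stations$x, a2x$profile$stations$w, xi)$y
  expect_lt(max(abs(w2x / 2 - w0) / w0), 0.05)
})

test_that("station points stay inside the outline", {
  r <- render_cell("wineglass", length_px = 300, max_width_px = 60)
  a <- analyze_cell(r$image)
  st <- a$profile$stations
  crv <- a$midline$curve
  s_ev <- pmin(pmax(st$s, 0.5), a$profile$L - 0.5)
  sx <- stats::approx(crv$s, crv$x, xout = s_ev)$y
  sy <- stats::approx(crv$s, crv$y, xout = s_ev)$y
  inside <- pracma::inpolygon(sx, sy, a$contour$points$x, a$contour$points$y)
  expect_true(all(inside))
})

test_that("normalize_profile orients the OA to the upper half and is idempotent", {
  # widest near s = 0: must be flipped
  wp <- profile_from(seq(0, 100, 10), seq(60, 5, length.out = 11),
                     oriented = FALSE)
  np <- normalize_profile(wp)
  expect_gt(np$stations$x[which.max(np$stations$w)], 0.5)
  expect_true(all(diff(np$stations$s) > 0))
  np2 <- normalize_profile(np)
  expect_equal(np2$stations, np$stations)

  # already oriented: unchanged
  wp2 <- profile_from(seq(0, 100, 10), seq(5, 60, length.out = 11),
                      oriented = FALSE)
  np3 <- normalize_profile(wp2)
  expect_equal(np3$stations$w, wp2$stations$w)

  # constant profile: idempotent under the tie rule
  wpc <- profile_from(seq(0, 100, 10), rep(40, 11), oriented = FALSE)
  npc <- normalize_profile(normalize_profile(wpc))
  expect_equal(npc$stations$w, rep(40, 11))
})

test_that("a gently curved cell measures like its straight counterpart", {
  straight <- analyze_cell(render_cell("wineglass", length_px = 400,
                                       max_width_px = 80)$image)
  curved <- analyze_cell(render_cell("wineglass", length_px = 400,
                                     max_width_px = 80,
                                     midline_curvature = 1 / 1400)$image)
  expect_lt(abs(curved$profile$L - straight$profile$L), 0.03 * 400)
  expect_lt(abs(curved$sf$shape_factor - straight$sf$shape_factor), 0.05)
})
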