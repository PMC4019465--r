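test_that("cell_spec validates its geometry", {
  prof <- make_radius_profile("cone")
  expect_error(cell_spec(prof, 100, 100), "smaller")
  expect_error(cell_spec(prof, 600, 120, midline_curvature = 0.01),
               "curvature")
  expect_error(noise_spec(boundary_jitter_px = -1))
  expect_error(noise_spec(speckle_rate = 1))
})

test_that("rendered silhouette area matches the swept-profile integral", {
  # cylinder: a 400 x 60 rectangle
  r <- render_cell("cylinder", length_px = 400, max_width_px = 60)
  expect_equal(sum(r$truth$mask$grid), 24000, tolerance = 0.01)
  # cone: half the rectangle
  r2 <- render_cell("cone", length_px = 400, max_width_px = 60)
  expect_equal(sum(r2$truth$mask$grid), 12000, tolerance = 0.02)
  # general invariant: area = L * w_max * integral of the unit profile
  for (fam in list(list("power_taper", 2), list("wineglass", numeric()))) {
    p <- make_radius_profile(fam[[1]], fam[[2]])
    r3 <- render_silhouette(cell_spec(p, 500, 100))
    expected <- 500 * 100 * pracma::trapz(p$samples$x,
                                          p$samples$w / max(p$samples$w))
    cap <- if (p$fn(0) > 0) pi / 2 * (p$fn(0) * 50)^2 else 0
    expect_equal(sum(r3$truth$mask$grid), expected + cap, tolerance = 0.02)
  }
})

test_that("rendering is deterministic under the cell_spec seed", {
  sp <- cell_spec(make_radius_profile("wineglass"), 300, 60,
                  noise = noise_spec(boundary_jitter_px = 1.5,
                                     speckle_rate = 0.001, hole_count = 2),
                  seed = 99)
  r1 <- render_silhouette(sp)
  r2 <- render_silhouette(sp)
  expect_identical(r1$image, r2$image)
  expect_identical(r1$truth$mask$grid, r2$truth$mask$grid)
})

test_that("noise-free masks are simply connected", {
  for (fam in c("cone", "cylinder", "wineglass", "bulge")) {
    g <- render_cell(fam, length_px = 300, max_width_px = 60)$truth$mask$grid
    expect_equal(max(EBImage::bwlabel(g * 1)), 1)
    expect_true(all((EBImage::fillHull(g * 1) > 0) == g))
  }
})

test_that("ground-truth width table matches the scaled profile and the mask", {
  p <- make_radius_profile("wineglass")
  r <- render_silhouette(cell_spec(p, 400, 80))
  wa <- r$truth$width_at
  expect_equal(wa$w, p$fn(wa$s / 400) * 80, tolerance = 1e-9)
  # mask columns agree with the width table within rasterization error
  g <- r$truth$mask$grid
  x0 <- r$truth$midline_points$x[1]
  for (s in seq(50, 350, by = 50)) {
    col <- round(x0 + s) + 1L
    expect_lt(abs(sum(g[, col]) - wa$w[wa$s == s]), 1.5)
  }
})

test_that("cohorts are reproducible and respect parameter jitter", {
  tmpl <- cell_spec(make_radius_profile("wineglass"), 250, 50)
  c1 <- make_cohort(4, tmpl, seed = 5)
  c2 <- make_cohort(4, tmpl, seed = 5)
  expect_identical(lapply(c1, `[[`, "image"), lapply(c2, `[[`, "image"))
  # zero jitter: identical geometry across cells
  dims <- vapply(c1, function(r) dim(r$image), c(1, 1))
  expect_true(all(dims == dims[, 1]))
  expect_identical(c1[[1]]$image, c1[[4]]$image)

  # exponent jitter on a concave family: distinct true shape factors in (0,1]
  tmpl3 <- cell_spec(make_radius_profile("power_taper", 3), 250, 50)
  c3 <- make_cohort(10, tmpl3, jitter = list(param_sd = 0.4), seed = 11)
  sfs <- vapply(c3, function(r) r$truth$profile_sf, 0)
  expect_equal(length(unique(sfs)), 10)
  expect_true(all(sfs > 0 & sfs <= 1))
})

test_that("silhouettes round-trip through disk with their truth sidecar", {
  r <- render_cell("wineglass", length_px = 250, max_width_px = 50)
  out <- withr::local_tempdir()
  paths <- write_silhouette(r, out, "cell01")
  expect_true(all(file.exists(unlist(paths))))
  img <- read_cell_image(paths$image)
  expect_equal(dim(img), dim(r$image))
  expect_equal(img, r$image, tolerance = 1e-6)
  tr <- jsonlite::read_json(paths$truth, simplifyVector = TRUE)
  expect_equal(tr$analytic_sf, r$truth$analytic_sf, tolerance = 1e-9)
  expect_equal(nrow(tr$midline_points), nrow(r$truth$midline_points))
})
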