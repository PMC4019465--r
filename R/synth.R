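#' @title Synthetic cell silhouettes with exact ground truth
#' @description Parametric renderer for elongated-cell silhouettes.
#'   A width profile is swept perpendicular to a straight or
#'   constant-curvature axis and rasterized over 0-based pixel centers,
#'   so the true midline, the true width at every axial position and the
#'   analytic shape factor are all known by construction. This is how the
#'   whole pipeline is validated without any microscope data.
#' @name synth
NULL

# run expr with a private RNG stream; restores global .Random.seed
with_local_seed <- function(seed, expr) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_seed) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (has_seed) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}

#' Noise specification for silhouette rendering
#'
#' @param boundary_jitter_px Scale (standard deviation, px) of smooth
#'   radial displacement of the cell boundary; independent on the two
#'   sides of the axis, correlated over ~10 px of arc.
#' @param speckle_rate Fraction of image pixels flipped to the wrong
#'   intensity (isolated specks), in `[0, 1)`.
#' @param hole_count Number of small (2-4 px radius) background-valued
#'   holes punched inside the cell body.
#' @param background_gradient Amplitude (8-bit intensity units) of a
#'   linear left-to-right illumination ramp added to the image.
#' @return A `noise_spec` list. All-zero (the default) renders a clean
#'   two-level image.
#' @export
noise_spec <- function(boundary_jitter_px = 0, speckle_rate = 0,
                       hole_count = 0L, background_gradient = 0) {
  stopifnot(is.finite(boundary_jitter_px), boundary_jitter_px >= 0,
            is.finite(speckle_rate), speckle_rate >= 0, speckle_rate < 1,
            is.finite(hole_count), hole_count >= 0,
            is.finite(background_gradient), background_gradient >= 0)
  structure(list(boundary_jitter_px = boundary_jitter_px,
                 speckle_rate = speckle_rate,
                 hole_count = as.integer(hole_count),
                 background_gradient = background_gradient),
            class = "noise_spec")
}

#' Specification of one synthetic cell
#'
#' @param profile A [make_radius_profile()] width profile; its maximum is
#'   rescaled to `max_width_px`.
#' @param length_px Axis (midline) length in pixels.
#' @param max_width_px Maximum full width in pixels; must be smaller than
#'   `length_px`.
#' @param midline_curvature Constant curvature of the cell axis in 1/px
#'   (0 = straight). Positive bends the axis to the left of its initial
#'   direction.
#' @param rotation_deg Rotation of the initial axis direction,
#'   counterclockwise in (x right, y down) pixel coordinates.
#' @param noise A [noise_spec()].
#' @param seed Integer seed; all randomness in the render flows from it.
#' @return A `cell_spec` list.
#' @export
cell_spec <- function(profile, length_px, max_width_px,
                      midline_curvature = 0, rotation_deg = 0,
                      noise = noise_spec(), seed = 1L) {
  stopifnot(inherits(profile, "radius_profile"),
            inherits(noise, "noise_spec"),
            length_px > 0, max_width_px > 0,
            is.finite(midline_curvature), is.finite(rotation_deg))
  length_px <- as.integer(round(length_px))
  max_width_px <- as.integer(round(max_width_px))
  if (max_width_px >= length_px)
    stop("max_width_px must be smaller than length_px", call. = FALSE)
  if (abs(midline_curvature) * length_px >= pi)
    stop("curvature too strong: axis would bend beyond a half circle",
         call. = FALSE)
  structure(list(profile = profile, length_px = length_px,
                 max_width_px = max_width_px,
                 midline_curvature = midline_curvature,
                 rotation_deg = rotation_deg, noise = noise,
                 seed = as.integer(seed)),
            class = "cell_spec")
}

# axis geometry: returns functions point(t) (n x 2 matrix, (x, y)) and
# normal(t) (unit left normal), for t in [0, 1], plus arc length L
axis_geometry <- function(spec, origin = c(0, 0)) {
  L <- spec$length_px
  th <- spec$rotation_deg * pi / 180
  u <- c(cos(th), sin(th))
  nv <- c(-sin(th), cos(th)) # left normal
  k <- spec$midline_curvature
  if (k == 0) {
    point <- function(t) cbind(origin[1] + t * L * u[1],
                               origin[2] + t * L * u[2])
    normal <- function(t) cbind(rep(nv[1], length(t)), rep(nv[2], length(t)))
    return(list(point = point, normal = normal, L = L))
  }
  R <- 1 / abs(k)
  s_dir <- sign(k)
  C <- origin + s_dir * R * nv
  psi0 <- atan2(origin[2] - C[2], origin[1] - C[1])
  Phi <- L / R
  point <- function(t) {
    psi <- psi0 + s_dir * t * Phi
    cbind(C[1] + R * cos(psi), C[2] + R * sin(psi))
  }
  normal <- function(t) {
    # left normal points from axis toward the centre for k > 0
    psi <- psi0 + s_dir * t * Phi
    cbind(-s_dir * cos(psi), -s_dir * sin(psi))
  }
  list(point = point, normal = normal, L = L, C = C, R = R,
       psi0 = psi0, Phi = Phi, s_dir = s_dir)
}

# Analytic shape factor of the rendered silhouette: the swept profile
# plus the rounded tail cap when one is rendered. With no cap this
# equals analytic_shape_factor(profile); with a cap the cell's true tail
# is the cap tip (width -> 0), which changes the reference trapezoid
# exactly as it does for a real cell with a pointed holdfast.
silhouette_analytic_sf <- function(profile, length_px, max_width_px,
                                   n_grid = 20001L) {
  wscale <- max_width_px / max(profile$samples$w)
  h_tail <- profile$fn(0) * wscale / 2
  r_cap <- if (h_tail > 0.5 && h_tail <= 0.15 * max_width_px) h_tail else 0
  s <- seq(0, length_px + r_cap, length.out = n_grid)
  w <- ifelse(s < r_cap,
              2 * sqrt(pmax(r_cap^2 - (r_cap - s)^2, 0)),
              profile$fn(pmin((s - r_cap) / length_px, 1)) * wscale)
  oa <- which.max(w)
  tail_i <- if (abs(s[oa]) >= abs(s[oa] - max(s))) 1L else length(s)
  rng <- seq(min(oa, tail_i), max(oa, tail_i))
  area <- pracma::trapz(s[rng], w[rng])
  trap <- (w[tail_i] + w[oa]) / 2 * abs(s[oa] - s[tail_i])
  area / trap
}

# piecewise-linear random field over t in [0,1], knot spacing ~10 px arc
jitter_field <- function(sd_px, L) {
  if (sd_px <= 0) return(function(t) rep(0, length(t)))
  n_knots <- max(4L, ceiling(L / 10) + 1L)
  kx <- seq(0, 1, length.out = n_knots)
  ky <- stats::rnorm(n_knots, 0, sd_px)
  function(t) stats::approx(kx, ky, xout = t, rule = 2)$y
}

#' Render one synthetic silhouette and its ground truth
#'
#' Sweeps the width profile of `spec` perpendicular to the cell axis and
#' rasterizes the result onto an 8-bit grayscale canvas (background 30,
#' cell 200) with a 10 px margin. The wide (OA) end is capped flat; the
#' tail end carries a semicircular cap when the profile width at the tail
#' is positive, and tapers to a point otherwise. Rendering is
#' deterministic given `spec$seed`.
#'
#' @param spec A [cell_spec()].
#' @return A list with `image` (numeric matrix, 0-255, rows = y) and
#'   `truth`, a `ground_truth` list carrying `midline_points` (tibble
#'   `x`, `y`, `s` at ~1 px arc spacing, axis only), `width_at` (tibble
#'   `s`, `w`: true full width in px along the axis), `analytic_sf` (the
#'   analytic shape factor of the full rendered silhouette, tail cap
#'   included; equal to `profile_sf` when no cap is rendered),
#'   `profile_sf` (= [analytic_shape_factor()] of the bare profile),
#'   `mask` (noise-free [binary_mask()]) and `axis_length_px`.
#' @examples
#' r <- render_silhouette(cell_spec(make_radius_profile("cone"), 300, 60))
#' dim(r$image)
#' r$truth$analytic_sf
#' @export
render_silhouette <- function(spec) {
  stopifnot(inherits(spec, "cell_spec"))
  with_local_seed(spec$seed, render_silhouette_impl(spec))
}

render_silhouette_impl <- function(spec) {
  margin <- 10
  L <- spec$length_px
  wmax_samples <- max(spec$profile$samples$w)
  wscale <- spec$max_width_px / wmax_samples
  half_w <- function(t) spec$profile$fn(t) * wscale / 2

  # bounding box from a dense sweep around a provisional origin
  geo0 <- axis_geometry(spec, origin = c(0, 0))
  tt <- seq(0, 1, length.out = 1024)
  P <- geo0$point(tt); N <- geo0$normal(tt)
  pad <- spec$noise$boundary_jitter_px * 3
  h <- half_w(tt) + pad
  xs <- c(P[, 1] + h * N[, 1], P[, 1] - h * N[, 1],
          P[1, 1] + c(-1, 1) * (h[1]), P[1, 1])
  ys <- c(P[, 2] + h * N[, 2], P[, 2] - h * N[, 2],
          P[1, 2], P[1, 2] + c(-1, 1) * h[1])
  origin <- c(margin - min(xs), margin - min(ys))
  # lay axis-aligned straight cells on a pixel-centre row/column so the
  # rasterized silhouette keeps its (possibly sub-pixel-thin) tail; no
  # physical cell has an infinitesimal tail, but the idealized profiles
  # do, and off-grid placement would alias it away
  if (spec$midline_curvature == 0 && spec$rotation_deg %% 90 == 0)
    origin <- round(origin)
  width_canvas <- ceiling(max(xs) - min(xs)) + 2 * margin + 1
  height_canvas <- ceiling(max(ys) - min(ys)) + 2 * margin + 1

  geo <- axis_geometry(spec, origin = origin)

  # pixel-centre coordinate grids, 0-based: x = col - 1, y = row - 1
  nc <- as.integer(width_canvas); nr <- as.integer(height_canvas)
  px <- matrix(rep(0:(nc - 1), each = nr), nr, nc)
  py <- matrix(rep(0:(nr - 1), times = nc), nr, nc)

  # axial parameter t and signed perpendicular offset d (positive = left)
  if (spec$midline_curvature == 0) {
    th <- spec$rotation_deg * pi / 180
    u <- c(cos(th), sin(th)); nv <- c(-sin(th), cos(th))
    rx <- px - geo$point(0)[1, 1]; ry <- py - geo$point(0)[1, 2]
    tpar <- (rx * u[1] + ry * u[2]) / L
    d <- rx * nv[1] + ry * nv[2]
  } else {
    vx <- px - geo$C[1]; vy <- py - geo$C[2]
    r <- sqrt(vx^2 + vy^2)
    dpsi <- atan2(vy, vx) - geo$psi0
    dpsi <- (dpsi + pi) %% (2 * pi) - pi
    tpar <- geo$s_dir * dpsi / geo$Phi
    d <- geo$s_dir * (geo$R - r)
  }

  jitL <- jitter_field(spec$noise$boundary_jitter_px, L)
  jitR <- jitter_field(spec$noise$boundary_jitter_px, L)

  in_body <- function(jitter) {
    tc <- pmin(pmax(tpar, 0), 1)
    h0 <- half_w(tc)
    if (jitter) {
      hl <- pmax(h0 + jitL(tc), 0)
      hr <- pmax(h0 + jitR(tc), 0)
    } else {
      hl <- h0; hr <- h0
    }
    # half-open sampling: a cell of length L and width w covers exactly
    # L x w pixel centres (axis-aligned case)
    body <- tpar >= 0 & tpar < 1 &
      ((d >= 0 & d <= hl) | (d < 0 & -d < hr))
    # round the tail only when it is narrow (holdfast-like); a wide,
    # essentially untapered tail (e.g. a cylinder) is capped flat so the
    # silhouette stays the swept body
    h_tail <- half_w(0)
    if (h_tail > 0.5 && h_tail <= 0.15 * spec$max_width_px) {
      P0 <- geo$point(0)
      cap <- tpar < 0 & (px - P0[1, 1])^2 + (py - P0[1, 2])^2 <= h_tail^2
      body <- body | cap
    }
    body
  }

  mask_true <- in_body(jitter = FALSE)
  fg_grid <- if (spec$noise$boundary_jitter_px > 0) in_body(TRUE) else mask_true

  img <- matrix(30, nr, nc)
  img[fg_grid] <- 200

  # holes: small background-valued disks well inside the body
  if (spec$noise$hole_count > 0) {
    cand <- which(fg_grid & tpar > 0.2 & tpar < 0.9 & abs(d) < half_w(pmin(pmax(tpar, 0), 1)) * 0.5)
    if (length(cand) > 0) {
      centers <- sample(cand, min(spec$noise$hole_count, length(cand)))
      for (ci in centers) {
        rad <- stats::runif(1, 2, 4)
        cx <- px[ci]; cy <- py[ci]
        img[(px - cx)^2 + (py - cy)^2 <= rad^2] <- 30
      }
    }
  }

  # speckle: isolated wrong-valued pixels
  if (spec$noise$speckle_rate > 0) {
    k <- round(spec$noise$speckle_rate * nr * nc)
    if (k > 0) {
      idx <- sample.int(nr * nc, k)
      img[idx] <- ifelse(img[idx] > 115, 30, 200)
    }
  }

  if (spec$noise$background_gradient > 0) {
    ramp <- spec$noise$background_gradient * ((px / max(nc - 1, 1)) - 0.5)
    img <- pmin(pmax(img + ramp, 0), 255)
  }

  s_grid <- seq(0, L, by = 1)
  t_grid <- s_grid / L
  mp <- geo$point(t_grid)
  truth <- structure(list(
    midline_points = tibble::tibble(x = mp[, 1], y = mp[, 2], s = s_grid),
    width_at = tibble::tibble(s = s_grid,
                              w = spec$profile$fn(t_grid) * wscale),
    analytic_sf = silhouette_analytic_sf(spec$profile, L, spec$max_width_px),
    profile_sf = analytic_shape_factor(spec$profile),
    mask = binary_mask(mask_true),
    axis_length_px = L,
    spec = spec
  ), class = "ground_truth")

  list(image = img, truth = truth)
}

#' Generate a cohort of synthetic cells with per-cell parameter jitter
#'
#' Renders `n` independent cells from a template spec, drawing per-cell
#' variation in geometry from `jitter` (all Gaussian, truncated to valid
#' ranges). Reproducible under `seed`; each cell receives its own derived
#' seed.
#'
#' @param n Number of cells.
#' @param spec_template A [cell_spec()] used as the base for every cell.
#' @param jitter Named list of standard deviations; recognised names:
#'   `length_px`, `max_width_px`, `curvature`, `rotation_deg`, and
#'   `param_sd` (applied to the first profile-family parameter, e.g. the
#'   power-taper exponent). Missing entries mean no variation.
#' @param seed Integer master seed.
#' @return A list of `n` elements, each a `render_silhouette()` result.
#' @export
make_cohort <- function(n, spec_template, jitter = list(), seed = 1L) {
  stopifnot(n >= 1, inherits(spec_template, "cell_spec"))
  jget <- function(name) if (!is.null(jitter[[name]])) jitter[[name]] else 0
  with_local_seed(seed, {
    cell_seeds <- sample.int(2^30, n)
    dl <- stats::rnorm(n, 0, jget("length_px"))
    dw <- stats::rnorm(n, 0, jget("max_width_px"))
    dk <- stats::rnorm(n, 0, jget("curvature"))
    dr <- stats::rnorm(n, 0, jget("rotation_deg"))
    dp <- stats::rnorm(n, 0, jget("param_sd"))
    lapply(seq_len(n), function(i) {
      len <- max(50, round(spec_template$length_px + dl[i]))
      wid <- max(8, round(spec_template$max_width_px + dw[i]))
      wid <- min(wid, len - 1)
      prof <- spec_template$profile
      if (dp[i] != 0 && length(prof$params) >= 1) {
        pars <- prof$params
        pars[1] <- max(pars[1] + dp[i], 0.1)
        prof <- make_radius_profile(prof$family, pars)
      }
      sp <- cell_spec(prof, len, wid,
                      midline_curvature = spec_template$midline_curvature + dk[i],
                      rotation_deg = spec_template$rotation_deg + dr[i],
                      noise = spec_template$noise,
                      seed = cell_seeds[i])
      render_silhouette(sp)
    })
  })
}

#' Write a rendered silhouette to disk
#'
#' Writes the grayscale image and the noise-free reference mask as 8-bit
#' PNGs plus a JSON ground-truth sidecar (midline points, true width
#' table, analytic shape factor).
#'
#' @param render A [render_silhouette()] result.
#' @param outdir Output directory (created if missing).
#' @param id Cell identifier used as the file stem.
#' @return Invisibly, the paths written (`image`, `mask`, `truth`).
#' @export
write_silhouette <- function(render, outdir, id) {
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  paths <- list(
    image = file.path(outdir, paste0(id, ".png")),
    mask = file.path(outdir, paste0(id, "_mask.png")),
    truth = file.path(outdir, paste0(id, "_truth.json"))
  )
  png::writePNG(render$image / 255, paths$image)
  png::writePNG(render$truth$mask$grid * 1, paths$mask)
  tr <- render$truth
  jsonlite::write_json(list(
    analytic_sf = tr$analytic_sf,
    axis_length_px = tr$axis_length_px,
    midline_points = as.data.frame(tr$midline_points),
    width_at = as.data.frame(tr$width_at)
  ), paths$truth, auto_unbox = TRUE, digits = NA)
  invisible(paths)
}
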