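# shared fixtures: everything is generated in code at test time

render_cell <- function(family, params = numeric(), length_px = 400,
                        max_width_px = 80, ...) {
  render_silhouette(cell_spec(make_radius_profile(family, params),
                              length_px, max_width_px, ...))
}

sf_of <- function(render, smooth_rounds = 2) {
  analyze_cell(render$image, smooth_rounds = smooth_rounds)$sf$shape_factor
}

# a width_profile built directly from vectors, for shape-factor tests
profile_from <- function(s, w, L = max(s), cell_id = "fixture",
                         oriented = TRUE) {
  structure(list(
    stations = tibble::tibble(s = s, x = s / L, w = w),
    dropped = tibble::tibble(s = numeric(), reason = character()),
    L = L, cell_id = cell_id, oriented = oriented
  ), class = "width_profile")
}

# a straight synthetic midline object (horizontal at height y0)
straight_midline <- function(L, x0 = 0, y0 = 0) {
  s <- seq(0, L, by = 0.5)
  structure(list(
    raw_points = tibble::tibble(x = x0 + s, y = rep(y0, length(s))),
    curve = tibble::tibble(s = s, x = x0 + s, y = y0,
                           tx = 1, ty = 0),
    L = L
  ), class = "midline")
}

# axis-aligned rectangle contour (x in [x1,x2], y in [y1,y2]), CCW-ish
rect_contour <- function(x1, x2, y1, y2) {
  pts <- tibble::tibble(
    x = c(x1, x2, x2, x1),
    y = c(y1, y1, y2, y2))
  structure(list(points = pts,
                 area = (x2 - x1) * (y2 - y1)),
            class = "contour")
}

jaccard <- function(a, b) sum(a & b) / sum(a | b)
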