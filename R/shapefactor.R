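#' Locate the oral apparatus and tail landmarks on a width profile
#'
#' The widest station is taken to represent the oral apparatus (OA); the
#' tail is the station farthest from the OA in arc length along the
#' midline. Raster widths are quantized to about half a pixel, so every
#' station within 0.5 px of the maximum is an equally credible widest
#' point; among those near-ties the station giving the largest tail-OA
#' span is chosen -- anatomically the OA sits at the anterior extreme,
#' and for a constant-width (cylinder) profile this reduces to the
#' documented endpoint convention (OA at one end, tail at the other),
#' which leaves the shape factor unaffected since the ratio is 1 for any
#' constant profile.
#'
#' @param profile A `width_profile` with at least 3 stations.
#' @return A list with integer `oa_index` and `tail_index` (row indices
#'   into `profile$stations`).
#' @export
locate_landmarks <- function(profile) {
  stopifnot(inherits(profile, "width_profile"))
  st <- profile$stations
  if (nrow(st) < 3)
    stop("need at least 3 stations to locate landmarks", call. = FALSE)
  cand <- which(st$w >= max(st$w) - 0.5)
  span_of <- function(i) max(abs(st$s - st$s[i]))
  spans <- vapply(cand, span_of, 0)
  oa <- cand[which.max(spans)]
  tail_i <- which.max(abs(st$s - st$s[oa]))
  if (tail_i == oa)
    stop("OA and tail coincide; degenerate profile", call. = FALSE)
  list(oa_index = oa, tail_index = tail_i)
}

#' Shape factor of a measured width profile
#'
#' Computes the paper-style proportionality statistic: the width profile
#' between the tail and the OA is integrated by the trapezoidal rule
#' (the "actual" area), a reference right trapezoid is built by joining
#' the tail and OA widths with a straight line over the same arc span,
#' and the shape factor is the ratio of the two areas. A straight-sided
#' cell (cone, with the cylinder as the constant-width special case)
#' scores 1; a concave, wine-glass-like taper scores below 1; a convex
#' bulge scores above 1. Integration uses absolute arc positions; the
#' ratio is invariant to normalization of either axis.
#'
#' @param profile A `width_profile` (orientation not required; the
#'   statistic is direction-invariant).
#' @return A `shape_factor_result`: list with `oa_index`, `tail_index`,
#'   `oa_x`, `tail_x`, `area_actual`, `area_trapezoid`, `shape_factor`,
#'   `cell_id` and `L`.
#' @examples
#' st <- tibble::tibble(s = seq(0, 100, 10), x = seq(0, 1, 0.1),
#'                      w = seq(0, 1, 0.1)^2 * 60)
#' p <- structure(list(stations = st, L = 100, cell_id = "demo",
#'                     oriented = TRUE), class = "width_profile")
#' compute_shape_factor(p)$shape_factor # ~ 2/3
#' @export
compute_shape_factor <- function(profile) {
  lm <- locate_landmarks(profile)
  st <- profile$stations
  rng <- seq(min(lm$oa_index, lm$tail_index), max(lm$oa_index, lm$tail_index))
  area_actual <- pracma::trapz(st$s[rng], st$w[rng])
  span <- abs(st$s[lm$oa_index] - st$s[lm$tail_index])
  area_trap <- (st$w[lm$tail_index] + st$w[lm$oa_index]) / 2 * span
  if (area_trap <= 0)
    stop("zero reference trapezoid area; cannot form the shape factor",
         call. = FALSE)
  structure(list(
    oa_index = lm$oa_index, tail_index = lm$tail_index,
    oa_x = st$s[lm$oa_index] / profile$L,
    tail_x = st$s[lm$tail_index] / profile$L,
    area_actual = area_actual, area_trapezoid = area_trap,
    shape_factor = area_actual / area_trap,
    cell_id = profile$cell_id, L = profile$L
  ), class = "shape_factor_result")
}

#' @export
print.shape_factor_result <- function(x, ...) {
  cat(sprintf("<shape_factor> %s: SF = %.3f (actual %.0f / trapezoid %.0f)\n",
              x$cell_id, x$shape_factor, x$area_actual, x$area_trapezoid))
  invisible(x)
}

#' One-row tidy summary of a shape-factor result
#' @param result A [compute_shape_factor()] result.
#' @return A one-row tibble: `cell_id`, `L`, `oa_x`, `tail_x`,
#'   `area_actual`, `area_trapezoid`, `shape_factor`.
#' @export
shape_factor_row <- function(result) {
  stopifnot(inherits(result, "shape_factor_result"))
  tibble::tibble(cell_id = result$cell_id, L = result$L,
                 oa_x = result$oa_x, tail_x = result$tail_x,
                 area_actual = result$area_actual,
                 area_trapezoid = result$area_trapezoid,
                 shape_factor = result$shape_factor)
}
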