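#' Parametric width profiles for synthetic cells
#'
#' A radius profile describes the full width `w(x)` of an idealised
#' elongated cell as a function of normalized axial position
#' `x in [0, 1]`, with `x = 0` at the narrow tail (holdfast) end and
#' `x = 1` at the wide anterior (oral apparatus, OA) end. Widths are in
#' arbitrary units; rendering rescales the profile so that its maximum
#' equals the requested width in pixels.
#'
#' Available families:
#' \describe{
#'   \item{`cone`}{`w(x) = x`: straight-sided right cone, apex at the tail.}
#'   \item{`cylinder`}{`w(x) = 1`: constant width.}
#'   \item{`power_taper`}{`w(x) = x^p`, `p > 0` (first element of `params`).
#'     `p > 1` gives a concave, wine-glass-like taper; `p < 1` a convex
#'     bulge; `p = 1` recovers the cone.}
#'   \item{`wineglass`}{`w(x) = stem + (1 - stem) * x^p` with
#'     `params = c(stem, p)`: a concave taper flaring from a stem of
#'     relative width `stem > 0` at the tail, so the silhouette keeps a
#'     positive width everywhere like a real cell. Defaults
#'     `stem = 0.15`, `p = 3`.}
#'   \item{`bulge`}{`w(x) = x + b * x * (1 - x)` with `params = b >= 0`:
#'     a cone with a convex mid-body bulge; its analytic shape factor is
#'     `1 + b/3 > 1`. Default `b = 1`.}
#'   \item{`custom`}{`params` ignored; supply `fn`, a vectorised function
#'     of `x` returning non-negative widths.}
#' }
#'
#' @param family One of `"cone"`, `"cylinder"`, `"power_taper"`,
#'   `"wineglass"`, `"bulge"`, `"custom"`.
#' @param params Numeric parameters for the family (see Details).
#' @param fn For `family = "custom"`, a vectorised width function of `x`.
#' @param n_samples Number of uniformly spaced sample positions
#'   (including both endpoints); at least 256.
#'
#' @return An object of class `radius_profile`: a list with `family`,
#'   `params`, `fn` (the continuous width function) and `samples`, a
#'   tibble with columns `x` and `w`.
#' @examples
#' prof <- make_radius_profile("power_taper", 2)
#' prof$fn(0.5) # 0.25
#' analytic_shape_factor(prof) # ~ 2/3
#' @export
make_radius_profile <- function(family = c("cone", "cylinder", "power_taper",
                                           "wineglass", "bulge", "custom"),
                                params = numeric(), fn = NULL,
                                n_samples = 513L) {
  family <- match.arg(family)
  n_samples <- max(as.integer(n_samples), 256L)
  params <- as.numeric(params)

  wfun <- switch(family,
    cone = function(x) x,
    cylinder = function(x) rep(1, length(x)),
    power_taper = {
      p <- if (length(params) >= 1) params[[1]] else 1
      if (!is.finite(p) || p <= 0)
        stop("power_taper requires exponent p > 0", call. = FALSE)
      function(x) x^p
    },
    wineglass = {
      stem <- if (length(params) >= 1) params[[1]] else 0.15
      p <- if (length(params) >= 2) params[[2]] else 3
      if (!is.finite(stem) || stem <= 0 || stem >= 1)
        stop("wineglass stem width must be in (0, 1)", call. = FALSE)
      if (!is.finite(p) || p <= 0)
        stop("wineglass exponent must be > 0", call. = FALSE)
      function(x) stem + (1 - stem) * x^p
    },
    bulge = {
      b <- if (length(params) >= 1) params[[1]] else 1
      if (!is.finite(b) || b < 0)
        stop("bulge amplitude must be >= 0", call. = FALSE)
      function(x) x + b * x * (1 - x)
    },
    custom = {
      if (!is.function(fn))
        stop("family 'custom' requires a width function `fn`", call. = FALSE)
      fn
    }
  )

  x <- seq(0, 1, length.out = n_samples)
  w <- as.numeric(wfun(x))
  if (length(w) != length(x) || anyNA(w) || any(!is.finite(w)))
    stop("width function returned non-finite values", call. = FALSE)
  if (any(w < 0))
    stop("width profile must be non-negative", call. = FALSE)
  if (any(w[-c(1L, length(w))] <= 0))
    stop("width profile must be positive on the interior", call. = FALSE)

  structure(
    list(family = family, params = params, fn = wfun,
         samples = tibble::tibble(x = x, w = w)),
    class = "radius_profile"
  )
}

#' @export
print.radius_profile <- function(x, ...) {
  cat(sprintf("<radius_profile> family=%s params=[%s] w(0)=%.3g w(1)=%.3g\n",
              x$family, paste(signif(x$params, 4), collapse = ", "),
              x$samples$w[1], x$samples$w[nrow(x$samples)]))
  invisible(x)
}

#' Analytic shape factor of a continuous width profile
#'
#' Computes the shape factor directly from the continuous width function,
#' on a fine quadrature grid, with the same landmark and integration
#' rules as the raster pipeline: the oral apparatus (OA) is the widest
#' point, the tail is the point farthest from the OA along the axis, the
#' "actual" area is the trapezoidal-rule integral of the width between
#' the two, and the reference area is the right trapezoid whose parallel
#' sides are the tail and OA widths. The returned value is the ratio of
#' the two areas. This is the brute-force oracle used to validate the
#' image-based pipeline: a straight-sided cone or cylinder gives exactly
#' 1, the power taper `x^p` gives `2 / (p + 1)`.
#'
#' @param profile A [make_radius_profile()] object.
#' @param n_grid Number of quadrature points (at least 1e4 + 1).
#' @return A single number, the analytic shape factor.
#' @examples
#' analytic_shape_factor(make_radius_profile("cone")) # 1
#' analytic_shape_factor(make_radius_profile("power_taper", 3)) # ~ 0.5
#' @export
analytic_shape_factor <- function(profile, n_grid = 10001L) {
  stopifnot(inherits(profile, "radius_profile"))
  n_grid <- max(as.integer(n_grid), 10001L)
  x <- seq(0, 1, length.out = n_grid)
  w <- as.numeric(profile$fn(x))
  if (all(w <= 0)) stop("degenerate profile: zero width everywhere", call. = FALSE)
  oa <- which.max(w)
  # tail = point farthest from the OA along the axis: one of the endpoints
  tail_i <- if (abs(x[oa] - 0) >= abs(x[oa] - 1)) 1L else n_grid
  if (tail_i == oa) stop("degenerate profile: OA and tail coincide", call. = FALSE)
  rng <- seq(min(oa, tail_i), max(oa, tail_i))
  area_actual <- pracma::trapz(x[rng], w[rng])
  area_trap <- (w[tail_i] + w[oa]) / 2 * abs(x[oa] - x[tail_i])
  if (area_trap <= 0) stop("degenerate profile: zero trapezoid area", call. = FALSE)
  area_actual / area_trap
}
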