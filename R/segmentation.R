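#' Binary mask container
#'
#' A thin wrapper around a logical matrix (`[row, col]`, 0-based pixel
#' centres in geometry space: `x = col - 1`, `y = row - 1`) holding one
#' cell's silhouette, plus an optional physical pixel size.
#'
#' @param grid Logical (or coercible) matrix; `TRUE` = foreground.
#' @param pixel_size Physical units per pixel (default 1).
#' @return A `binary_mask` object.
#' @export
binary_mask <- function(grid, pixel_size = 1) {
  grid <- if (is.logical(grid)) grid else grid > 0
  stopifnot(is.matrix(grid), pixel_size > 0)
  structure(list(grid = grid, pixel_size = pixel_size), class = "binary_mask")
}

#' @export
print.binary_mask <- function(x, ...) {
  cat(sprintf("<binary_mask> %d x %d, %d fg px\n",
              nrow(x$grid), ncol(x$grid), sum(x$grid)))
  invisible(x)
}

#' Threshold a grayscale image into a cell mask
#'
#' Chooses a global threshold by the iterative intermeans (IsoData) rule:
#' starting from the image mean, the threshold is replaced by the average
#' of the means of the two classes it induces, until it stabilises. With
#' one cell per image the background is the class that dominates the
#' image border, so by default (`"auto"`) the border-minority side of
#' the threshold is taken as the cell; this stays correct for dark cells
#' on bright fields and vice versa, and for cells occupying most of the
#' interior. `"smaller"` picks the smaller-area side instead; `"bright"`
#' / `"dark"` force a side.
#'
#' @param image Numeric matrix, any monotone intensity scale (0-255 or
#'   0-1 both work).
#' @param foreground `"auto"`, `"smaller"`, `"bright"` or `"dark"`.
#' @return A [binary_mask()].
#' @export
binarize <- function(image, foreground = c("auto", "smaller", "bright", "dark")) {
  foreground <- match.arg(foreground)
  stopifnot(is.matrix(image), is.numeric(image))
  v <- as.numeric(image)
  if (diff(range(v)) == 0)
    stop("constant image: no threshold separates foreground from background",
         call. = FALSE)
  t_old <- -Inf; t_new <- mean(v)
  for (i in 1:200) {
    lo <- v[v <= t_new]; hi <- v[v > t_new]
    if (length(lo) == 0 || length(hi) == 0) break
    t_old <- t_new
    t_new <- (mean(lo) + mean(hi)) / 2
    if (abs(t_new - t_old) < 1e-8) break
  }
  bright <- image > t_new
  border <- c(bright[1, ], bright[nrow(bright), ],
              bright[, 1], bright[, ncol(bright)])
  fg <- switch(foreground,
    bright = bright,
    dark = !bright,
    smaller = if (sum(bright) <= length(bright) / 2) bright else !bright,
    auto = if (mean(border) <= 0.5) bright else !bright
  )
  binary_mask(fg)
}

# 3x3 mean filter with replicate-border padding, vectorised
mean3x3 <- function(m) {
  nr <- nrow(m); nc <- ncol(m)
  p <- matrix(0, nr + 2, nc + 2)
  p[2:(nr + 1), 2:(nc + 1)] <- m
  p[1, ] <- p[2, ]; p[nr + 2, ] <- p[nr + 1, ]
  p[, 1] <- p[, 2]; p[, nc + 2] <- p[, nc + 1]
  acc <- matrix(0, nr, nc)
  for (dr in 0:2) for (dc in 0:2)
    acc <- acc + p[(1 + dr):(nr + dr), (1 + dc):(nc + dc)]
  acc / 9
}

#' Smooth a binary mask as repeated 3x3 mean filtering
#'
#' Each round treats the mask as a {0, 255} image, applies a 3x3 mean
#' filter with replicate-border padding, and re-thresholds at >= 128 so
#' the result stays binary. Two rounds (the default) remove single-pixel
#' specks and fill single-pixel notches along otherwise straight edges
#' while leaving large convex bodies essentially unchanged.
#'
#' @param mask A [binary_mask()].
#' @param rounds Number of smoothing rounds (>= 0).
#' @return A smoothed [binary_mask()].
#' @export
smooth_binary <- function(mask, rounds = 2L) {
  stopifnot(inherits(mask, "binary_mask"), rounds >= 0)
  g <- mask$grid * 255
  for (i in seq_len(rounds)) g <- (mean3x3(g) >= 128) * 255
  binary_mask(g > 0, mask$pixel_size)
}

#' Reduce a mask to one clean connected component
#'
#' Keeps only the largest 8-connected foreground component and fills all
#' of its holes, yielding the single simply connected silhouette the
#' geometry stages require. Warns if the component touches the image
#' border (the cell may be clipped). Idempotent.
#'
#' @param mask A [binary_mask()].
#' @return A cleaned [binary_mask()].
#' @export
clean_mask <- function(mask) {
  stopifnot(inherits(mask, "binary_mask"))
  g <- mask$grid
  if (!any(g)) stop("empty mask: no foreground pixels", call. = FALSE)
  lab <- EBImage::bwlabel(g * 1)
  if (max(lab) > 1) {
    sizes <- tabulate(lab[lab > 0])
    g <- lab == which.max(sizes)
  }
  g <- EBImage::fillHull(g * 1) > 0
  if (any(g[1, ]) || any(g[nrow(g), ]) || any(g[, 1]) || any(g[, ncol(g)]))
    warning("foreground touches the image border; cell may be clipped")
  binary_mask(g, mask$pixel_size)
}

# TRUE if mask holds exactly one 8-connected component with no holes
is_clean <- function(mask) {
  g <- mask$grid
  if (!any(g)) return(FALSE)
  if (max(EBImage::bwlabel(g * 1)) != 1) return(FALSE)
  all((EBImage::fillHull(g * 1) > 0) == g)
}
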