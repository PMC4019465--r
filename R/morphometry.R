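#' @title Outline, midline and width-profile extraction
#' @description Geometry stages of the pipeline: trace the subpixel cell
#'   outline, thin the mask to a skeleton and reduce it to the cell
#'   midline, then measure perpendicular chord widths at regular arc
#'   intervals along the midline.
#' @name morphometry
NULL

shoelace_area <- function(x, y) {
  0.5 * sum(x * c(y[-1], y[1]) - c(x[-1], x[1]) * y)
}

#' Trace the subpixel outline of a clean mask
#'
#' Extracts the 0.5-level isocontour of the binary grid (marching
#' squares), i.e. a closed polygon passing midway between foreground and
#' background pixel centres. The polygon is oriented so its shoelace
#' area is positive in the stored (x right, y down) coordinates.
#'
#' @param mask A clean [binary_mask()] (one component, no holes).
#' @return A `contour` object: list with `points` (tibble `x`, `y`,
#'   subpixel 0-based pixel coordinates, closed implicitly) and `area`.
#' @export
trace_outline <- function(mask) {
  stopifnot(inherits(mask, "binary_mask"))
  if (!is_clean(mask))
    stop("mask must hold exactly one component with no holes; run clean_mask()",
         call. = FALSE)
  g <- mask$grid
  if (sum(g) < 4)
    stop("degenerate mask: too few foreground pixels to trace an outline",
         call. = FALSE)
  nr <- nrow(g); nc <- ncol(g)
  # pad with background so border-adjacent cells still close
  z <- matrix(0, nr + 2, nc + 2)
  z[2:(nr + 1), 2:(nc + 1)] <- g * 1
  cl <- grDevices::contourLines(x = seq(-1, nr) , y = seq(-1, nc),
                                z = z, levels = 0.5)
  if (length(cl) == 0) stop("no contour found", call. = FALSE)
  # z rows run along image rows (y); contourLines' x is our y
  areas <- vapply(cl, function(cc) abs(shoelace_area(cc$y, cc$x)), 0)
  cc <- cl[[which.max(areas)]]
  x <- cc$y; y <- cc$x
  # drop duplicated closing vertex if present
  n <- length(x)
  if (n > 1 && x[1] == x[n] && y[1] == y[n]) { x <- x[-n]; y <- y[-n] }
  if (shoelace_area(x, y) < 0) { x <- rev(x); y <- rev(y) }
  structure(list(points = tibble::tibble(x = x, y = y),
                 area = shoelace_area(x, y)),
            class = "contour")
}

#' @export
print.contour <- function(x, ...) {
  cat(sprintf("<contour> %d vertices, area %.1f px^2\n",
              nrow(x$points), x$area))
  invisible(x)
}

# ---- skeletonization ---------------------------------------------------

shift_mat <- function(m, dr, dc) {
  nr <- nrow(m); nc <- ncol(m)
  out <- matrix(0L, nr, nc)
  rs <- max(1, 1 + dr):min(nr, nr + dr)
  cs <- max(1, 1 + dc):min(nc, nc + dc)
  out[rs, cs] <- m[rs - dr, cs - dc]
  out
}

# Zhang-Suen topology-preserving thinning on a 0/1 matrix
thin_mask <- function(g) {
  m <- g * 1L
  repeat {
    changed <- FALSE
    for (step in 1:2) {
      # neighbours clockwise from north: P2..P9
      P2 <- shift_mat(m, 1, 0);  P3 <- shift_mat(m, 1, -1)
      P4 <- shift_mat(m, 0, -1); P5 <- shift_mat(m, -1, -1)
      P6 <- shift_mat(m, -1, 0); P7 <- shift_mat(m, -1, 1)
      P8 <- shift_mat(m, 0, 1);  P9 <- shift_mat(m, 1, 1)
      B <- P2 + P3 + P4 + P5 + P6 + P7 + P8 + P9
      A <- (P2 == 0 & P3 == 1) + (P3 == 0 & P4 == 1) +
           (P4 == 0 & P5 == 1) + (P5 == 0 & P6 == 1) +
           (P6 == 0 & P7 == 1) + (P7 == 0 & P8 == 1) +
           (P8 == 0 & P9 == 1) + (P9 == 0 & P2 == 1)
      if (step == 1) {
        cond <- m == 1 & B >= 2 & B <= 6 & A == 1 &
          (P2 * P4 * P6 == 0) & (P4 * P6 * P8 == 0)
      } else {
        cond <- m == 1 & B >= 2 & B <= 6 & A == 1 &
          (P2 * P4 * P8 == 0) & (P2 * P6 * P8 == 0)
      }
      if (any(cond)) { m[cond] <- 0L; changed <- TRUE }
    }
    if (!changed) break
  }
  m
}

# longest endpoint-to-endpoint geodesic through the skeleton pixel graph;
# returns ordered (row, col) matrix
skeleton_longest_path <- function(skel) {
  idx <- which(skel == 1L)
  if (length(idx) < 2)
    stop("skeleton is empty or a single pixel; cannot extract a midline",
         call. = FALSE)
  nr <- nrow(skel)
  rows <- ((idx - 1) %% nr) + 1
  cols <- ((idx - 1) %/% nr) + 1
  key <- function(r, c) (c - 1) * nr + r
  vid <- seq_along(idx)
  names(vid) <- as.character(idx)
  edges <- NULL; weights <- NULL
  # edges to half of the 8-neighbourhood to avoid duplicates
  for (d in list(c(0, 1), c(1, 0), c(1, 1), c(-1, 1))) {
    nb <- key(rows + d[1], cols + d[2])
    ok <- rows + d[1] >= 1 & rows + d[1] <= nr & cols + d[2] >= 1 &
      cols + d[2] <= ncol(skel)
    ok[ok] <- skel[cbind(rows[ok] + d[1], cols[ok] + d[2])] == 1L
    if (!any(ok)) next
    from <- vid[as.character(idx[ok])]
    to <- vid[as.character(nb[ok])]
    edges <- c(edges, rbind(from, to))
    weights <- c(weights, rep(sqrt(sum(d^2)), sum(ok)))
  }
  if (is.null(edges))
    stop("skeleton pixels are disconnected; cannot extract a midline",
         call. = FALSE)
  gr <- igraph::make_graph(edges = as.numeric(edges), n = length(idx),
                           directed = FALSE)
  igraph::E(gr)$weight <- weights
  if (!any(igraph::degree(gr) == 1))
    stop("skeleton has no free endpoints (cyclic); cannot extract a midline",
         call. = FALSE)
  # the midline is the weighted graph diameter; using all vertices as
  # candidate terminals (not just leaves) keeps arms reachable even
  # when rasterization noise closes a small loop at an arm's tip
  fv <- igraph::farthest_vertices(gr, weights = igraph::E(gr)$weight)
  sp <- igraph::shortest_paths(gr, from = fv$vertices[1], to = fv$vertices[2],
                               output = "vpath")$vpath[[1]]
  vi <- as.integer(sp)
  list(path = cbind(row = rows[vi], col = cols[vi]),
       degree = igraph::degree(gr)[vi])
}

# Near a flat cell end the medial axis forks into the corners, so the
# longest geodesic terminates in a corner instead of mid-edge. Trim each
# path end back to the last skeleton junction lying within `window` px
# of arc from that end; the remaining trunk tangent then points at the
# middle of the end wall, which endpoint extension reaches.
trim_terminal_branches <- function(path, degree, window) {
  n <- nrow(path)
  if (n < 5) return(path)
  arc <- c(0, cumsum(sqrt(diff(path[, "col"])^2 + diff(path[, "row"])^2)))
  total <- arc[n]
  junct <- which(degree >= 3)
  lo <- 1; hi <- n
  near_start <- junct[arc[junct] <= min(window, total / 3)]
  if (length(near_start) > 0) lo <- max(near_start)
  near_end <- junct[total - arc[junct] <= min(window, total / 3)]
  if (length(near_end) > 0) hi <- min(near_end)
  if (hi - lo + 1 < 5) return(path)
  path[lo:hi, , drop = FALSE]
}

# first intersection of ray p0 + u * dir (u > 0) with polygon; NA if none
ray_polygon_hit <- function(p0, dir, poly_x, poly_y) {
  ax <- poly_x; ay <- poly_y
  bx <- c(poly_x[-1], poly_x[1]); by <- c(poly_y[-1], poly_y[1])
  ex <- bx - ax; ey <- by - ay
  qx <- ax - p0[1]; qy <- ay - p0[2]
  det <- dir[1] * (-ey) - (-ex) * dir[2]
  u <- (qx * (-ey) - (-ex) * qy) / det
  v <- (dir[1] * qy - dir[2] * qx) / det
  ok <- is.finite(u) & is.finite(v) & v >= 0 & v < 1 & u > 1e-9
  if (!any(ok)) return(NA_real_)
  min(u[ok])
}

#' Extract the cell midline from a mask and its outline
#'
#' The mask is thinned to a one-pixel skeleton (Zhang-Suen), the
#' skeleton is reduced to its longest endpoint-to-endpoint geodesic
#' (side branches from rasterization are pruned), a cubic smoothing
#' spline of x and y against arc length is fitted to the ordered path,
#' and both curve ends are extended linearly along their end tangents
#' until they meet the outline, so the midline spans the full cell.
#'
#' @param mask A clean [binary_mask()].
#' @param contour The [trace_outline()] contour of the same mask;
#'   computed if missing.
#' @param spline_df Degrees of freedom of the smoothing spline; default
#'   scales with midline length (`clamp(L / 40, 4, 25)`).
#' @return A `midline` object: list with `raw_points` (skeleton path,
#'   tibble `x`, `y`), `curve` (tibble `s`, `x`, `y`, `tx`, `ty` sampled
#'   every ~0.5 px of arc, tangent unit vectors) and `L` (total arc
#'   length, px).
#' @export
extract_midline <- function(mask, contour = NULL, spline_df = NULL) {
  stopifnot(inherits(mask, "binary_mask"))
  if (is.null(contour)) contour <- trace_outline(mask)
  g <- mask$grid * 1L

  # elongation check via principal axes of the pixel cloud
  fg <- which(g == 1L)
  rr <- ((fg - 1) %% nrow(g)) + 1; cc <- ((fg - 1) %/% nrow(g)) + 1
  ev <- eigen(stats::cov(cbind(cc, rr)), symmetric = TRUE,
              only.values = TRUE)$values
  if (sqrt(max(ev) / max(min(ev), 1e-12)) < 1.5)
    warning("cell elongation < 1.5; midline extraction may be unreliable")

  sk <- skeleton_longest_path(thin_mask(g))
  # junction-trim window scales with the cell's inscribed half-width
  half_w_max <- max(EBImage::distmap(g))
  # corner branches at a flat end run up to ~sqrt(2) * half-width of arc
  path <- trim_terminal_branches(sk$path, sk$degree, window = 2.2 * half_w_max)
  # (row, col) -> 0-based geometry (x = col - 1, y = row - 1)
  xs <- path[, "col"] - 1; ys <- path[, "row"] - 1
  s_raw <- c(0, cumsum(sqrt(diff(xs)^2 + diff(ys)^2)))
  n <- length(xs)
  if (n >= 10) {
    if (is.null(spline_df))
      spline_df <- min(max(4, round(s_raw[n] / 40)), 25)
    spline_df <- min(spline_df, n - 1)
    fx <- stats::smooth.spline(s_raw, xs, df = spline_df)
    fy <- stats::smooth.spline(s_raw, ys, df = spline_df)
    sd_ <- seq(0, s_raw[n], by = 0.5)
    cx <- stats::predict(fx, sd_)$y
    cy <- stats::predict(fy, sd_)$y
  } else {
    sd_ <- s_raw; cx <- xs; cy <- ys
  }

  # extend both ends along their tangents to the outline
  px <- contour$points$x; py <- contour$points$y
  m <- length(sd_)
  t0 <- c(cx[1] - cx[2], cy[1] - cy[2])
  t1 <- c(cx[m] - cx[m - 1], cy[m] - cy[m - 1])
  t0 <- t0 / sqrt(sum(t0^2)); t1 <- t1 / sqrt(sum(t1^2))
  u0 <- ray_polygon_hit(c(cx[1], cy[1]), t0, px, py)
  u1 <- ray_polygon_hit(c(cx[m], cy[m]), t1, px, py)
  if (!is.na(u0)) { cx <- c(cx[1] + u0 * t0[1], cx); cy <- c(cy[1] + u0 * t0[2], cy) }
  if (!is.na(u1)) { cx <- c(cx, cx[length(cx)] + u1 * t1[1]); cy <- c(cy, cy[length(cy)] + u1 * t1[2]) }

  s <- c(0, cumsum(sqrt(diff(cx)^2 + diff(cy)^2)))
  L <- s[length(s)]
  if (L <= 0) stop("degenerate midline of zero length", call. = FALSE)
  # tangents by central differences on the resampled curve
  ix <- seq_along(cx)
  im <- pmax(ix - 1, 1); ip <- pmin(ix + 1, length(cx))
  tx <- cx[ip] - cx[im]; ty <- cy[ip] - cy[im]
  nrm <- sqrt(tx^2 + ty^2); nrm[nrm == 0] <- 1
  structure(list(
    raw_points = tibble::tibble(x = xs, y = ys),
    curve = tibble::tibble(s = s, x = cx, y = cy, tx = tx / nrm, ty = ty / nrm),
    L = L
  ), class = "midline")
}

#' @export
print.midline <- function(x, ...) {
  cat(sprintf("<midline> L = %.1f px, %d curve samples\n", x$L, nrow(x$curve)))
  invisible(x)
}

#' Measure perpendicular chord widths along the midline
#'
#' Places stations every `step_px` of arc along the midline (plus the
#' far endpoint), draws the line through each station perpendicular to
#' the local tangent, intersects it with the outline, and records the
#' distance between the nearest intersection on each side of the midline
#' as the full cell width there. Stations whose perpendicular fails to
#' cross the outline on both sides (typically at the end caps) are
#' dropped and listed in the `dropped` field.
#'
#' @param midline A [extract_midline()] result.
#' @param contour The matching [trace_outline()] contour.
#' @param step_px Arc spacing between stations (default 10 px).
#' @param cell_id Identifier stored with the profile.
#' @return A `width_profile`: list with `stations` (tibble `s`, `x`
#'   = `s / L`, `w`), `dropped` (tibble `s`, `reason`), `L`, `cell_id`
#'   and `oriented = FALSE` (see [normalize_profile()]).
#' @export
measure_widths <- function(midline, contour, step_px = 10, cell_id = "cell") {
  stopifnot(inherits(midline, "midline"), inherits(contour, "contour"),
            step_px > 0)
  L <- midline$L
  s_st <- seq(0, L, by = step_px)
  if (L - s_st[length(s_st)] > 1e-9) s_st <- c(s_st, L)

  ax <- contour$points$x; ay <- contour$points$y
  bx <- c(ax[-1], ax[1]); by <- c(ay[-1], ay[1])
  ex <- bx - ax; ey <- by - ay
  crv <- midline$curve
  chord_at <- function(s) {
    cx <- stats::approx(crv$s, crv$x, xout = s)$y
    cy <- stats::approx(crv$s, crv$y, xout = s)$y
    tx <- stats::approx(crv$s, crv$tx, xout = s)$y
    ty <- stats::approx(crv$s, crv$ty, xout = s)$y
    nrm <- sqrt(tx^2 + ty^2)
    nx <- -ty / nrm; ny <- tx / nrm
    qx <- ax - cx; qy <- ay - cy
    det <- nx * (-ey) + ex * ny
    u <- (qx * (-ey) + ex * qy) / det
    v <- (nx * qy - ny * qx) / det
    ok <- is.finite(u) & is.finite(v) & v >= 0 & v < 1
    up <- u[ok & u > 1e-9]; um <- u[ok & u < -1e-9]
    if (length(up) > 0 && length(um) > 0) min(up) - max(um) else NA_real_
  }

  w <- vapply(pmin(pmax(s_st, 0.25), L - 0.25), chord_at, 0)
  # The terminal stations sit on the outline itself. At a flat end wall
  # the chord runs almost parallel to the local boundary, and with a
  # ragged (noisy) wall the nearest intersections are wall corrugations,
  # clipping the chord. For the two end stations take, on each side, the
  # farthest intersection within a bound set by the neighbouring
  # station's width: this reads through corrugations to the true cell
  # sides, is identical at a pointed tip (only the tip crossings exist),
  # and cannot jump to a distant cell part on curved cells.
  n_st <- length(s_st)
  for (i in c(1L, n_st)) {
    w_nb <- if (i == 1L) w[2L] else w[n_st - 1L]
    if (is.na(w_nb)) next
    s0 <- if (i == 1L) 0.25 else L - 0.25
    cx <- stats::approx(crv$s, crv$x, xout = s0)$y
    cy <- stats::approx(crv$s, crv$y, xout = s0)$y
    tx <- stats::approx(crv$s, crv$tx, xout = s0)$y
    ty <- stats::approx(crv$s, crv$ty, xout = s0)$y
    nrm <- sqrt(tx^2 + ty^2)
    nx <- -ty / nrm; ny <- tx / nrm
    qx <- ax - cx; qy <- ay - cy
    det <- nx * (-ey) + ex * ny
    u <- (qx * (-ey) + ex * qy) / det
    v <- (nx * qy - ny * qx) / det
    ok <- is.finite(u) & is.finite(v) & v >= 0 & v < 1
    bound <- 0.75 * w_nb
    ip <- which(ok & u > 1e-9); im_ <- which(ok & u < -1e-9)
    if (length(ip) > 0 && length(im_) > 0) {
      pick <- function(cand, side) {
        uu <- side * u[cand] # positive magnitudes outward on this side
        inb <- uu <= bound
        if (any(inb)) cand[which.max(ifelse(inb, uu, -Inf))]
        else cand[which.min(uu)]
      }
      j_hi <- pick(ip, +1); j_lo <- pick(im_, -1)
      # a chord terminating on a contour edge nearly parallel to itself
      # lies along a flat end wall: an end-cap artifact, station dropped
      cosang <- function(j) {
        el <- sqrt(ex[j]^2 + ey[j]^2)
        abs((nx * ex[j] + ny * ey[j]) / el)
      }
      if (max(cosang(j_hi), cosang(j_lo)) <= 0.985)
        w[i] <- u[j_hi] - u[j_lo]
      else
        w[i] <- NA_real_
    }
  }
  keep <- !is.na(w) & w > 0
  if (!any(keep))
    stop("no station produced a valid perpendicular chord", call. = FALSE)
  dropped <- tibble::tibble(
    s = s_st[!keep],
    reason = rep("perpendicular does not cross both sides of the outline",
                 sum(!keep)))
  structure(list(
    stations = tibble::tibble(s = s_st[keep], x = s_st[keep] / L, w = w[keep]),
    dropped = dropped, L = L, cell_id = cell_id, oriented = FALSE
  ), class = "width_profile")
}

#' @export
print.width_profile <- function(x, ...) {
  cat(sprintf("<width_profile> %s: %d stations, L = %.1f px%s\n",
              x$cell_id, nrow(x$stations), x$L,
              if (isTRUE(x$oriented)) ", oriented" else ""))
  invisible(x)
}

#' Normalize and orient a width profile
#'
#' Sets the normalized axial coordinate `x = s / L` and orients the
#' profile so that the widest station falls in the upper half of
#' `[0, 1]`, i.e. the oral apparatus (widest point) ends up near `x = 1`
#' and the tail near `x = 0`; the station order is reversed when needed.
#' Ties for the widest station are resolved toward the larger arc
#' position, which makes the operation idempotent (a constant-width
#' cylinder profile is left as-is). Idempotent.
#'
#' @param profile A [measure_widths()] profile (>= 3 stations).
#' @return The oriented `width_profile` (`oriented = TRUE`).
#' @export
normalize_profile <- function(profile) {
  stopifnot(inherits(profile, "width_profile"))
  st <- profile$stations
  if (nrow(st) < 3)
    stop("need at least 3 stations to orient a profile", call. = FALSE)
  st$x <- st$s / profile$L
  wmax <- max(st$w)
  widest_x <- max(st$x[st$w >= wmax - 1e-9])
  if (widest_x < 0.5) {
    st$s <- profile$L - st$s
    st$x <- st$s / profile$L
    st <- st[order(st$s), ]
  }
  profile$stations <- st
  profile$oriented <- TRUE
  profile
}
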