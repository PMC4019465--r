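#' Pooled moving-average trend curve for a cohort of width profiles
#'
#' Pools the normalized stations of all member profiles, sorts them by
#' normalized position `x`, and slides a window of `2 * n_cells`
#' consecutive samples (stride 1) over the pooled scatter, averaging
#' both coordinates within the window. This is the standard
#' scatter-smoothing used to draw one width-versus-normalized-length
#' trendline per experimental group.
#'
#' @param profiles List of normalized `width_profile` objects (run
#'   [normalize_profile()] first).
#' @param group_label Label stored with the trend.
#' @param window Window size; default `2 * length(profiles)`.
#' @return A `cohort_trend`: list with `group_label`, `n_cells`,
#'   `points` (pooled tibble `x`, `w`, `cell_id`, sorted by `x`) and
#'   `trend` (tibble `x_mean`, `w_mean`).
#' @export
trend_curve <- function(profiles, group_label = "group", window = NULL) {
  stopifnot(length(profiles) >= 1,
            all(vapply(profiles, inherits, TRUE, "width_profile")))
  if (!all(vapply(profiles, function(p) isTRUE(p$oriented), TRUE)))
    stop("profiles must be normalized/oriented first", call. = FALSE)
  n_cells <- length(profiles)
  pooled <- do.call(rbind, lapply(profiles, function(p)
    tibble::tibble(x = p$stations$x, w = p$stations$w, cell_id = p$cell_id)))
  pooled <- pooled[order(pooled$x, pooled$w), ] # stable under input order
  if (is.null(window)) window <- 2L * n_cells
  window <- as.integer(window)
  if (window > nrow(pooled))
    stop(sprintf("window (%d) larger than pooled sample count (%d)",
                 window, nrow(pooled)), call. = FALSE)
  # moving average of both coordinates over the sorted pooled scatter
  cm <- function(v) {
    cs <- c(0, cumsum(v))
    (cs[(window + 1):length(cs)] - cs[1:(length(cs) - window)]) / window
  }
  structure(list(group_label = group_label, n_cells = n_cells,
                 points = pooled,
                 trend = tibble::tibble(x_mean = cm(pooled$x),
                                        w_mean = cm(pooled$w))),
            class = "cohort_trend")
}

#' @export
print.cohort_trend <- function(x, ...) {
  cat(sprintf("<cohort_trend> %s: %d cells, %d pooled points, %d trend points\n",
              x$group_label, x$n_cells, nrow(x$points), nrow(x$trend)))
  invisible(x)
}

#' Compare shape factors between two groups
#'
#' Two-sided two-sample t-test on per-cell shape factors, Welch's
#' unequal-variance form by default (group variances typically differ
#' severalfold between control and perturbed cohorts); the pooled
#' Student form is available via `method`. Standard deviations use the
#' n - 1 denominator. If both groups are constant and equal, `t = 0`
#' and `p = 1` by convention.
#'
#' @param sf_a,sf_b Numeric vectors of per-cell shape factors (n >= 2
#'   each, finite).
#' @param method `"welch"` (default) or `"student"`.
#' @param labels Length-2 character vector of group labels.
#' @return A `group_comparison`: list with per-group `mean`, `sd`, `n`,
#'   plus `t_statistic`, `dof`, `p_value` and `method`.
#' @export
compare_groups <- function(sf_a, sf_b, method = c("welch", "student"),
                           labels = c("A", "B")) {
  method <- match.arg(method)
  stopifnot(length(sf_a) >= 2, length(sf_b) >= 2,
            all(is.finite(sf_a)), all(is.finite(sf_b)))
  base <- list(
    group_a = labels[1], mean_a = mean(sf_a), sd_a = stats::sd(sf_a),
    n_a = length(sf_a),
    group_b = labels[2], mean_b = mean(sf_b), sd_b = stats::sd(sf_b),
    n_b = length(sf_b), method = method)
  if (stats::sd(sf_a) == 0 && stats::sd(sf_b) == 0 &&
      mean(sf_a) == mean(sf_b)) {
    res <- c(base, list(t_statistic = 0, dof = length(sf_a) + length(sf_b) - 2,
                        p_value = 1))
    return(structure(res, class = "group_comparison"))
  }
  tt <- stats::t.test(sf_a, sf_b, var.equal = (method == "student"))
  res <- c(base, list(t_statistic = unname(tt$statistic),
                      dof = unname(tt$parameter),
                      p_value = max(tt$p.value, .Machine$double.xmin)))
  structure(res, class = "group_comparison")
}

#' @export
print.group_comparison <- function(x, ...) {
  cat(sprintf("<group_comparison> %s: %.3f+-%.3f (n=%d) vs %s: %.3f+-%.3f (n=%d)\n",
              x$group_a, x$mean_a, x$sd_a, x$n_a,
              x$group_b, x$mean_b, x$sd_b, x$n_b))
  cat(sprintf("  %s t = %.3f, dof = %.2f, p = %.3g\n",
              x$method, x$t_statistic, x$dof, x$p_value))
  invisible(x)
}

#' Width-versus-length figure for one or more cohorts
#'
#' Draws the pooled per-station scatter (optional) with one
#' moving-average trendline per group: width against normalized cell
#' length, tail at 0, oral apparatus at 1.
#'
#' @param trends List of [trend_curve()] results.
#' @param show_points Overlay the pooled station scatter.
#' @return A ggplot object.
#' @export
plot_cohort_trends <- function(trends, show_points = FALSE) {
  stopifnot(all(vapply(trends, inherits, TRUE, "cohort_trend")))
  tr <- do.call(rbind, lapply(trends, function(t)
    tibble::tibble(group = t$group_label, x = t$trend$x_mean,
                   w = t$trend$w_mean)))
  p <- ggplot2::ggplot(tr, ggplot2::aes(x = .data$x, y = .data$w,
                                        colour = .data$group))
  if (show_points) {
    pts <- do.call(rbind, lapply(trends, function(t)
      tibble::tibble(group = t$group_label, x = t$points$x, w = t$points$w)))
    p <- p + ggplot2::geom_point(data = pts, alpha = 0.15, size = 0.6)
  }
  p + ggplot2::geom_line(linewidth = 1) +
    ggplot2::labs(x = "normalized cell length (tail = 0, OA = 1)",
                  y = "cell width (px)", colour = NULL) +
    ggplot2::theme_classic()
}

#' Mean +- SD bar chart of group shape factors
#'
#' @param sf_by_group Named list of numeric shape-factor vectors.
#' @return A ggplot object.
#' @export
plot_shape_factors <- function(sf_by_group) {
  df <- do.call(rbind, lapply(names(sf_by_group), function(g)
    tibble::tibble(group = g, mean = mean(sf_by_group[[g]]),
                   sd = stats::sd(sf_by_group[[g]]))))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$group, y = .data$mean)) +
    ggplot2::geom_col(width = 0.6, fill = "grey70", colour = "black") +
    ggplot2::geom_errorbar(ggplot2::aes(ymin = .data$mean - .data$sd,
                                        ymax = .data$mean + .data$sd),
                           width = 0.2) +
    ggplot2::labs(x = NULL, y = "shape factor") +
    ggplot2::theme_classic()
}
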