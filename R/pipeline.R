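#' Read a grayscale cell image
#'
#' Reads an 8-bit PNG or TIFF and returns a numeric matrix on the 0-255
#' scale. Multi-channel images are averaged to one channel.
#'
#' @param path Path to a `.png`, `.tif` or `.tiff` file.
#' @return Numeric matrix (rows = image rows).
#' @export
read_cell_image <- function(path) {
  ext <- tolower(tools::file_ext(path))
  img <- switch(ext,
    png = png::readPNG(path),
    tif = ,
    tiff = tiff::readTIFF(path),
    stop("unsupported image format: ", ext, call. = FALSE))
  if (length(dim(img)) == 3) img <- apply(img[, , 1:min(3, dim(img)[3]), drop = FALSE], c(1, 2), mean)
  img * 255
}

#' Run the full single-cell analysis on one image
#'
#' Composes the whole measurement chain: IsoData binarization, the
#' configured rounds of 3x3 mean-filter smoothing, reduction to a single
#' filled component, outline tracing, skeleton-based midline extraction
#' with spline fitting and endpoint extension, perpendicular chord
#' widths every `step_px`, normalization (tail = 0, OA = 1) and the
#' shape factor.
#'
#' @param image Numeric matrix (grayscale) or a [binary_mask()] to skip
#'   thresholding.
#' @param step_px Station spacing along the midline (px).
#' @param smooth_rounds Rounds of binary smoothing after thresholding.
#' @param spline_df Midline spline flexibility (`NULL` = auto).
#' @param cell_id Identifier carried through all outputs.
#' @return A `cell_analysis` list: `mask`, `contour`, `midline`,
#'   `profile` (normalized), `sf` (a `shape_factor_result`).
#' @export
analyze_cell <- function(image, step_px = 10, smooth_rounds = 2,
                         spline_df = NULL, cell_id = "cell") {
  mask <- if (inherits(image, "binary_mask")) image else binarize(image)
  mask <- smooth_binary(mask, rounds = smooth_rounds)
  mask <- clean_mask(mask)
  contour <- trace_outline(mask)
  midline <- extract_midline(mask, contour, spline_df = spline_df)
  profile <- measure_widths(midline, contour, step_px = step_px,
                            cell_id = cell_id)
  profile <- normalize_profile(profile)
  sf <- compute_shape_factor(profile)
  structure(list(mask = mask, contour = contour, midline = midline,
                 profile = profile, sf = sf, cell_id = cell_id),
            class = "cell_analysis")
}

#' Pipeline configuration
#'
#' @param groups Named list; each element a character vector of image
#'   paths and/or glob patterns defining one experimental group.
#' @param step_px Station spacing (px), default 10.
#' @param smooth_rounds Binary smoothing rounds, default 2.
#' @param spline_df Midline spline flexibility (`NULL` = auto).
#' @param pixel_size Physical units per pixel (scalar; widths and
#'   lengths in outputs are multiplied by it).
#' @param test `"welch"` or `"student"` group comparison.
#' @param outdir Output directory.
#' @param seed Integer recorded in the log (the measurement chain itself
#'   is deterministic).
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(groups, step_px = 10, smooth_rounds = 2,
                            spline_df = NULL, pixel_size = 1,
                            test = c("welch", "student"),
                            outdir = "stentorshape_out", seed = 1L) {
  test <- match.arg(test)
  stopifnot(is.list(groups), length(groups) >= 1,
            !is.null(names(groups)), all(nzchar(names(groups))),
            step_px > 0, smooth_rounds >= 0, pixel_size > 0)
  structure(list(groups = groups, step_px = step_px,
                 smooth_rounds = smooth_rounds, spline_df = spline_df,
                 pixel_size = pixel_size, test = test,
                 outdir = outdir, seed = as.integer(seed)),
            class = "pipeline_config")
}

#' Read a pipeline configuration from a YAML file
#'
#' The file may set any [pipeline_config()] field; `groups` is a named
#' mapping from group label to a path/glob or list of them.
#'
#' @param path YAML file path.
#' @return A `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  y <- yaml::read_yaml(path)
  stopifnot(!is.null(y$groups))
  y$groups <- lapply(y$groups, as.character)
  args <- y[intersect(names(y), names(formals(pipeline_config)))]
  do.call(pipeline_config, args)
}

expand_group_paths <- function(patterns) {
  out <- unlist(lapply(patterns, function(p) {
    hits <- Sys.glob(p)
    if (length(hits) == 0 && file.exists(p)) p else hits
  }))
  unique(out)
}

#' Run the end-to-end cohort pipeline
#'
#' Analyzes every image of every group, writes per-station and per-cell
#' CSVs, per-group trend CSVs, a group-comparison JSON (for the first
#' two groups), figures, and a timestamped log with per-cell provenance
#' including every dropped station or failed cell and the reason.
#' Per-cell failures are logged and skipped; the run fails only if a
#' group ends up empty. Identical configuration and inputs give
#' identical tabular outputs.
#'
#' @param config A [pipeline_config()].
#' @return A `pipeline_report`: list with `cells` (named list of
#'   `cell_analysis` by group), `shape_factors` tibble, `trends`,
#'   `comparison` (or `NULL`), `failures` tibble and `outdir`.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(config$outdir, recursive = TRUE, showWarnings = FALSE)
  log_path <- file.path(config$outdir, "run.log")
  logf <- function(...) cat(sprintf("[%s] %s\n",
                                    format(Sys.time(), "%Y-%m-%d %H:%M:%S"),
                                    sprintf(...)),
                            file = log_path, append = TRUE)
  cat("", file = log_path)
  logf("pipeline start: step_px=%g smooth_rounds=%d pixel_size=%g test=%s seed=%d",
       config$step_px, config$smooth_rounds, config$pixel_size,
       config$test, config$seed)

  cells <- list(); fail_rows <- list(); station_rows <- list()
  for (grp in names(config$groups)) {
    paths <- expand_group_paths(config$groups[[grp]])
    logf("group '%s': %d input file(s)", grp, length(paths))
    res <- list()
    for (p in paths) {
      id <- tools::file_path_sans_ext(basename(p))
      ans <- tryCatch({
        img <- read_cell_image(p)
        a <- analyze_cell(img, step_px = config$step_px,
                          smooth_rounds = config$smooth_rounds,
                          spline_df = config$spline_df, cell_id = id)
        logf("cell %s (%s): L=%.1f px, %d stations, %d dropped, SF=%.4f",
             id, p, a$profile$L, nrow(a$profile$stations),
             nrow(a$profile$dropped), a$sf$shape_factor)
        for (k in seq_len(nrow(a$profile$dropped)))
          logf("  dropped station s=%.1f: %s", a$profile$dropped$s[k],
               a$profile$dropped$reason[k])
        a
      }, error = function(e) {
        logf("cell %s (%s) FAILED: %s", id, p, conditionMessage(e))
        fail_rows[[length(fail_rows) + 1]] <<-
          tibble::tibble(group = grp, path = p, reason = conditionMessage(e))
        NULL
      })
      if (!is.null(ans)) res[[id]] <- ans
    }
    if (length(res) == 0)
      stop(sprintf("group '%s' produced no analyzable cells", grp),
           call. = FALSE)
    cells[[grp]] <- res
    station_rows[[grp]] <- do.call(rbind, lapply(res, function(a)
      tibble::tibble(group = grp, cell_id = a$cell_id,
                     s = a$profile$stations$s * config$pixel_size,
                     x = a$profile$stations$x,
                     w = a$profile$stations$w * config$pixel_size)))
  }

  sf_tbl <- do.call(rbind, lapply(names(cells), function(grp)
    do.call(rbind, lapply(cells[[grp]], function(a) {
      row <- shape_factor_row(a$sf)
      row$L <- row$L * config$pixel_size
      cbind(tibble::tibble(group = grp), row)
    }))))
  stations_tbl <- do.call(rbind, station_rows)
  utils::write.csv(stations_tbl, file.path(config$outdir, "stations.csv"),
                   row.names = FALSE)
  utils::write.csv(sf_tbl, file.path(config$outdir, "shape_factors.csv"),
                   row.names = FALSE)

  trends <- lapply(names(cells), function(grp) {
    tr <- trend_curve(lapply(cells[[grp]], `[[`, "profile"), grp)
    utils::write.csv(
      data.frame(x_mean = tr$trend$x_mean,
                 w_mean = tr$trend$w_mean * config$pixel_size),
      file.path(config$outdir, paste0("trend_", grp, ".csv")),
      row.names = FALSE)
    tr
  })
  names(trends) <- names(cells)

  comparison <- NULL
  if (length(cells) >= 2) {
    g <- names(cells)[1:2]
    comparison <- compare_groups(
      sf_tbl$shape_factor[sf_tbl$group == g[1]],
      sf_tbl$shape_factor[sf_tbl$group == g[2]],
      method = config$test, labels = g)
    jsonlite::write_json(unclass(comparison),
                         file.path(config$outdir, "comparison.json"),
                         auto_unbox = TRUE, digits = NA)
    logf("comparison %s vs %s: t=%.3f dof=%.2f p=%.3g", g[1], g[2],
         comparison$t_statistic, comparison$dof, comparison$p_value)
  }

  grDevices::pdf(NULL) # keep ggsave from opening a device in headless runs
  try({
    ggplot2::ggsave(file.path(config$outdir, "trend_curves.png"),
                    plot_cohort_trends(trends), width = 6, height = 4, dpi = 150)
    sf_groups <- split(sf_tbl$shape_factor, sf_tbl$group)
    ggplot2::ggsave(file.path(config$outdir, "shape_factors.png"),
                    plot_shape_factors(sf_groups), width = 4, height = 4,
                    dpi = 150)
  }, silent = TRUE)
  grDevices::dev.off()

  failures <- if (length(fail_rows)) do.call(rbind, fail_rows) else
    tibble::tibble(group = character(), path = character(),
                   reason = character())
  if (nrow(failures))
    utils::write.csv(failures, file.path(config$outdir, "failures.csv"),
                     row.names = FALSE)
  logf("pipeline done: %d cell(s), %d failure(s)", nrow(sf_tbl),
       nrow(failures))
  structure(list(cells = cells, shape_factors = sf_tbl,
                 stations = stations_tbl, trends = trends,
                 comparison = comparison, failures = failures,
                 config = config, outdir = config$outdir),
            class = "pipeline_report")
}

#' @export
print.pipeline_report <- function(x, ...) {
  cat(sprintf("<pipeline_report> %d group(s), %d cell(s), %d failure(s)\n",
              length(x$cells), nrow(x$shape_factors), nrow(x$failures)))
  invisible(x)
}

#' Validate a pipeline run against synthetic ground truth
#'
#' For every analyzed cell with a ground-truth JSON sidecar (written by
#' [write_silhouette()]) this tabulates the pipeline-versus-analytic
#' shape-factor error, the RMS distance from the true midline to the
#' fitted one, and the R-squared of measured station widths against the
#' true width function, and flags cells whose relative shape-factor
#' error exceeds `sf_tol`. Cells without a sidecar are skipped with a
#' log entry.
#'
#' @param report A [run_pipeline()] report.
#' @param truth_dir Directory holding `<cell_id>_truth.json` sidecars.
#' @param sf_tol Relative shape-factor tolerance for flagging (default
#'   0.03).
#' @return A tibble: `group`, `cell_id`, `sf_pipeline`, `sf_analytic`,
#'   `sf_rel_error`, `midline_rms_px`, `width_r2`, `flagged`.
#' @export
validate_against_truth <- function(report, truth_dir, sf_tol = 0.03) {
  stopifnot(inherits(report, "pipeline_report"))
  rows <- list()
  for (grp in names(report$cells)) for (a in report$cells[[grp]]) {
    tp <- file.path(truth_dir, paste0(a$cell_id, "_truth.json"))
    if (!file.exists(tp)) {
      message("no truth sidecar for ", a$cell_id, "; skipped")
      next
    }
    tr <- jsonlite::read_json(tp, simplifyVector = TRUE)
    sf_an <- tr$analytic_sf
    rel <- abs(a$sf$shape_factor - sf_an) / sf_an
    # RMS of true-midline points to the fitted curve
    mp <- tr$midline_points
    d2 <- vapply(seq_len(nrow(mp)), function(i)
      min((a$midline$curve$x - mp$x[i])^2 + (a$midline$curve$y - mp$y[i])^2),
      0)
    rms <- sqrt(mean(d2))
    # width agreement on normalized positions (orientation-robust)
    wa <- tr$width_at
    xt <- wa$s / max(wa$s)
    st <- a$profile$stations
    w_hat <- stats::approx(xt, wa$w, xout = st$x, rule = 2)$y
    w_rev <- stats::approx(xt, wa$w, xout = 1 - st$x, rule = 2)$y
    use <- if (stats::cor(st$w, w_hat) >= stats::cor(st$w, w_rev)) w_hat else w_rev
    r2 <- stats::cor(st$w, use)^2
    rows[[length(rows) + 1]] <- tibble::tibble(
      group = grp, cell_id = a$cell_id,
      sf_pipeline = a$sf$shape_factor, sf_analytic = sf_an,
      sf_rel_error = rel, midline_rms_px = rms, width_r2 = r2,
      flagged = rel > sf_tol)
  }
  if (length(rows) == 0)
    return(tibble::tibble(group = character(), cell_id = character(),
                          sf_pipeline = numeric(), sf_analytic = numeric(),
                          sf_rel_error = numeric(), midline_rms_px = numeric(),
                          width_r2 = numeric(), flagged = logical()))
  do.call(rbind, rows)
}
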