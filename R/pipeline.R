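# End-to-end orchestration: series -> segmentation -> detection ->
# per-eye metrics -> cohort statistics, plus the synthetic benchmark.

#' Pipeline configuration
#'
#' Bundles the segmentation and detection parameters with run options and
#' validates them up front (before any image is touched).
#'
#' @param segmentation [segmentation_params()].
#' @param detection [detection_params()].
#' @param class_bounds Soma-size class boundaries in um^2 (strictly
#'   increasing, length 3: isolated/non-activated, non-activated/
#'   activated, activated/complex). Only validated here; the classifier
#'   uses the study's fixed 10/50/250 boundaries.
#' @param seed Master seed for synthetic runs.
#' @param outdir Output directory for CSV tables, or `NULL`.
#' @return A list of class `"pipeline_config"`.
#' @export
pipeline_config <- function(segmentation = segmentation_params(),
                            detection = detection_params(),
                            class_bounds = c(10, 50, 250),
                            seed = 1L, outdir = NULL) {
  stopifnot(inherits(segmentation, "segmentation_params"),
            inherits(detection, "detection_params"))
  if (length(class_bounds) != 3L || any(diff(class_bounds) <= 0) ||
      any(class_bounds <= 0))
    stop("'class_bounds' must be three strictly increasing positive values")
  structure(list(segmentation = segmentation, detection = detection,
                 class_bounds = class_bounds, seed = as.integer(seed),
                 outdir = outdir),
            class = "pipeline_config")
}

#' Read a pipeline configuration from YAML
#'
#' Top-level keys `segmentation`, `detection`, `class_bounds`, `seed`,
#' `outdir`, each mapping to the corresponding [pipeline_config()]
#' argument; unknown keys (at either level) are rejected.
#'
#' @param path YAML file path.
#' @return A `"pipeline_config"`.
#' @export
read_pipeline_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  known <- c("segmentation", "detection", "class_bounds", "seed", "outdir")
  bad <- setdiff(names(cfg), known)
  if (length(bad)) stop("unknown config keys: ", paste(bad, collapse = ", "))
  seg <- do.call(segmentation_params, cfg$segmentation %||% list())
  det <- do.call(detection_params, cfg$detection %||% list())
  pipeline_config(segmentation = seg, detection = det,
                  class_bounds = cfg$class_bounds %||% c(10, 50, 250),
                  seed = cfg$seed %||% 1L, outdir = cfg$outdir)
}

#' Analyse one eye: segmentation, detection, per-eye summary
#'
#' Runs the full per-eye pipeline over every B-scan of the series:
#' ILM/RPE segmentation, VIT/RPE relative intensity, opacity detection
#' and measurement, and the pooled per-eye summary. B-scans whose
#' segmentation fails are reported and skipped; the pipeline continues
#' over the remaining B-scans.
#'
#' @param series An [eye_scan_series()].
#' @param config A [pipeline_config()].
#' @param keep_series Keep a reference to the input series on the result
#'   (needed by the plot method).
#' @return Object of class `"eye_analysis"`: list with `summary` (one-row
#'   [summarize_eye()] frame), `opacities` (per-opacity table with
#'   metadata columns), `ratios` (per-B-scan VIT/RPE), `failed_bscans`
#'   (indices), `boundaries` (per-B-scan [layer_boundaries()]).
#' @export
analyze_eye <- function(series, config = pipeline_config(),
                        keep_series = TRUE) {
  stopifnot(inherits(series, "eye_scan_series"),
            inherits(config, "pipeline_config"))
  n <- length(series$bscans)
  ratios <- rep(NA_real_, n)
  failed <- integer(0)
  boundaries <- vector("list", n)
  op_rows <- list()
  for (i in seq_len(n)) {
    b <- series$bscans[[i]]
    seg <- tryCatch(segment_bscan(b, config$segmentation),
                    error = function(e) e)
    if (inherits(seg, "error")) {
      failed <- c(failed, b$index)
      next
    }
    boundaries[[i]] <- seg$boundaries
    ratios[i] <- vit_rpe_relative_intensity(b, seg$masks)
    ops <- detect_opacities(b, seg$masks, b$calibration, config$detection)
    attr(ops, "labels") <- NULL
    if (nrow(ops)) op_rows[[length(op_rows) + 1L]] <- ops
  }
  opacities <- if (length(op_rows)) do.call(rbind, op_rows) else
    data.frame(bscan_index = integer(), label = integer(),
               n_pixels = integer(), area_um2 = numeric(),
               mean_intensity = numeric(), eccentricity = numeric(),
               orientation_deg = numeric(), centroid_col = numeric(),
               centroid_row = numeric(), size_class = character())
  if (nrow(opacities)) {
    meta <- data.frame(animal_id = series$animal_id, side = series$side,
                       group = series$group, sex = series$sex,
                       week = series$week)
    opacities <- cbind(meta[rep(1L, nrow(opacities)), , drop = FALSE],
                       opacities)
    rownames(opacities) <- NULL
  }
  summary_row <- summarize_eye(series, opacities,
                               ratios = ratios[!is.na(ratios)])
  if (!is.null(config$outdir)) {
    dir.create(config$outdir, recursive = TRUE, showWarnings = FALSE)
    stem <- sprintf("%s_%s_w%02d", series$animal_id, series$side,
                    series$week)
    write_opacity_table(opacities,
                        file.path(config$outdir,
                                  paste0("opacities_", stem, ".csv")))
    write_summary_table(summary_row,
                        file.path(config$outdir,
                                  paste0("summary_", stem, ".csv")))
  }
  structure(list(summary = summary_row, opacities = opacities,
                 ratios = ratios, failed_bscans = failed,
                 boundaries = boundaries,
                 series = if (keep_series) series else NULL),
            class = "eye_analysis")
}

#' @export
print.eye_analysis <- function(x, ...) {
  s <- x$summary
  cat(sprintf("Eye analysis: animal %s %s (%s, %s), week %d\n",
              s$animal_id, s$side, s$group, s$sex, s$week))
  cat(sprintf("  VIT/RPE relative intensity: %.4f\n", s$vit_rpe_intensity))
  cat(sprintf("  opacities: %d total, %.2f per b-scan, %.1f um^2 total area\n",
              s$n_opacities, s$mean_n_opacities, s$total_area_um2))
  if (s$n_opacities > 0) {
    pct <- unlist(s[paste0(.SIZE_CLASSES, "_pct")])
    cat("  size classes (%):",
        paste(sprintf("%s %.1f", .SIZE_CLASSES, pct), collapse = ", "), "\n")
  }
  if (length(x$failed_bscans))
    cat("  segmentation failed on", length(x$failed_bscans), "b-scan(s)\n")
  invisible(x)
}

#' @export
summary.eye_analysis <- function(object, ...) object$summary

#' Plot one analysed B-scan
#'
#' Shows the B-scan with the segmented ILM (solid) and RPE boundaries
#' (dashed) and the centroids of detected opacities.
#'
#' @param x An `"eye_analysis"` produced with `keep_series = TRUE`.
#' @param bscan_index Index of the B-scan to show (0-based, as recorded).
#' @param ... Passed to [graphics::image()].
#' @export
plot.eye_analysis <- function(x, bscan_index = 0L, ...) {
  if (is.null(x$series))
    stop("plotting requires analyze_eye(..., keep_series = TRUE)")
  i <- bscan_index + 1L
  b <- x$series$bscans[[i]]
  img <- b$pixels
  h <- nrow(img); w <- ncol(img)
  graphics::image(x = seq_len(w), y = seq_len(h),
                  z = t(img[h:1, , drop = FALSE]),
                  col = grDevices::gray.colors(256, 0, 1),
                  xlab = "lateral (px)", ylab = "axial (px)",
                  useRaster = TRUE, yaxt = "n", ...)
  graphics::axis(2, at = pretty(seq_len(h)), labels = rev(pretty(seq_len(h))))
  bd <- x$boundaries[[i]]
  if (!is.null(bd)) {
    graphics::lines(seq_len(w), h + 1 - bd$ilm, col = "yellow")
    graphics::lines(seq_len(w), h + 1 - bd$rpe_inner, col = "red", lty = 2)
    graphics::lines(seq_len(w), h + 1 - bd$rpe_outer, col = "red", lty = 2)
  }
  ops <- x$opacities
  ops <- ops[ops$bscan_index == b$index, , drop = FALSE]
  if (nrow(ops))
    graphics::points(ops$centroid_col, h + 1 - ops$centroid_row,
                     col = "cyan", cex = 1.2)
  invisible(x)
}

#' Analyse a cohort of eye series
#'
#' Applies [analyze_eye()] to every series and stacks the per-eye
#' summaries and opacity tables; optionally writes the combined CSVs and
#' runs the cohort statistics.
#'
#' @param cohort List of [eye_scan_series()] objects, or of
#'   `list(series=, truth=)` pairs as produced by [generate_cohort()].
#' @param config A [pipeline_config()]; if its `outdir` is set, combined
#'   `opacities.csv` and `summaries.csv` are written there.
#' @param run_stats Compute [cohort_stats()] on the summaries.
#' @return Object of class `"cohort_analysis"`: list with `summaries`,
#'   `opacities`, `stats` (or `NULL`), `eyes` (list of `"eye_analysis"`).
#' @export
analyze_cohort <- function(cohort, config = pipeline_config(),
                           run_stats = TRUE) {
  series_list <- lapply(cohort, function(el)
    if (inherits(el, "eye_scan_series")) el else el$series)
  eye_cfg <- config
  eye_cfg$outdir <- NULL
  eyes <- lapply(series_list, analyze_eye, config = eye_cfg,
                 keep_series = FALSE)
  summaries <- do.call(rbind, lapply(eyes, function(e) e$summary))
  opacities <- do.call(rbind, lapply(eyes, function(e) e$opacities))
  rownames(summaries) <- rownames(opacities) <- NULL
  st <- if (run_stats && length(unique(summaries$group)) > 1L)
    tryCatch(cohort_stats(summaries), error = function(e) NULL) else NULL
  if (!is.null(config$outdir)) {
    dir.create(config$outdir, recursive = TRUE, showWarnings = FALSE)
    write_opacity_table(opacities, file.path(config$outdir, "opacities.csv"))
    write_summary_table(summaries, file.path(config$outdir, "summaries.csv"))
  }
  structure(list(summaries = summaries, opacities = opacities,
                 stats = st, eyes = eyes),
            class = "cohort_analysis")
}

#' @export
print.cohort_analysis <- function(x, ...) {
  cat(sprintf("Cohort analysis: %d eye-series, groups: %s\n",
              nrow(x$summaries),
              paste(unique(x$summaries$group), collapse = ", ")))
  agg <- stats::aggregate(
    cbind(vit_rpe_intensity, mean_n_opacities, total_area_um2) ~ group,
    data = x$summaries, FUN = mean)
  print(agg, row.names = FALSE)
  if (!is.null(x$stats)) print(x$stats)
  invisible(x)
}

# one-to-one greedy IoU matching between detected and true label images
match_regions <- function(det_labels, true_labels, iou_threshold = 0.3) {
  nd <- max(det_labels); nt <- max(true_labels)
  if (nd == 0L || nt == 0L)
    return(data.frame(det = integer(), true = integer(), iou = numeric()))
  both <- det_labels > 0L & true_labels > 0L
  size_d <- tabulate(det_labels[det_labels > 0L], nd)
  size_t <- tabulate(true_labels[true_labels > 0L], nt)
  if (!any(both))
    return(data.frame(det = integer(), true = integer(), iou = numeric()))
  key <- (as.numeric(det_labels[both]) - 1) * nt +
    as.numeric(true_labels[both])
  tab <- table(key)
  k <- as.numeric(names(tab))
  d <- floor((k - 1) / nt) + 1
  t_ <- k - (d - 1) * nt
  inter <- as.numeric(tab)
  iou <- inter / (size_d[d] + size_t[t_] - inter)
  ord <- order(iou, decreasing = TRUE)
  used_d <- logical(nd); used_t <- logical(nt)
  res <- list()
  for (i in ord) {
    if (iou[i] <= iou_threshold) break
    if (used_d[d[i]] || used_t[t_[i]]) next
    used_d[d[i]] <- TRUE; used_t[t_[i]] <- TRUE
    res[[length(res) + 1L]] <- data.frame(det = d[i], true = t_[i],
                                          iou = iou[i])
  }
  if (length(res)) do.call(rbind, res) else
    data.frame(det = integer(), true = integer(), iou = numeric())
}

#' Benchmark detection against planted ground truth
#'
#' Runs segmentation + detection on a synthetic cohort and matches
#' detected regions to the planted opacities by pixel-overlap
#' (intersection-over-union above `iou_threshold`, one-to-one greedy
#' matching). Reports recall/precision, area and eccentricity errors of
#' the matched pairs, and the size-class mix error.
#'
#' @param cohort List of `list(series=, truth=)` pairs from
#'   [generate_cohort()] or [generate_series()] (a single pair is also
#'   accepted).
#' @param config A [pipeline_config()].
#' @param iou_threshold Minimum IoU for a match.
#' @param min_pixels_recall Recall is additionally reported restricted to
#'   planted opacities of at least this many pixels.
#' @param min_axis_px Eccentricity error is evaluated on matched planted
#'   opacities whose semi-minor axis is at least this many pixels.
#' @return Object of class `"benchmark_report"`: recall, recall_large,
#'   precision, median/mean area relative error, mean absolute
#'   eccentricity error, class-mix error (max absolute percentage-point
#'   difference), and counts.
#' @export
run_benchmark <- function(cohort,
                          config = pipeline_config(
                            detection = synthetic_detection_params()),
                          iou_threshold = 0.3, min_pixels_recall = 10,
                          min_axis_px = 5) {
  if (!is.null(cohort$series)) cohort <- list(cohort)
  n_true <- n_true_large <- n_det <- 0L
  n_match <- n_match_large <- 0L
  area_err <- ecc_err <- numeric(0)
  class_true <- class_det <- character(0)
  for (el in cohort) {
    series <- el$series; truths <- el$truth
    for (i in seq_along(series$bscans)) {
      b <- series$bscans[[i]]
      seg <- tryCatch(segment_bscan(b, config$segmentation),
                      error = function(e) NULL)
      if (is.null(seg)) next
      ops <- detect_opacities(b, seg$masks, b$calibration, config$detection)
      det_labels <- attr(ops, "labels")
      tr <- truths[[i]]
      n_det <- n_det + nrow(ops)
      n_true <- n_true + nrow(tr$table)
      large <- tr$table$n_pixels >= min_pixels_recall
      n_true_large <- n_true_large + sum(large)
      if (nrow(ops)) class_det <- c(class_det, ops$size_class)
      if (nrow(tr$table))
        class_true <- c(class_true, classify_size(tr$table$area_um2))
      mm <- match_regions(det_labels, tr$labels, iou_threshold)
      n_match <- n_match + nrow(mm)
      if (nrow(mm)) {
        n_match_large <- n_match_large + sum(large[mm$true])
        tt <- tr$table[mm$true, ]
        dd <- ops[mm$det, ]
        keep <- tt$n_pixels >= min_pixels_recall
        area_err <- c(area_err,
                      abs(dd$n_pixels[keep] - tt$n_pixels[keep]) /
                        tt$n_pixels[keep])
        ax <- tt$semi_minor_px >= min_axis_px
        ecc_err <- c(ecc_err,
                     abs(dd$eccentricity[ax] - tt$eccentricity[ax]))
      }
    }
  }
  class_mix_err <- if (length(class_true) && length(class_det)) {
    pt <- 100 * table(factor(class_true, .SIZE_CLASSES)) / length(class_true)
    pd <- 100 * table(factor(class_det, .SIZE_CLASSES)) / length(class_det)
    max(abs(pt - pd))
  } else NA_real_
  structure(list(
    recall = if (n_true) n_match / n_true else NA_real_,
    recall_large = if (n_true_large) n_match_large / n_true_large else NA_real_,
    precision = if (n_det) n_match / n_det else NA_real_,
    area_rel_error_median = if (length(area_err)) stats::median(area_err) else NA_real_,
    area_rel_error_mean = if (length(area_err)) mean(area_err) else NA_real_,
    ecc_error_mean = if (length(ecc_err)) mean(ecc_err) else NA_real_,
    class_mix_error_pts = class_mix_err,
    n_true = n_true, n_true_large = n_true_large,
    n_detected = n_det, n_matched = n_match),
    class = "benchmark_report")
}

#' @export
print.benchmark_report <- function(x, ...) {
  cat("Synthetic detection benchmark\n")
  cat(sprintf("  planted: %d (%d large), detected: %d, matched: %d\n",
              x$n_true, x$n_true_large, x$n_detected, x$n_matched))
  cat(sprintf("  recall %.3f (large-only %.3f), precision %.3f\n",
              x$recall, x$recall_large, x$precision))
  cat(sprintf("  area rel. error: median %.3f, mean %.3f\n",
              x$area_rel_error_median, x$area_rel_error_mean))
  cat(sprintf("  eccentricity error (mean abs): %.4f\n", x$ecc_error_mean))
  cat(sprintf("  class-mix error: %.2f percentage points\n",
              x$class_mix_error_pts))
  invisible(x)
}
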