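# Per-B-scan and per-eye vitreous metrics: VIT/RPE relative intensity,
# soma-size classification, and per-eye longitudinal summaries.

.SIZE_CLASSES <- c("isolated", "non_activated", "activated", "complex")

#' VIT/RPE relative intensity of one B-scan
#'
#' Mean grayscale intensity over the vitreous mask divided by the mean
#' over the RPE mask — the turbidity/inflammation proxy of vitreous OCT
#' imaging.
#'
#' @param bscan A [bscan()] or numeric matrix.
#' @param masks `"region_masks"` from [build_masks()].
#' @return Scalar ratio.
#' @export
vit_rpe_relative_intensity <- function(bscan, masks) {
  img <- .pixels_of(bscan)
  if (!any(masks$vitreous)) stop("empty vitreous mask")
  if (!any(masks$rpe)) stop("empty RPE mask")
  rpe_mean <- mean(img[masks$rpe])
  if (rpe_mean == 0) stop("zero mean RPE intensity")
  mean(img[masks$vitreous]) / rpe_mean
}

#' Per-eye VIT/RPE relative intensity
#'
#' The eye-level value is the arithmetic mean of the per-B-scan ratios
#' (61 B-scans in the study protocol).
#'
#' @param ratios Numeric vector of per-B-scan VIT/RPE ratios.
#' @return Scalar mean ratio.
#' @export
eye_relative_intensity <- function(ratios) {
  if (length(ratios) == 0L) stop("need at least one b-scan ratio")
  mean(ratios)
}

#' Soma-size activation class of an opacity
#'
#' Classifies areas into the four soma-size classes used for
#' microglia/hyalocyte activation staging: isolated (< 10 um^2),
#' non-activated (10-50 um^2, right-open), activated (50-250 um^2, both
#' ends included), complexes (> 250 um^2). The four intervals partition
#' the positive reals.
#'
#' @param area_um2 Numeric vector of positive areas in square microns.
#' @return Character vector of class labels.
#' @export
classify_size <- function(area_um2) {
  if (length(area_um2) == 0L) return(character(0))
  if (any(!is.finite(area_um2) | area_um2 <= 0))
    stop("areas must be positive")
  ifelse(area_um2 < 10, "isolated",
         ifelse(area_um2 < 50, "non_activated",
                ifelse(area_um2 <= 250, "activated", "complex")))
}

# arithmetic mean of signed orientations, or the circular mean on the
# doubled angle (axial data), as configured
.mean_orientation <- function(deg, circular = FALSE) {
  if (length(deg) == 0L) return(NA_real_)
  if (!circular) return(mean(deg))
  a <- 2 * deg * pi / 180
  m <- atan2(mean(sin(a)), mean(cos(a))) / 2 * 180 / pi
  if (m <= -90) m + 180 else m
}

#' Summarize one eye over its B-scan series
#'
#' Pools the opacities of all B-scans of the series and computes the
#' per-eye metrics: VIT/RPE relative intensity (mean of the supplied
#' per-B-scan ratios), mean opacity count per B-scan, total opacity area,
#' and per soma-size class the count, percentage of all opacities, and
#' mean area/intensity/eccentricity/orientation. Orientation is averaged
#' as signed degrees by default, so opposed orientations cancel.
#'
#' @param series An [eye_scan_series()] (for the metadata and B-scan
#'   count).
#' @param opacities Data frame of pooled opacity records for the series
#'   (rows as returned by [detect_opacities()]).
#' @param ratios Optional numeric vector of per-B-scan VIT/RPE ratios.
#' @param circular_orientation Use the circular (axial) mean for
#'   orientations instead of the arithmetic mean of signed degrees.
#' @return One-row data frame (`"eye_summary"`): metadata columns, then
#'   `n_bscans`, `vit_rpe_intensity`, `n_opacities`, `mean_n_opacities`,
#'   `total_area_um2`, and `<class>_count`, `<class>_pct`,
#'   `<class>_mean_area_um2`, `<class>_mean_intensity`,
#'   `<class>_mean_eccentricity`, `<class>_mean_orientation_deg` for each
#'   of the four classes. Empty classes have count 0 and missing means.
#' @export
summarize_eye <- function(series, opacities, ratios = NULL,
                          circular_orientation = FALSE) {
  stopifnot(inherits(series, "eye_scan_series"))
  n_bscans <- length(series$bscans)
  n_op <- if (is.null(opacities)) 0L else nrow(opacities)
  out <- data.frame(animal_id = series$animal_id, side = series$side,
                    group = series$group, sex = series$sex,
                    week = series$week, n_bscans = n_bscans,
                    vit_rpe_intensity = if (length(ratios) == 0L)
                      NA_real_ else eye_relative_intensity(ratios),
                    n_opacities = n_op,
                    mean_n_opacities = n_op / n_bscans,
                    total_area_um2 = if (n_op) sum(opacities$area_um2) else 0)
  for (cl in .SIZE_CLASSES) {
    sub <- if (n_op) opacities[opacities$size_class == cl, , drop = FALSE]
      else NULL
    k <- if (is.null(sub)) 0L else nrow(sub)
    out[[paste0(cl, "_count")]] <- k
    out[[paste0(cl, "_pct")]] <- if (n_op) 100 * k / n_op else NA_real_
    out[[paste0(cl, "_mean_area_um2")]] <- if (k) mean(sub$area_um2) else NA_real_
    out[[paste0(cl, "_mean_intensity")]] <- if (k) mean(sub$mean_intensity) else NA_real_
    out[[paste0(cl, "_mean_eccentricity")]] <- if (k) mean(sub$eccentricity) else NA_real_
    out[[paste0(cl, "_mean_orientation_deg")]] <- if (k)
      .mean_orientation(sub$orientation_deg, circular_orientation) else NA_real_
  }
  class(out) <- c("eye_summary", "data.frame")
  out
}
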