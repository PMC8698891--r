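# Layer segmentation: per-column ILM and RPE-band boundaries, and the
# vitreous / RPE masks derived from them.

#' Segmentation parameters
#'
#' Tunable parameters of the column-wise boundary finder.
#'
#' @param smooth_window Axial moving-average window (pixels, odd).
#' @param k_sd ILM detection threshold: background median plus `k_sd`
#'   robust (MAD-based) background standard deviations.
#' @param min_run Number of consecutive above-threshold (smoothed) samples
#'   required to call the retina. The default, 20, exceeds the axial
#'   extent of any single opacity so bright vitreous cells cannot capture
#'   the boundary.
#' @param bg_rows Number of top image rows used to estimate the vitreous
#'   background; `NULL` uses 10% of the height (at least 5 rows).
#' @param guard_offset_px Rows skipped below the ILM before searching for
#'   the RPE peak.
#' @param median_width Width (columns, odd) of the median filter applied
#'   to each boundary curve.
#' @param rpe_min_contrast Minimum peak elevation above the sub-ILM median
#'   intensity for a column's RPE peak to count.
#' @return A list of class `"segmentation_params"`.
#' @export
segmentation_params <- function(smooth_window = 5, k_sd = 3, min_run = 20,
                                bg_rows = NULL, guard_offset_px = 20,
                                median_width = 15, rpe_min_contrast = 40) {
  structure(list(smooth_window = smooth_window, k_sd = k_sd,
                 min_run = min_run, bg_rows = bg_rows,
                 guard_offset_px = guard_offset_px,
                 median_width = median_width,
                 rpe_min_contrast = rpe_min_contrast),
            class = "segmentation_params")
}

# moving average down each column, window shrinking at the edges
smooth_cols <- function(img, w) {
  if (w <= 1L) return(img)
  h <- nrow(img)
  half <- (w - 1L) %/% 2L
  cs <- apply(img, 2, cumsum)
  if (!is.matrix(cs)) cs <- matrix(cs, nrow = h)
  hi <- pmin(h, seq_len(h) + half)
  lo <- pmax(1L, seq_len(h) - half)
  (cs[hi, , drop = FALSE] - rbind(0, cs)[lo, , drop = FALSE]) /
    (hi - lo + 1)
}

# odd-width median filter with endpoint rule "keep"; returns numeric
median_filter <- function(x, width) {
  if (width <= 1L || length(x) < 3L) return(x)
  k <- min(width, length(x) - (length(x) + 1) %% 2)
  if (k %% 2L == 0L) k <- k - 1L
  if (k < 3L) return(x)
  stats::runmed(x, k, endrule = "keep")
}

# linear interpolation over NA entries; error when everything failed
interpolate_na <- function(x, what) {
  ok <- !is.na(x)
  if (!any(ok)) stop("segmentation failed: ", what)
  if (all(ok)) return(x)
  stats::approx(which(ok), x[ok], xout = seq_along(x), rule = 2)$y
}

.pixels_of <- function(x) if (inherits(x, "bscan")) x$pixels else x

#' Locate the internal limiting membrane per column
#'
#' Scanning each column downward, the ILM is called at the first axial
#' position where the axially smoothed intensity exceeds the robust
#' vitreous background level (median plus `k_sd` MAD-based standard
#' deviations, so bright cells crossing the top rows do not inflate the
#' estimate) for at least `min_run`
#' consecutive samples (so isolated bright opacities do not trigger), then
#' refined to the first raw above-threshold pixel near the run start.
#' The background is estimated from the top image rows. Failed columns
#' are filled by linear interpolation and the curve is median-filtered
#' across columns.
#'
#' @param bscan A [bscan()] or a numeric intensity matrix.
#' @param params [segmentation_params()].
#' @return Integer vector of per-column ILM rows (first retina row).
#' @export
find_ilm <- function(bscan, params = segmentation_params()) {
  img <- .pixels_of(bscan)
  h <- nrow(img); w <- ncol(img)
  if (h < 4L || w < 1L) stop("image too small to segment")
  nbg <- params$bg_rows %||% max(5L, round(0.1 * h))
  bg <- img[seq_len(min(nbg, h - 1L)), , drop = FALSE]
  # robust location/scale: bright opacities crossing the top rows must not
  # inflate the background estimate
  thr <- stats::median(bg) + params$k_sd * stats::mad(bg)
  sm <- smooth_cols(img, params$smooth_window)
  m <- min(params$min_run, h - 1L)
  above <- sm > thr
  rs <- apply(above, 2, cumsum)
  if (!is.matrix(rs)) rs <- matrix(rs, nrow = h)
  runm <- rs
  if (h > m) runm[(m + 1):h, ] <- rs[(m + 1):h, , drop = FALSE] -
      rs[1:(h - m), , drop = FALSE]
  hit <- runm == m
  if (m > 1L) hit[seq_len(m - 1L), ] <- FALSE
  found <- colSums(hit) > 0L
  if (!any(found)) stop("segmentation failed: no ILM crossing in any column")
  first_hit <- max.col(t(hit), ties.method = "first")
  half <- (params$smooth_window - 1L) %/% 2L
  ilm <- rep(NA_real_, w)
  for (cc in which(found)) {
    start <- first_hit[cc] - m + 1L
    lo <- max(1L, start - half)
    hi <- min(h, start + half + m)
    raw_hit <- which(img[lo:hi, cc] > thr)
    ilm[cc] <- if (length(raw_hit)) lo + raw_hit[1L] - 1L else start
  }
  ilm <- interpolate_na(ilm, "no ILM crossing")
  ilm <- median_filter(ilm, params$median_width)
  pmin(pmax(as.integer(round(ilm)), 1L), h)
}

#' Locate the RPE band per column
#'
#' Below `ilm + guard_offset_px` the RPE is taken as the brightest
#' (smoothed) axial position; the inner and outer boundaries are the
#' nearest rows above/below the peak where the smoothed intensity falls
#' below half the peak elevation over the sub-ILM median intensity.
#' Curves are median-filtered and failed columns interpolated as for the
#' ILM.
#'
#' @param bscan A [bscan()] or numeric matrix.
#' @param ilm Per-column ILM rows from [find_ilm()].
#' @param params [segmentation_params()].
#' @return List with integer vectors `inner` and `outer`.
#' @export
find_rpe_band <- function(bscan, ilm, params = segmentation_params()) {
  img <- .pixels_of(bscan)
  h <- nrow(img); w <- ncol(img)
  sm <- smooth_cols(img, params$smooth_window)
  sub_mask <- matrix(seq_len(h), h, w) >= matrix(ilm, h, w, byrow = TRUE)
  ref <- stats::median(img[sub_mask])
  inner <- outer_ <- rep(NA_real_, w)
  for (cc in seq_len(w)) {
    from <- min(h, ilm[cc] + params$guard_offset_px)
    rows <- from:h
    if (length(rows) < 2L) next
    s <- sm[rows, cc]
    pk <- which.max(s)
    peak_val <- s[pk]
    if (peak_val - ref < params$rpe_min_contrast) next
    halflev <- ref + (peak_val - ref) / 2
    p <- rows[pk]
    i <- p
    while (i > 1L && sm[i - 1L, cc] >= halflev) i <- i - 1L
    o <- p
    while (o < h && sm[o + 1L, cc] >= halflev) o <- o + 1L
    inner[cc] <- i
    outer_[cc] <- o
  }
  if (!any(!is.na(inner)))
    stop("segmentation failed: no RPE band found below the ILM")
  inner <- median_filter(interpolate_na(inner, "no RPE band"),
                         params$median_width)
  outer_ <- median_filter(interpolate_na(outer_, "no RPE band"),
                          params$median_width)
  inner <- pmin(pmax(as.integer(round(inner)), 1L), h)
  outer_ <- pmax(pmin(pmax(as.integer(round(outer_)), 1L), h), inner)
  if (any(ilm >= inner))
    stop("segmentation failed: ILM at or below the RPE inner boundary")
  list(inner = inner, outer = outer_)
}

#' Per-column layer boundaries
#'
#' @param ilm,rpe_inner,rpe_outer Integer vectors of per-column axial
#'   indices satisfying `0 < ilm < rpe_inner <= rpe_outer <= height`.
#' @param height Image height the boundaries refer to.
#' @return An object of class `"layer_boundaries"`.
#' @export
layer_boundaries <- function(ilm, rpe_inner, rpe_outer, height) {
  if (length(ilm) != length(rpe_inner) ||
      length(ilm) != length(rpe_outer))
    stop("boundary vectors must have equal length")
  if (!all(ilm >= 1 & ilm < rpe_inner & rpe_inner <= rpe_outer &
           rpe_outer <= height))
    stop("boundary ordering violated: need ilm < rpe_inner <= rpe_outer <= height")
  structure(list(ilm = as.integer(ilm), rpe_inner = as.integer(rpe_inner),
                 rpe_outer = as.integer(rpe_outer),
                 height = as.integer(height)),
            class = "layer_boundaries")
}

#' Build vitreous and RPE masks from boundaries
#'
#' The vitreous mask holds rows strictly above the ILM per column (the
#' ILM row itself is retina); the RPE mask holds rows between the inner
#' and outer boundaries inclusive. The two masks are disjoint by
#' construction.
#'
#' @param boundaries A [layer_boundaries()].
#' @param width Image width (columns).
#' @return List of class `"region_masks"` with logical matrices
#'   `vitreous` and `rpe`.
#' @export
build_masks <- function(boundaries, width = length(boundaries$ilm)) {
  stopifnot(inherits(boundaries, "layer_boundaries"))
  h <- boundaries$height
  rows <- matrix(seq_len(h), h, width)
  vit <- rows < matrix(boundaries$ilm, h, width, byrow = TRUE)
  rpe <- rows >= matrix(boundaries$rpe_inner, h, width, byrow = TRUE) &
    rows <= matrix(boundaries$rpe_outer, h, width, byrow = TRUE)
  structure(list(vitreous = vit, rpe = rpe), class = "region_masks")
}

#' Segment one B-scan
#'
#' Runs [find_ilm()] and [find_rpe_band()] and assembles the boundaries
#' and masks.
#'
#' @param bscan A [bscan()] or numeric matrix.
#' @param params [segmentation_params()].
#' @return List with `boundaries` (a [layer_boundaries()]) and `masks`
#'   (from [build_masks()]).
#' @export
segment_bscan <- function(bscan, params = segmentation_params()) {
  img <- .pixels_of(bscan)
  ilm <- find_ilm(img, params)
  rpe <- find_rpe_band(img, ilm, params)
  b <- layer_boundaries(ilm, rpe$inner, rpe$outer, nrow(img))
  list(boundaries = b, masks = build_masks(b, ncol(img)))
}
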