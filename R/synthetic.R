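# Synthetic B-scan and cohort generator with exact planted ground truth.
# Scenes emulate the anatomy the analysis assumes: dark speckled vitreous on
# top, a mid-gray retina band below the ILM, a bright RPE band, and bright
# elliptical opacities planted strictly above the ILM.

# evaluate expr under a local RNG seeded with `seed`, restoring global state
with_seed <- function(seed, expr) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_seed) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}

# counter-scheme child seeds: master -> per-eye -> per-b-scan, all < 2^31-1
derive_seed <- function(seed, k) {
  as.integer((as.numeric(seed) * 69069 + as.numeric(k)) %% 2147483647)
}

#' Specification of one planted elliptical opacity
#'
#' @param center_col,center_row Ellipse centre in pixel coordinates
#'   (column = lateral, row = axial, row index increasing downward).
#' @param semi_major_px,semi_minor_px Semi-axes in pixels,
#'   `semi_major_px >= semi_minor_px > 0`.
#' @param orientation_deg Major-axis angle in degrees in (-90, 90],
#'   0 = horizontal, positive counterclockwise (toward decreasing row).
#' @param intensity Mean gray level of the opacity, above the vitreous
#'   background and at most 255.
#' @return An object of class `"opacity_spec"`.
#' @export
opacity_spec <- function(center_col, center_row, semi_major_px,
                         semi_minor_px, orientation_deg = 0,
                         intensity = 150) {
  if (semi_minor_px <= 0 || semi_major_px < semi_minor_px)
    stop("need semi_major_px >= semi_minor_px > 0")
  if (orientation_deg <= -90 || orientation_deg > 90)
    stop("orientation_deg must lie in (-90, 90]")
  if (intensity <= 0 || intensity > 255)
    stop("intensity must lie in (0, 255]")
  structure(list(center_col = center_col, center_row = center_row,
                 semi_major_px = semi_major_px,
                 semi_minor_px = semi_minor_px,
                 orientation_deg = orientation_deg,
                 intensity = intensity),
            class = "opacity_spec")
}

#' Rasterize an elliptical opacity
#'
#' A pixel belongs to the ellipse iff its centre satisfies the (rotated)
#' ellipse inequality, boundary included. This simple rule is the planted
#' ground truth that detection accuracy is judged against.
#'
#' @param spec An [opacity_spec()].
#' @param width,height Image dimensions in pixels.
#' @return Two-column integer matrix of (row, col) pixel coordinates
#'   (1-based).
#' @export
rasterize_ellipse <- function(spec, width, height) {
  a <- spec$semi_major_px; b <- spec$semi_minor_px
  th <- spec$orientation_deg * pi / 180
  r0 <- spec$center_row; c0 <- spec$center_col
  rr <- max(1L, floor(r0 - a)):min(height, ceiling(r0 + a))
  cc <- max(1L, floor(c0 - a)):min(width, ceiling(c0 + a))
  dx <- rep(cc - c0, each = length(rr))
  dy <- rep(rr - r0, times = length(cc))
  # y-up convention: image row increases downward
  u <- dx * cos(th) + dy * sin(th)
  v <- -dx * sin(th) + dy * cos(th)
  inside <- (u / a)^2 + (v / b)^2 <= 1
  out <- cbind(row = rep(rr, times = length(cc))[inside],
               col = rep(cc, each = length(rr))[inside])
  if (nrow(out) == 0L) {
    # sub-pixel ellipse whose centre falls between pixel centres: plant
    # the nearest pixel so every specified opacity occupies >= 1 px
    out <- cbind(row = min(max(1L, round(r0)), height),
                 col = min(max(1L, round(c0)), width))
  }
  out
}

#' Specification of a synthetic B-scan scene
#'
#' Describes the noiseless anatomy: per-column ILM row (rows strictly above
#' it are vitreous), the RPE band, the three layer intensity levels, a
#' multiplicative gamma speckle model, and planted opacities.
#'
#' @param width,height Image size in pixels.
#' @param ilm_row Scalar or per-column vector: first retina row per column.
#' @param rpe_inner,rpe_outer Scalar or per-column vectors delimiting the
#'   bright RPE band (inclusive). Defaults put a flat ILM at 40% of the
#'   height and an 8-px RPE band near 85%.
#' @param vitreous_level,retina_level,rpe_level Gray levels of the three
#'   compartments.
#' @param speckle_shape Shape parameter of the multiplicative gamma speckle
#'   (mean 1, variance 1/shape); `Inf` disables noise. The default, 25
#'   (20% intensity SD), emulates the residual speckle of frame-averaged
#'   Spectralis acquisition; small values (2-4) emulate raw single-frame
#'   speckle.
#' @param opacities List of [opacity_spec()] objects.
#' @return An object of class `"scene_spec"`.
#' @export
scene_spec <- function(width = 1536, height = 496,
                       ilm_row = round(0.4 * height),
                       rpe_inner = round(0.85 * height) - 4,
                       rpe_outer = round(0.85 * height) + 3,
                       vitreous_level = 25, retina_level = 110,
                       rpe_level = 230, speckle_shape = 25,
                       opacities = list()) {
  expand <- function(x) if (length(x) == 1L) rep(x, width) else x
  ilm_row <- expand(ilm_row); rpe_inner <- expand(rpe_inner)
  rpe_outer <- expand(rpe_outer)
  if (length(ilm_row) != width || length(rpe_inner) != width ||
      length(rpe_outer) != width)
    stop("boundary vectors must have one entry per column")
  if (!all(ilm_row > 0 & ilm_row < rpe_inner & rpe_inner <= rpe_outer &
           rpe_outer <= height))
    stop("need 0 < ilm_row < rpe_inner <= rpe_outer <= height per column")
  if (length(opacities) &&
      !all(vapply(opacities, inherits, logical(1), "opacity_spec")))
    stop("'opacities' must be a list of opacity_spec objects")
  structure(list(width = as.integer(width), height = as.integer(height),
                 ilm_row = ilm_row, rpe_inner = rpe_inner,
                 rpe_outer = rpe_outer, vitreous_level = vitreous_level,
                 retina_level = retina_level, rpe_level = rpe_level,
                 speckle_shape = speckle_shape, opacities = opacities),
            class = "scene_spec")
}

#' Render one synthetic B-scan with ground truth
#'
#' Builds the noiseless layered image, stamps the planted opacities at
#' their specified intensity, records the ground-truth label mask *before*
#' noise, then applies multiplicative gamma speckle and quantizes to
#' 8-bit. Identical seeds give bit-identical images.
#'
#' @param scene A [scene_spec()].
#' @param calibration An [oct_calibration()].
#' @param seed Integer seed for the speckle.
#' @param index B-scan index recorded on the output.
#' @return List with elements `bscan` (a [bscan()]) and `truth`: a list
#'   with `labels` (integer matrix, 0 = background) and `table` (one row
#'   per planted opacity: label, n_pixels, area_um2, mean_intensity,
#'   eccentricity, orientation_deg, center_col, center_row, semi_major_px,
#'   semi_minor_px).
#' @export
render_bscan <- function(scene, calibration = default_calibration(),
                         seed = 0L, index = 0L) {
  stopifnot(inherits(scene, "scene_spec"))
  h <- scene$height; w <- scene$width
  img <- matrix(scene$vitreous_level, h, w)
  row_idx <- matrix(seq_len(h), h, w)
  ilm <- matrix(scene$ilm_row, h, w, byrow = TRUE)
  img[row_idx >= ilm] <- scene$retina_level
  inner <- matrix(scene$rpe_inner, h, w, byrow = TRUE)
  outer <- matrix(scene$rpe_outer, h, w, byrow = TRUE)
  img[row_idx >= inner & row_idx <= outer] <- scene$rpe_level

  labels <- matrix(0L, h, w)
  n_op <- length(scene$opacities)
  tab <- vector("list", n_op)
  for (i in seq_len(n_op)) {
    sp <- scene$opacities[[i]]
    px <- rasterize_ellipse(sp, w, h)
    if (nrow(px) == 0L)
      stop("opacity ", i, " rasterizes to zero pixels")
    if (any(px[, "row"] >= scene$ilm_row[px[, "col"]]))
      stop("opacity ", i, " extends outside the vitreous (below the ILM)")
    idx <- px[, "row"] + (px[, "col"] - 1L) * h
    if (any(labels[idx] != 0L))
      stop("opacity ", i, " overlaps an earlier opacity")
    labels[idx] <- i
    img[idx] <- sp$intensity
    ab <- c(sp$semi_major_px, sp$semi_minor_px)
    tab[[i]] <- data.frame(
      label = i, n_pixels = nrow(px),
      area_um2 = nrow(px) * calibration$pixel_area_um2,
      mean_intensity = sp$intensity,
      eccentricity = sqrt(1 - (ab[2] / ab[1])^2),
      orientation_deg = sp$orientation_deg,
      center_col = sp$center_col, center_row = sp$center_row,
      semi_major_px = ab[1], semi_minor_px = ab[2])
  }
  truth_table <- if (n_op) do.call(rbind, tab) else
    data.frame(label = integer(), n_pixels = integer(),
               area_um2 = numeric(), mean_intensity = numeric(),
               eccentricity = numeric(), orientation_deg = numeric(),
               center_col = numeric(), center_row = numeric(),
               semi_major_px = numeric(), semi_minor_px = numeric())

  if (is.finite(scene$speckle_shape)) {
    noise <- with_seed(seed, matrix(
      stats::rgamma(h * w, shape = scene$speckle_shape,
                    rate = scene$speckle_shape), h, w))
    img <- img * noise
  }
  img <- pmin(pmax(round(img), 0), 255)
  list(bscan = bscan(img, index = index, calibration = calibration),
       truth = list(labels = labels, table = truth_table))
}

#' Distributional model for planted opacities
#'
#' Describes how opacities are drawn for each B-scan of a synthetic
#' series: the per-B-scan count distribution, the soma-size class mix,
#' and the intensity/eccentricity/orientation distributions.
#'
#' Defaults follow the regimes reported for the rat glaucoma study:
#' control eyes carry 10-20 opacities per B-scan and glaucomatous eyes
#' fluctuate around a mean of 70 (see [glaucoma_opacity_model()] /
#' [control_opacity_model()]).
#'
#' @param count Per-B-scan count distribution: `list("fixed", n)`,
#'   `list("uniform", min, max)` (discrete) or `list("poisson", lambda)`.
#' @param class_probs Probabilities of the four soma-size classes
#'   (isolated, non_activated, activated, complex); must sum to 1. Areas
#'   are drawn uniformly within each class interval (complexes up to
#'   `complex_max_um2`), intersected with `[min_area_um2, Inf)`.
#' @param size_unit `"um2"` (default) draws areas in square microns using
#'   the calibration; `"px"` draws pixel areas directly on the same
#'   numeric intervals (useful for low-resolution benchmark profiles).
#' @param min_area_um2 Smallest target area; at least one pixel is always
#'   planted.
#' @param complex_max_um2 Upper bound of the complex-class areas.
#' @param intensity_mean,intensity_sd Normal distribution of opacity mean
#'   intensity, truncated to `[intensity_min, 255]`.
#' @param intensity_min Lower truncation; the default, 125, is five times
#'   the default vitreous background of 25.
#' @param ecc_range Planted eccentricities are drawn uniformly in this
#'   range (the study reports 0.85-1 for most cells).
#' @param orientation_range Planted major-axis angles are drawn uniformly
#'   in this range of degrees (within (-90, 90]).
#' @param ilm_margin_px Minimum gap, in pixels, kept between an opacity
#'   and the ILM.
#' @param size_scale Multiplier applied to every sampled area (used by
#'   downscaled benchmark profiles).
#' @param min_sep_px Minimum clearance, in pixels, between the bounding
#'   circles of planted opacities (placement is rejection-sampled).
#' @return An object of class `"opacity_model"`.
#' @export
opacity_model <- function(count = list("uniform", 10, 20),
                          class_probs = c(isolated = 0.05,
                                          non_activated = 0.55,
                                          activated = 0.30,
                                          complex = 0.10),
                          size_unit = c("um2", "px"),
                          min_area_um2 = 4,
                          complex_max_um2 = 600,
                          intensity_mean = 160, intensity_sd = 25,
                          intensity_min = 125,
                          ecc_range = c(0.80, 0.97),
                          orientation_range = c(-90, 90),
                          ilm_margin_px = 4,
                          size_scale = 1, min_sep_px = 5) {
  size_unit <- match.arg(size_unit)
  if (abs(sum(class_probs) - 1) > 1e-9 || any(class_probs < 0))
    stop("'class_probs' must be non-negative and sum to 1")
  if (length(class_probs) != 4L)
    stop("'class_probs' needs one probability per soma-size class")
  if (!count[[1]] %in% c("fixed", "uniform", "poisson"))
    stop("unknown count distribution: ", count[[1]])
  structure(list(count = count, class_probs = class_probs,
                 size_unit = size_unit, min_area_um2 = min_area_um2,
                 complex_max_um2 = complex_max_um2,
                 intensity_mean = intensity_mean,
                 intensity_sd = intensity_sd,
                 intensity_min = intensity_min,
                 ecc_range = ecc_range,
                 orientation_range = orientation_range,
                 ilm_margin_px = ilm_margin_px,
                 size_scale = size_scale, min_sep_px = min_sep_px),
            class = "opacity_model")
}

#' @rdname opacity_model
#' @export
control_opacity_model <- function() opacity_model()

#' @rdname opacity_model
#' @export
glaucoma_opacity_model <- function() {
  # ~70 opacities per b-scan, 40-50% activated (50-250 um^2)
  opacity_model(count = list("poisson", 70),
                class_probs = c(isolated = 0.10, non_activated = 0.38,
                                activated = 0.45, complex = 0.07))
}

.sample_count <- function(count) {
  switch(count[[1]],
         fixed = count[[2]],
         uniform = sample(count[[2]]:count[[3]], 1L),
         poisson = stats::rpois(1L, count[[2]]))
}

.CLASS_BOUNDS <- list(isolated = c(0, 10), non_activated = c(10, 50),
                      activated = c(50, 250), complex = c(250, NA))

# draw one opacity spec; RNG must already be seeded by the caller
.sample_opacity <- function(model, scene, calibration, placed) {
  px_area <- if (model$size_unit == "um2") calibration$pixel_area_um2 else 1
  cls <- sample(4L, 1L, prob = model$class_probs)
  b0 <- .CLASS_BOUNDS[[cls]]
  if (is.na(b0[2])) b0[2] <- model$complex_max_um2
  b0[1] <- max(b0[1], model$min_area_um2)
  area <- stats::runif(1L, b0[1], b0[2]) * model$size_scale
  n_px <- max(1.2, area / px_area)
  ecc <- stats::runif(1L, model$ecc_range[1], model$ecc_range[2])
  q <- sqrt(1 - ecc^2)                      # axis ratio b/a
  a <- sqrt(n_px / (pi * q))
  b <- max(0.55, a * q)                     # keep at least ~1 px thick
  a <- max(a, b)
  th <- stats::runif(1L, model$orientation_range[1], model$orientation_range[2])
  intensity <- min(255, max(model$intensity_min,
                            stats::rnorm(1L, model$intensity_mean,
                                         model$intensity_sd)))
  margin <- model$ilm_margin_px
  for (try in 1:40) {
    c0 <- stats::runif(1L, a + 2, scene$width - a - 1)
    top_limit <- a + 2
    bot_limit <- min(scene$ilm_row) - margin - a
    if (bot_limit <= top_limit) return(NULL)
    r0 <- stats::runif(1L, top_limit, bot_limit)
    ok <- TRUE
    if (nrow(placed)) {
      d <- sqrt((placed[, 1] - c0)^2 + (placed[, 2] - r0)^2)
      ok <- all(d > placed[, 3] + a + model$min_sep_px)
    }
    if (ok)
      return(list(spec = opacity_spec(c0, r0, a, b, th, intensity),
                  radius = a))
  }
  NULL
}

#' Generate a synthetic per-eye B-scan series with ground truth
#'
#' Renders `n_bscans` B-scans from a scene template; each B-scan draws its
#' opacity count from the model's count distribution and places
#' non-overlapping opacities uniformly in the vitreous. Per-B-scan seeds
#' are derived from `seed` by a counter scheme, so any single B-scan can
#' be regenerated in isolation.
#'
#' @param scene A [scene_spec()] used as template (its `opacities` field
#'   is ignored; opacities are sampled from `model`).
#' @param model An [opacity_model()]; `NULL` plants no opacities.
#' @param n_bscans Number of B-scans (61 in the study protocol).
#' @param calibration An [oct_calibration()].
#' @param seed Integer master seed for this eye.
#' @param animal_id,side,group,sex,week Metadata for [eye_scan_series()].
#' @return List with `series` (an [eye_scan_series()]) and `truth` (list
#'   of per-B-scan ground-truth objects as in [render_bscan()]).
#' @export
generate_series <- function(scene, model = control_opacity_model(),
                            n_bscans = 61,
                            calibration = default_calibration(),
                            seed = 0L, animal_id = "A0", side = "RE",
                            group = "control", sex = "female", week = 0L) {
  bscans <- vector("list", n_bscans)
  truths <- vector("list", n_bscans)
  for (i in seq_len(n_bscans)) {
    bseed <- derive_seed(seed, i)
    sc <- scene
    sc$opacities <- if (is.null(model)) list() else with_seed(bseed, {
      n <- .sample_count(model$count)
      placed <- matrix(numeric(0), 0, 3)
      specs <- list()
      for (k in seq_len(n)) {
        s <- .sample_opacity(model, scene, calibration, placed)
        if (is.null(s)) next
        specs[[length(specs) + 1L]] <- s$spec
        placed <- rbind(placed, c(s$spec$center_col, s$spec$center_row,
                                  s$radius))
      }
      specs
    })
    out <- render_bscan(sc, calibration, seed = derive_seed(bseed, 7919L),
                        index = i - 1L)
    bscans[[i]] <- out$bscan
    truths[[i]] <- out$truth
  }
  list(series = eye_scan_series(bscans, animal_id = animal_id, side = side,
                                group = group, sex = sex, week = week),
       truth = truths)
}

#' Design of a synthetic longitudinal cohort
#'
#' @param groups Character vector of group labels (subset of MEPI, Ms,
#'   control).
#' @param weeks Named list mapping each group to its follow-up weeks;
#'   glaucoma groups default to the full schedule (0, 2, 4, 6, 8, 12, 18,
#'   24) and controls to 0, 12, 24.
#' @param eyes_per_group Animals per group (each contributes one eye).
#' @param sexes Sexes cycled over the animals of each group.
#' @param side Eye side recorded for the series.
#' @param n_bscans B-scans per series.
#' @param scene A [scene_spec()] template shared by all eyes.
#' @param calibration An [oct_calibration()].
#' @param models Named list mapping each group to an [opacity_model()].
#' @param seed Master seed; per-eye seeds are derived from it.
#' @return An object of class `"cohort_design"`.
#' @export
cohort_design <- function(groups = c("control", "MEPI"),
                          weeks = NULL,
                          eyes_per_group = 5,
                          sexes = c("female", "male"),
                          side = "RE",
                          n_bscans = 61,
                          scene = scene_spec(),
                          calibration = default_calibration(),
                          models = NULL,
                          seed = 1L) {
  groups <- match.arg(groups, .GROUPS, several.ok = TRUE)
  if (length(groups) == 0L || eyes_per_group < 1L)
    stop("cohort design must contain at least one group and one eye")
  if (is.null(weeks))
    weeks <- stats::setNames(lapply(groups, function(g)
      if (g == "control") c(0L, 12L, 24L) else .WEEKS), groups)
  for (g in groups) {
    wk <- weeks[[g]]
    if (is.null(wk) || !all(wk %in% .WEEKS))
      stop("weeks for group ", g, " must be a subset of the study schedule")
    if (g == "control" && !all(wk %in% c(0L, 12L, 24L)))
      stop("control weeks must be a subset of 0, 12, 24")
  }
  if (is.null(models))
    models <- stats::setNames(lapply(groups, function(g)
      if (g == "control") control_opacity_model() else
        glaucoma_opacity_model()), groups)
  structure(list(groups = groups, weeks = weeks,
                 eyes_per_group = as.integer(eyes_per_group),
                 sexes = sexes, side = side, n_bscans = as.integer(n_bscans),
                 scene = scene, calibration = calibration, models = models,
                 seed = as.integer(seed)),
            class = "cohort_design")
}

#' Reduced-resolution benchmark cohort design
#'
#' A 4x-downscaled profile (384 x 124 px with rescaled calibration) used
#' for fast synthetic benchmarking. Opacity sizes are drawn on the pixel
#' scale (the soma-size class intervals read as pixel counts) because the
#' micron-scale classes are sub-pixel at this pitch.
#'
#' @inheritParams cohort_design
#' @param ... Passed on to [cohort_design()].
#' @export
reduced_cohort_design <- function(groups = c("control", "MEPI"),
                                  eyes_per_group = 5, n_bscans = 61,
                                  seed = 1L, ...) {
  cal <- default_calibration(width_px = 384, height_px = 124)
  scn <- scene_spec(width = 384, height = 124)
  models <- stats::setNames(lapply(groups, function(g) {
    m <- if (g == "control") control_opacity_model() else
      glaucoma_opacity_model()
    m$size_unit <- "px"
    m$size_scale <- 0.25       # pixel-count intervals shrink with the pitch
    m$min_sep_px <- 3
    m
  }), groups)
  cohort_design(groups = groups, eyes_per_group = eyes_per_group,
                n_bscans = n_bscans, scene = scn, calibration = cal,
                models = models, seed = seed, ...)
}

#' Generate a synthetic cohort
#'
#' One series per eye per scheduled week, fully reproducible from the
#' design's master seed (per-eye seeds are derived by a counter scheme).
#'
#' @param design A [cohort_design()].
#' @return List of elements, each `list(series=, truth=)` as returned by
#'   [generate_series()], in group/animal/week order.
#' @export
generate_cohort <- function(design) {
  stopifnot(inherits(design, "cohort_design"))
  out <- list()
  counter <- 0L
  for (g in design$groups) {
    for (e in seq_len(design$eyes_per_group)) {
      aid <- sprintf("%s-%02d", g, e)
      sex <- design$sexes[[(e - 1L) %% length(design$sexes) + 1L]]
      for (wk in design$weeks[[g]]) {
        counter <- counter + 1L
        eye_seed <- derive_seed(design$seed, counter * 104729L)
        out[[length(out) + 1L]] <- generate_series(
          design$scene, model = design$models[[g]],
          n_bscans = design$n_bscans, calibration = design$calibration,
          seed = eye_seed, animal_id = aid, side = design$side,
          group = g, sex = sex, week = wk)
      }
    }
  }
  if (length(out) == 0L) stop("empty cohort design")
  out
}

#' Read a cohort design from a YAML config
#'
#' Recognized top-level keys mirror the [cohort_design()] arguments
#' (`groups`, `weeks`, `eyes_per_group`, `sexes`, `side`, `n_bscans`,
#' `seed`, `profile`); `profile: reduced` starts from
#' [reduced_cohort_design()]. Unknown keys are an error.
#'
#' @param path YAML file path.
#' @return A `"cohort_design"`.
#' @export
read_cohort_design <- function(path) {
  cfg <- yaml::read_yaml(path)
  known <- c("groups", "weeks", "eyes_per_group", "sexes", "side",
             "n_bscans", "seed", "profile")
  bad <- setdiff(names(cfg), known)
  if (length(bad)) stop("unknown config keys: ", paste(bad, collapse = ", "))
  profile <- cfg$profile %||% "full"
  cfg$profile <- NULL
  if (!is.null(cfg$weeks)) cfg$weeks <- lapply(cfg$weeks, as.integer)
  fn <- if (identical(profile, "reduced")) reduced_cohort_design else
    cohort_design
  do.call(fn, cfg)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
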