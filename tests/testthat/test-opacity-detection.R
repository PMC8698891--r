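test_that("horizontal-edge filter matches hand-evaluated responses", {
  expect_true(all(horizontal_edge_filter(matrix(37, 8, 8)) == 0))

  step <- rbind(matrix(0, 4, 8), matrix(100, 4, 8))
  resp <- horizontal_edge_filter(step)
  expect_true(all(resp[4:5, ] == 400))    # rows adjacent to the step
  expect_true(all(resp[c(1:3, 6:8), ] == 0))

  vert <- cbind(matrix(0, 8, 4), matrix(100, 8, 4))
  rv <- horizontal_edge_filter(vert)
  expect_true(all(rv == 0))               # top/bottom kernel rows cancel

  expect_error(horizontal_edge_filter(matrix(1, 2, 5)), "3 x 3")
})

test_that("Otsu threshold equals the exhaustive-search minimizer", {
  bi <- c(rep(20, 60), rep(220, 40))
  t0 <- otsu_threshold(bi)
  expect_gt(t0, 20); expect_lt(t0, 220)
  expect_identical(which(bi > t0), which(bi == 220))

  expect_equal(otsu_threshold(matrix(9, 4, 4)), 9)   # degenerate constant
  expect_length(which(rep(9, 16) > otsu_threshold(rep(9, 16))), 0)

  set.seed(101)
  for (i in 1:100) {
    img <- switch(1 + i %% 3,
      matrix(sample(0:255, 32 * 32, replace = TRUE), 32, 32),
      matrix(round(c(rnorm(512, 60, 18), rnorm(512, 190, 22))), 32, 32),
      matrix(runif(32 * 32, 0, 947.3), 32, 32))   # non-integer path
    img[img < 0] <- 0
    expect_equal(otsu_threshold(img), otsu_bruteforce(img))
  }
})

test_that("component labeling agrees with a flood-fill oracle", {
  diag2 <- matrix(FALSE, 4, 4); diag2[1, 1] <- diag2[2, 2] <- TRUE
  expect_equal(max(label_components(diag2, connectivity = 8)), 1L)
  expect_equal(max(label_components(diag2, connectivity = 4)), 2L)

  # vitreous restriction removes below-boundary pixels
  blob <- matrix(FALSE, 6, 4); blob[2:5, 2] <- TRUE
  vit <- matrix(TRUE, 6, 4); vit[4:6, ] <- FALSE
  lab <- label_components(blob, vit)
  expect_equal(sum(lab > 0), 2L)

  set.seed(77)
  for (i in 1:400) {
    mask <- matrix(runif(12 * 14) < 0.4, 12, 14)
    conn <- if (i %% 2) 8 else 4
    expect_true(labels_equivalent(label_components(mask, connectivity = conn),
                                  floodfill_labels(mask, conn)))
  }
  # a few larger ones
  for (i in 1:20) {
    mask <- matrix(runif(64 * 64) < 0.45, 64, 64)
    expect_true(labels_equivalent(label_components(mask, connectivity = 8),
                                  floodfill_labels(mask, 8)))
  }
})

test_that("Tukey upper fence follows the quartile convention", {
  vals <- c(10:19, 250)
  q <- quantile(vals, c(0.25, 0.75), names = FALSE)
  expect_equal(tukey_upper_fence(vals), q[2] + 1.5 * (q[2] - q[1]))
  expect_identical(which(vals > tukey_upper_fence(vals)), 11L)

  expect_equal(tukey_upper_fence(rep(5, 10)), 5)
  expect_identical(tukey_upper_fence(c(1, 2, 3)), Inf)
  expect_error(tukey_upper_fence(numeric(0)), "non-empty")
})

test_that("fence denoising keeps only strict upper outliers", {
  regions <- data.frame(label = 1:11, mean_intensity = c(10:19, 250))
  kept <- denoise_regions(regions)
  expect_equal(kept$label, 11L)

  equal <- data.frame(label = 1:6, mean_intensity = rep(80, 6))
  expect_equal(nrow(denoise_regions(equal)), 0L)

  expect_equal(nrow(denoise_regions(regions[0, ])), 0L)
})

test_that("moment measurement matches the covariance oracle", {
  cal <- default_calibration()
  gray <- matrix(120, 40, 40)

  px1 <- cbind(7, 7)
  m1 <- measure_opacity(px1, gray, cal)
  expect_equal(m1$area_um2, cal$pixel_area_um2)
  expect_equal(m1$eccentricity, 0)
  expect_equal(m1$orientation_deg, 0)

  line <- cbind(20, 11:30)
  ml <- measure_opacity(line, gray, cal)
  expect_equal(ml$eccentricity, sqrt(1 - (1 / 12) / (399 / 12 + 1 / 12)))
  expect_equal(ml$orientation_deg, 0)

  disc <- rasterize_ellipse(opacity_spec(20, 20, 10, 10, 0, 100), 40, 40)
  md <- measure_opacity(disc, gray, cal)
  expect_lt(md$eccentricity, 0.1)

  set.seed(55)
  for (i in 1:50) {
    n <- sample(2:40, 1)
    px <- unique(cbind(sample(1:40, n, TRUE), sample(1:40, n, TRUE)))
    m <- measure_opacity(px, gray, cal)
    o <- moments_oracle(px)
    expect_equal(m$eccentricity, o$ecc, tolerance = 1e-9)
    expect_equal(m$orientation_deg, o$orientation, tolerance = 1e-9)
  }
  expect_error(measure_opacity(cbind(integer(0), integer(0)), gray, cal),
               "at least one pixel")
})

test_that("eccentricity is translation-invariant; rotation flips orientation", {
  cal <- default_calibration()
  gray <- matrix(0, 60, 60)
  px <- rasterize_ellipse(opacity_spec(20, 20, 9, 4, 0, 100), 60, 60)
  m <- measure_opacity(px, gray, cal)
  shifted <- px + matrix(rep(c(13, 9), each = nrow(px)), ncol = 2)
  ms <- measure_opacity(shifted, gray, cal)
  expect_equal(ms$eccentricity, m$eccentricity, tolerance = 1e-12)
  # 90-degree rotation (transpose) maps orientation 0 to 90
  rotated <- px[, c(2, 1)]
  mr <- measure_opacity(rotated, gray, cal)
  expect_equal(mr$orientation_deg, 90, tolerance = 1e-6)
  expect_equal(mr$eccentricity, m$eccentricity, tolerance = 1e-12)
})

test_that("noiseless planted opacities are recovered one-to-one", {
  cal <- tiny_calibration()
  sp <- list(opacity_spec(40, 25, 6, 3, 20, 170),
             opacity_spec(90, 18, 5, 2.5, -30, 190),
             opacity_spec(140, 30, 7, 3.5, 0, 160),
             opacity_spec(185, 22, 4, 2, 45, 200))
  out <- render_bscan(tiny_scene(sp), cal, seed = 1)
  seg <- segment_bscan(out$bscan)
  det <- detect_opacities(out$bscan, seg$masks, cal,
                          synthetic_detection_params(noiseless = TRUE))
  expect_equal(nrow(det), 4L)
  mm <- vitreoct:::match_regions(attr(det, "labels"), out$truth$labels,
                                 iou_threshold = 0.3)
  expect_equal(nrow(mm), 4L)
  # areas within one perimeter's worth of pixels of the planted areas
  for (k in seq_len(nrow(mm))) {
    tr <- out$truth$table[mm$true[k], ]
    dd <- det[det$label == mm$det[k], ]
    perim <- pi * (tr$semi_major_px + tr$semi_minor_px)
    expect_lt(abs(dd$n_pixels - tr$n_pixels), perim)
  }
})

test_that("the fence isolates bright cells from heavy raw speckle", {
  # raw single-frame speckle: hundreds of noise candidates per b-scan;
  # the planted bright cells must be the surviving upper outliers
  w <- 700; h <- 240
  cal <- default_calibration(w, h, 3 * w / 1536, 0.969 * h / 496)
  sp <- list(opacity_spec(150, 45, 6, 3, 10, 210),
             opacity_spec(350, 40, 6, 3, -20, 220),
             opacity_spec(550, 60, 5, 2.5, 0, 230))
  scn <- scene_spec(width = w, height = h, speckle_shape = 3,
                    opacities = sp)
  out <- render_bscan(scn, cal, seed = 12)
  seg <- segment_bscan(out$bscan)
  pre <- detect_opacities(out$bscan, seg$masks, cal,
                          detection_params(denoise = FALSE))
  post <- detect_opacities(out$bscan, seg$masks, cal,
                           detection_params(denoise = TRUE))
  expect_gt(nrow(pre), 30)                   # noise-dominated population
  expect_lt(nrow(post), nrow(pre) / 3)       # fence removes the bulk
  mm <- vitreoct:::match_regions(attr(post, "labels"), out$truth$labels,
                                 iou_threshold = 0.1)
  expect_gte(nrow(mm), 2L)                   # bright cells survive
})

test_that("an opacity-free noisy scene yields at most a few spurious regions", {
  cal <- tiny_calibration()
  spurious <- integer(20)
  for (seed in 1:20) {
    out <- render_bscan(tiny_scene(speckle = 25), cal, seed = seed)
    seg <- segment_bscan(out$bscan)
    det <- detect_opacities(out$bscan, seg$masks, cal,
                            synthetic_detection_params())
    spurious[seed] <- nrow(det)
  }
  expect_gte(mean(spurious <= 1), 0.95)
})
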