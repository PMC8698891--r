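test_that("VIT/RPE relative intensity follows the mask means", {
  img <- matrix(50, 20, 10)
  masks <- list(vitreous = matrix(FALSE, 20, 10),
                rpe = matrix(FALSE, 20, 10))
  masks$vitreous[1:5, ] <- TRUE
  masks$rpe[15:16, ] <- TRUE
  expect_equal(vit_rpe_relative_intensity(img, masks), 1)

  img[1:5, ] <- 20; img[15:16, ] <- 200
  expect_equal(vit_rpe_relative_intensity(img, masks), 0.1)

  empty <- masks; empty$vitreous[] <- FALSE
  expect_error(vit_rpe_relative_intensity(img, empty), "empty vitreous")
  zero <- masks; img2 <- img; img2[15:16, ] <- 0
  expect_error(vit_rpe_relative_intensity(img2, zero), "zero mean RPE")

  # noiseless rendered scene: ratio equals the planted level ratio
  cal <- tiny_calibration()
  out <- render_bscan(tiny_scene(), cal, seed = 1)
  seg <- segment_bscan(out$bscan)
  expect_equal(vit_rpe_relative_intensity(out$bscan, seg$masks), 25 / 230,
               tolerance = 1e-10)
})

test_that("eye-level intensity is the mean of b-scan ratios and bounded", {
  expect_equal(eye_relative_intensity(rep(0.1, 61)), 0.1)
  expect_equal(eye_relative_intensity(c(0.1, 0.3)), 0.2)
  set.seed(9)
  r <- runif(61, 0.05, 0.4)
  m <- eye_relative_intensity(r)
  expect_equal(m, mean(r))
  expect_gte(m, min(r)); expect_lte(m, max(r))
  expect_error(eye_relative_intensity(numeric(0)), "at least one")
})

test_that("size classification partitions the positive reals", {
  expect_equal(classify_size(9.9), "isolated")
  expect_equal(classify_size(10), "non_activated")
  expect_equal(classify_size(49.999), "non_activated")
  expect_equal(classify_size(50), "activated")
  expect_equal(classify_size(250), "activated")
  expect_equal(classify_size(250.1), "complex")
  expect_equal(classify_size(default_calibration()$pixel_area_um2),
               "isolated")   # one-pixel opacity
  expect_error(classify_size(0), "positive")
  expect_error(classify_size(-3), "positive")

  set.seed(3)
  areas <- c(10^runif(2000, -2, 4), 10, 50, 250)
  cls <- classify_size(areas)
  expect_true(all(cls %in% c("isolated", "non_activated", "activated",
                             "complex")))
  # interval convention re-derived independently
  expect_identical(cls, ifelse(areas < 10, "isolated",
                        ifelse(areas < 50, "non_activated",
                        ifelse(areas <= 250, "activated", "complex"))))
})

test_that("per-eye summaries pool correctly and percentages close to 100", {
  cal <- tiny_calibration()
  series <- eye_scan_series(lapply(1:4, function(i)
    bscan(matrix(10, 20, 30), index = i - 1L, calibration = cal)),
    animal_id = "A7", group = "Ms", week = 8)

  ops <- data.frame(bscan_index = c(0, 1, 2, 3),
                    n_pixels = c(2, 6, 30, 90),
                    area_um2 = c(5, 20, 100, 300),
                    mean_intensity = c(200, 150, 140, 130),
                    eccentricity = c(0.2, 0.5, 0.9, 0.95),
                    orientation_deg = c(10, -10, 40, 0),
                    size_class = classify_size(c(5, 20, 100, 300)))
  s <- summarize_eye(series, ops, ratios = rep(0.2, 4))
  expect_equal(s$mean_n_opacities, 1)
  expect_equal(s$total_area_um2, 425)
  expect_equal(s$vit_rpe_intensity, 0.2)
  pct <- c(s$isolated_pct, s$non_activated_pct, s$activated_pct,
           s$complex_pct)
  expect_equal(unname(pct), rep(25, 4))
  expect_equal(sum(pct), 100)
  expect_equal(s$activated_mean_intensity, 140)
  expect_equal(s$non_activated_mean_orientation_deg, -10)
  # total area identity over classes
  counts <- c(s$isolated_count, s$non_activated_count, s$activated_count,
              s$complex_count)
  means <- c(s$isolated_mean_area_um2, s$non_activated_mean_area_um2,
             s$activated_mean_area_um2, s$complex_mean_area_um2)
  expect_equal(sum(counts * means), s$total_area_um2, tolerance = 1e-6)

  none <- summarize_eye(series, ops[0, ], ratios = rep(0.2, 4))
  expect_equal(none$n_opacities, 0L)
  expect_equal(none$total_area_um2, 0)
  expect_true(is.na(none$activated_pct))
  expect_true(is.na(none$isolated_mean_area_um2))
})

test_that("signed orientation means cancel while the circular option does not", {
  cal <- tiny_calibration()
  series <- eye_scan_series(list(bscan(matrix(10, 20, 30),
                                       calibration = cal)))
  ops <- data.frame(bscan_index = 0, n_pixels = c(10, 10),
                    area_um2 = c(100, 100), mean_intensity = c(1, 1),
                    eccentricity = c(0.9, 0.9),
                    orientation_deg = c(60, -60),
                    size_class = c("activated", "activated"))
  s <- summarize_eye(series, ops)
  expect_equal(s$activated_mean_orientation_deg, 0)
  sc <- summarize_eye(series, ops, circular_orientation = TRUE)
  expect_equal(abs(sc$activated_mean_orientation_deg), 90)
})
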