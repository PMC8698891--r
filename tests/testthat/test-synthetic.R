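test_that("ellipse rasterization matches a brute-force pixel-center scan", {
  spec <- opacity_spec(30, 20, 8, 4, 0, 150)
  px <- rasterize_ellipse(spec, 60, 40)
  # independent full-grid scan of the ellipse inequality
  grid <- expand.grid(row = 1:40, col = 1:60)
  ins <- with(grid, ((col - 30) / 8)^2 + ((row - 20) / 4)^2 <= 1)
  expect_equal(nrow(px), sum(ins))
  expect_setequal(paste(px[, 1], px[, 2]),
                  paste(grid$row[ins], grid$col[ins]))
  # rotated case against the rotated inequality
  spec2 <- opacity_spec(30, 20, 8, 4, 35, 150)
  px2 <- rasterize_ellipse(spec2, 60, 40)
  th <- 35 * pi / 180
  u <- (grid$col - 30) * cos(th) + (grid$row - 20) * sin(th)
  v <- -(grid$col - 30) * sin(th) + (grid$row - 20) * cos(th)
  ins2 <- (u / 8)^2 + (v / 4)^2 <= 1
  expect_setequal(paste(px2[, 1], px2[, 2]),
                  paste(grid$row[ins2], grid$col[ins2]))
  # rasterized area is within one perimeter of pi*a*b
  for (ab in list(c(8, 4), c(12, 6), c(5, 5))) {
    p <- rasterize_ellipse(opacity_spec(40, 25, ab[1], ab[2], 10, 150),
                           90, 60)
    perim <- pi * (ab[1] + ab[2])  # Euler upper-ish approximation
    expect_lt(abs(nrow(p) - pi * ab[1] * ab[2]), perim)
  }
})

test_that("rendering is seed-deterministic and honors scene structure", {
  cal <- tiny_calibration()
  sp <- opacity_spec(60, 25, 6, 3, 20, 160)
  scn <- tiny_scene(list(sp), speckle = 10)
  a <- render_bscan(scn, cal, seed = 5)
  b <- render_bscan(scn, cal, seed = 5)
  c <- render_bscan(scn, cal, seed = 6)
  expect_identical(a$bscan$pixels, b$bscan$pixels)
  expect_false(identical(a$bscan$pixels, c$bscan$pixels))

  # zero-noise scene: vitreous pixels equal the background level exactly
  clean <- render_bscan(tiny_scene(), cal, seed = 1)
  ilm <- round(0.4 * 120)
  expect_true(all(clean$bscan$pixels[1:(ilm - 1), ] == 25))

  # ground truth: mask matches rasterization, count and area agree
  expect_equal(sum(a$truth$labels == 1L), a$truth$table$n_pixels[1])
  expect_equal(a$truth$table$area_um2[1],
               a$truth$table$n_pixels[1] * cal$pixel_area_um2)
  expect_equal(a$truth$table$eccentricity[1], sqrt(1 - (3 / 6)^2))

  # planted region below the ILM is rejected
  bad <- opacity_spec(60, 60, 6, 3, 0, 160)
  expect_error(render_bscan(tiny_scene(list(bad)), cal),
               "outside the vitreous")
  # overlapping opacities are rejected
  twin <- list(opacity_spec(60, 25, 6, 3, 0, 160),
               opacity_spec(62, 25, 6, 3, 0, 180))
  expect_error(render_bscan(tiny_scene(twin), cal), "overlaps")
})

test_that("series generation follows the count model and seed scheme", {
  cal <- tiny_calibration()
  scn <- tiny_scene(speckle = 25)
  none <- generate_series(scn, model = NULL, n_bscans = 5,
                          calibration = cal, seed = 2)
  expect_true(all(vapply(none$truth, function(t) nrow(t$table),
                         integer(1)) == 0L))

  fixed <- opacity_model(count = list("fixed", 5))
  five <- generate_series(scn, fixed, n_bscans = 6, calibration = cal,
                          seed = 2)
  expect_true(all(vapply(five$truth, function(t) nrow(t$table),
                         integer(1)) == 5L))

  # law-of-large-numbers check on Poisson counts at full width
  pois <- opacity_model(count = list("poisson", 70))
  big <- generate_series(scene_spec(speckle_shape = 25), pois,
                         n_bscans = 61, seed = 9)
  counts <- vapply(big$truth, function(t) nrow(t$table), integer(1))
  se <- sqrt(70 / 61)
  expect_lt(abs(mean(counts) - 70), 3 * se)

  # same seed, same series
  again <- generate_series(scn, fixed, n_bscans = 6, calibration = cal,
                           seed = 2)
  expect_identical(five$series$bscans[[3]]$pixels,
                   again$series$bscans[[3]]$pixels)
})

test_that("ground-truth masks are disjoint and strictly above the ILM", {
  cal <- tiny_calibration()
  model <- opacity_model(count = list("uniform", 8, 14))
  gen <- generate_series(tiny_scene(speckle = 25), model, n_bscans = 6,
                         calibration = cal, seed = 31)
  ilm <- round(0.4 * 120)
  for (tr in gen$truth) {
    on <- which(tr$labels > 0L, arr.ind = TRUE)
    expect_true(all(on[, 1] < ilm))
    # one label per pixel by construction; region pixel counts consistent
    expect_equal(sum(tabulate(tr$labels[tr$labels > 0])),
                 sum(tr$labels > 0))
    expect_equal(as.vector(table(tr$labels[tr$labels > 0L])),
                 tr$table$n_pixels)
  }
})

test_that("cohort generation is reproducible and group-structured", {
  des <- reduced_cohort_design(eyes_per_group = 2, n_bscans = 2, seed = 7,
                               weeks = list(control = c(0L, 12L),
                                            MEPI = c(0L, 12L)))
  coh1 <- generate_cohort(des)
  coh2 <- generate_cohort(des)
  expect_length(coh1, 8L)   # 2 groups x 2 eyes x 2 weeks
  expect_identical(coh1[[5]]$series$bscans[[1]]$pixels,
                   coh2[[5]]$series$bscans[[1]]$pixels)

  planted <- vapply(coh1, function(el)
    mean(vapply(el$truth, function(t) nrow(t$table), integer(1))),
    numeric(1))
  grp <- vapply(coh1, function(el) el$series$group, character(1))
  expect_gt(min(planted[grp == "MEPI"]), max(planted[grp == "control"]))

  single <- cohort_design(groups = "control", eyes_per_group = 1,
                          weeks = list(control = 0L),
                          scene = tiny_scene(speckle = 25),
                          calibration = tiny_calibration(), n_bscans = 1)
  expect_length(generate_cohort(single), 1L)

  expect_error(cohort_design(groups = "control",
                             weeks = list(control = c(0L, 8L))),
               "control weeks")
  expect_error(cohort_design(eyes_per_group = 0), "at least one")
})

test_that("cohort designs load from YAML with unknown keys rejected", {
  path <- withr::local_tempfile(fileext = ".yaml")
  writeLines(c("profile: reduced", "eyes_per_group: 2", "n_bscans: 3",
               "seed: 11", "groups: [control, MEPI]"), path)
  des <- read_cohort_design(path)
  expect_s3_class(des, "cohort_design")
  expect_equal(des$eyes_per_group, 2L)
  expect_equal(des$scene$width, 384L)

  writeLines(c("eyes_per_group: 2", "bogus_key: 1"), path)
  expect_error(read_cohort_design(path), "unknown config keys")
})
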