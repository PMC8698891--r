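test_that("Monte-Carlo Lilliefors screen separates normal from skewed data", {
  set.seed(14)
  norm <- rnorm(100)
  expo <- rexp(100)
  expect_gt(ks_normality(norm, nsim = 500, seed = 4)$p.value, 0.05)
  expect_lt(ks_normality(expo, nsim = 500, seed = 4)$p.value, 0.05)
  expect_error(ks_normality(rep(1, 10)), "degenerate")
  expect_error(ks_normality(c(1, 2)), "at least 5")
  # agrees broadly with the analytic Lilliefors approximation
  skip_if_not_installed("nortest")
  p_mc <- ks_normality(expo, nsim = 2000, seed = 4)$p.value
  p_an <- nortest::lillie.test(expo)$p.value
  expect_equal(p_mc < 0.05, p_an < 0.05)
})

test_that("one-way ANOVA reproduces hand-computed sums of squares", {
  same <- anova_oneway(list(a = c(1, 2, 3), b = c(1, 2, 3)))
  expect_equal(same$statistic, 0)

  g <- list(a = c(1, 2, 3), b = c(7, 8, 9))
  # SS_between = 2*3^2*... manual: grand mean 5; between = 3*(2-5)^2+3*(8-5)^2 = 54
  # within = 2+2 = 4 on 4 df -> F = (54/1)/(4/4) = 54
  out <- anova_oneway(g)
  expect_equal(out$statistic, 54)
  expect_equal(out$df, c(1, 4))
  expect_equal(out$p.value, pf(54, 1, 4, lower.tail = FALSE))

  expect_error(anova_oneway(list(a = 1:3)), "two groups")
  expect_error(anova_oneway(list(a = 1, b = 1:3)), "at least two values")

  # oracle equivalence on random data: direct SS formula
  set.seed(21)
  for (i in 1:100) {
    k <- sample(2:4, 1)
    gs <- lapply(seq_len(k), function(j) rnorm(sample(3:9, 1), mean = j))
    names(gs) <- paste0("g", seq_len(k))
    res <- anova_oneway(gs)
    all_v <- unlist(gs); gm <- mean(all_v); n <- length(all_v)
    ssb <- sum(vapply(gs, function(x) length(x) * (mean(x) - gm)^2,
                      numeric(1)))
    ssw <- sum(vapply(gs, function(x) sum((x - mean(x))^2), numeric(1)))
    f_manual <- (ssb / (k - 1)) / (ssw / (n - k))
    expect_equal(res$statistic, f_manual, tolerance = 1e-10)
  }
})

test_that("Tukey HSD flags the shifted group and dominates raw p-values", {
  set.seed(33)
  base <- rnorm(10)
  g <- list(a = base, b = base + rnorm(10, 0, 0.1), c = base + 5)
  tk <- tukey_hsd(g)
  expect_equal(nrow(tk), 3L)
  expect_gt(tk$p_adj[tk$comparison == "b-a"], 0.05)
  expect_lt(tk$p_adj[tk$comparison == "c-a"], 0.05)
  expect_lt(tk$p_adj[tk$comparison == "c-b"], 0.05)

  ident <- tukey_hsd(list(a = c(1, 2, 3), b = c(1, 2, 3)))
  expect_gt(ident$p_adj[1], 0.99)

  # adjusted p >= the unadjusted pairwise p computed from the same pooled
  # within-group variance
  for (i in 1:25) {
    gs <- lapply(1:3, function(j) rnorm(8, mean = j / 2))
    names(gs) <- c("a", "b", "c")
    tk <- tukey_hsd(gs)
    mse <- mean(vapply(gs, var, numeric(1)))
    df <- 3 * 8 - 3
    raw <- vapply(list(c("b", "a"), c("c", "a"), c("c", "b")), function(p) {
      se <- sqrt(mse * (1 / 8 + 1 / 8))
      2 * pt(-abs(mean(gs[[p[1]]]) - mean(gs[[p[2]]])) / se, df)
    }, numeric(1))
    expect_true(all(tk$p_adj >= raw - 1e-8))
  }
})

test_that("Pearson correlation handles exact and noisy association", {
  x <- 1:20
  expect_equal(pearson_corr(x, 2 * x + 1)$r, 1)
  expect_equal(pearson_corr(x, -x)$r, -1)
  set.seed(8)
  z <- rnorm(1000); e <- rnorm(1000)
  y <- 0.8 * z + sqrt(1 - 0.8^2) * e
  r <- pearson_corr(z, y)
  expect_gt(r$r, 0.75); expect_lt(r$r, 0.85)
  expect_lt(r$p.value, 1e-10)
  expect_error(pearson_corr(1:3, c(2, 2, 2)), "zero variance")
  expect_error(pearson_corr(1:3, 1:4), "equal length")
  # affine invariance up to scale sign
  a <- rnorm(30); b <- rnorm(30)
  r0 <- pearson_corr(a, b)$r
  expect_equal(pearson_corr(3 * a + 2, b)$r, r0, tolerance = 1e-12)
  expect_equal(pearson_corr(-2 * a, b)$r, -r0, tolerance = 1e-12)
})

test_that("Bonferroni correction divides alpha by the comparison count", {
  expect_equal(bonferroni_adjust(0.05, 1), 0.05)
  expect_equal(bonferroni_adjust(0.05, 5), 0.01)
  expect_equal(bonferroni_adjust(0.05, 10), 0.005)
  expect_error(bonferroni_adjust(1.2, 3), "alpha")
  expect_error(bonferroni_adjust(0.05, 0), "positive integer")
})

test_that("the cohort report assembles ANOVA, post-hoc and correlations", {
  set.seed(61)
  rows <- list()
  for (g in c("control", "MEPI", "Ms")) {
    shift <- switch(g, control = 0, MEPI = 3, Ms = 2)
    for (e in 1:6) {
      base <- rnorm(1)
      for (wk in c(0, 12, 24)) {
        rows[[length(rows) + 1L]] <- data.frame(
          animal_id = paste0(g, e), group = g,
          sex = if (e %% 2) "male" else "female", week = wk,
          vit_rpe_intensity = 0.1 + 0.01 * shift + 0.01 * base +
            rnorm(1, 0, 0.002),
          mean_n_opacities = 15 + 20 * shift + rnorm(1, 0, 2),
          total_area_um2 = 1000 * (1 + shift) + rnorm(1, 0, 50))
      }
    }
  }
  summaries <- do.call(rbind, rows)
  st <- cohort_stats(summaries)
  expect_s3_class(st, "cohort_stats")
  expect_equal(nrow(st$anova), 9L)   # 3 metrics x 3 weeks
  expect_true(all(st$anova$p[st$anova$metric == "mean_n_opacities"] < 0.01))
  expect_equal(unique(st$anova$alpha_bonferroni), 0.05 / 9)
  expect_true(all(c("pooled", "male", "female") %in% st$correlations$sex))
  # correlations induced by the shared per-eye baseline are strong
  vit_pooled <- st$correlations[st$correlations$metric == "vit_rpe_intensity" &
                                st$correlations$sex == "pooled", ]
  expect_true(all(vit_pooled$r > 0.5))
  expect_output(print(st), "Cohort statistics")
})
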