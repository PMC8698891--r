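# Cohort-level statistics: normality screening, one-way ANOVA with Tukey
# post-hoc, Pearson correlations, Bonferroni correction. The inferential
# machinery is standard; this module only gives it the study's contracts.

#' Kolmogorov-Smirnov normality screen (Monte-Carlo Lilliefors)
#'
#' One-sample KS statistic against a normal with the sample mean and SD.
#' Because the parameters are estimated, the classical KS null
#' distribution does not apply; the p-value is obtained by Monte-Carlo
#' simulation of the statistic under normal samples with re-estimated
#' parameters (Lilliefors construction), at a fixed seed.
#'
#' @param x Numeric vector, at least 5 values, non-degenerate SD.
#' @param nsim Number of Monte-Carlo replicates.
#' @param seed Seed for the simulation.
#' @return An object of class `"htest"` with `statistic` (D) and
#'   `p.value`.
#' @export
ks_normality <- function(x, nsim = 2000, seed = 1L) {
  if (length(x) < 5L) stop("need at least 5 values")
  s <- stats::sd(x)
  if (!is.finite(s) || s == 0) stop("degenerate (constant) sample")
  n <- length(x)
  d_stat <- function(v) {
    f <- stats::pnorm(sort(v), mean(v), stats::sd(v))
    i <- seq_len(length(v))
    max(pmax(i / length(v) - f, f - (i - 1) / length(v)))
  }
  d <- d_stat(x)
  sims <- with_seed(seed, replicate(nsim, d_stat(stats::rnorm(n))))
  p <- (1 + sum(sims >= d)) / (nsim + 1)
  structure(list(statistic = c(D = d), p.value = p,
                 method = "Monte-Carlo Lilliefors normality test",
                 data.name = deparse(substitute(x))),
            class = "htest")
}

.check_groups <- function(groups) {
  if (!is.list(groups) || length(groups) < 2L)
    stop("need at least two groups")
  if (any(vapply(groups, length, integer(1)) < 2L))
    stop("every group needs at least two values")
  if (is.null(names(groups)))
    names(groups) <- paste0("g", seq_along(groups))
  groups
}

.stack_groups <- function(groups) {
  data.frame(value = unlist(groups, use.names = FALSE),
             group = factor(rep(names(groups),
                                vapply(groups, length, integer(1)))))
}

#' One-way analysis of variance
#'
#' Classical fixed-effects one-way ANOVA (equal-variance F test) across
#' groups of per-eye values.
#'
#' @param groups Named list of numeric vectors, one per group; at least
#'   two groups of at least two values each.
#' @return List with `statistic` (F), `df` (between, within), `p.value`.
#' @export
anova_oneway <- function(groups) {
  groups <- .check_groups(groups)
  df <- .stack_groups(groups)
  if (stats::var(df$value) == 0)
    return(list(statistic = 0, df = c(length(groups) - 1L,
                                      nrow(df) - length(groups)),
                p.value = 1))
  ht <- stats::oneway.test(value ~ group, data = df, var.equal = TRUE)
  list(statistic = unname(ht$statistic),
       df = unname(ht$parameter), p.value = unname(ht$p.value))
}

#' Tukey HSD post-hoc comparisons
#'
#' All pairwise group mean differences with studentized-range adjusted
#' p-values, as the post-hoc to [anova_oneway()].
#'
#' @param groups Named list of numeric vectors as in [anova_oneway()].
#' @return Data frame with columns `comparison`, `diff`, `lwr`, `upr`,
#'   `p_adj`.
#' @export
tukey_hsd <- function(groups) {
  groups <- .check_groups(groups)
  df <- .stack_groups(groups)
  fit <- stats::aov(value ~ group, data = df)
  tk <- stats::TukeyHSD(fit)$group
  data.frame(comparison = rownames(tk), diff = tk[, "diff"],
             lwr = tk[, "lwr"], upr = tk[, "upr"],
             p_adj = tk[, "p adj"], row.names = NULL)
}

#' Pearson correlation with two-sided p-value
#'
#' @param x,y Numeric vectors of equal length (>= 3), each with nonzero
#'   variance.
#' @return List with `r`, `p.value`, `n`.
#' @export
pearson_corr <- function(x, y) {
  if (length(x) != length(y)) stop("'x' and 'y' must have equal length")
  if (length(x) < 3L) stop("need at least 3 pairs")
  if (stats::var(x) == 0 || stats::var(y) == 0)
    stop("zero variance in 'x' or 'y'")
  ht <- stats::cor.test(x, y, method = "pearson")
  list(r = unname(ht$estimate), p.value = ht$p.value, n = length(x))
}

#' Bonferroni-corrected per-test significance level
#'
#' @param alpha Family-wise significance level in (0, 1).
#' @param m Number of comparisons (>= 1).
#' @return `alpha / m`.
#' @export
bonferroni_adjust <- function(alpha, m) {
  if (!is.numeric(alpha) || alpha <= 0 || alpha >= 1)
    stop("'alpha' must lie in (0, 1)")
  if (!is.numeric(m) || m < 1 || m != round(m))
    stop("'m' must be a positive integer")
  alpha / m
}

#' Cohort statistics report
#'
#' For each metric and week with at least two groups of two or more eyes:
#' one-way ANOVA across groups plus Tukey HSD post-hoc; the family-wise
#' Bonferroni-corrected alpha over all ANOVAs performed is reported
#' alongside. Additionally, Pearson correlations of each metric between
#' pairs of weeks within each group (pooled over sexes and, where both
#' sexes are present, per sex).
#'
#' @param summaries Data frame of per-eye summary rows (one row per
#'   eye x week, e.g. stacked [summarize_eye()] rows).
#' @param metrics Character vector of summary columns to analyse.
#' @param alpha Family-wise significance level.
#' @return List of class `"cohort_stats"` with data frames `anova`
#'   (metric, week, F, df1, df2, p, alpha_bonferroni, significant),
#'   `tukey` (per pair), and `correlations` (metric, group, sex,
#'   week_a, week_b, r, p, n).
#' @export
cohort_stats <- function(summaries,
                         metrics = c("vit_rpe_intensity",
                                     "mean_n_opacities",
                                     "total_area_um2"),
                         alpha = 0.05) {
  summaries <- as.data.frame(summaries)
  metrics <- intersect(metrics, names(summaries))
  if (length(metrics) == 0L) stop("no requested metric found in summaries")
  anova_rows <- list(); tukey_rows <- list(); cor_rows <- list()

  for (metric in metrics) {
    for (wk in sort(unique(summaries$week))) {
      sub <- summaries[summaries$week == wk & !is.na(summaries[[metric]]), ]
      groups <- split(sub[[metric]], sub$group, drop = TRUE)
      groups <- groups[vapply(groups, length, integer(1)) >= 2L]
      if (length(groups) < 2L) next
      a <- anova_oneway(groups)
      anova_rows[[length(anova_rows) + 1L]] <- data.frame(
        metric = metric, week = wk, F = a$statistic,
        df1 = a$df[1], df2 = a$df[2], p = a$p.value)
      tk <- tukey_hsd(groups)
      tk <- cbind(metric = metric, week = wk, tk)
      tukey_rows[[length(tukey_rows) + 1L]] <- tk
    }
    # between-week correlations within group (pooled and per sex)
    for (g in unique(summaries$group)) {
      gsub <- summaries[summaries$group == g, ]
      strata <- c(list(pooled = gsub),
                  if (length(unique(gsub$sex)) > 1L)
                    split(gsub, gsub$sex))
      wks <- sort(unique(gsub$week))
      if (length(wks) < 2L) next
      for (sx in names(strata)) {
        ss <- strata[[sx]]
        wide <- stats::reshape(
          ss[, c("animal_id", "week", metric)],
          idvar = "animal_id", timevar = "week", direction = "wide")
        for (i in seq_len(length(wks) - 1L)) for (j in (i + 1L):length(wks)) {
          ca <- paste0(metric, ".", wks[i]); cb <- paste0(metric, ".", wks[j])
          if (!all(c(ca, cb) %in% names(wide))) next
          pair <- stats::na.omit(wide[, c(ca, cb)])
          if (nrow(pair) < 3L || stats::var(pair[[1]]) == 0 ||
              stats::var(pair[[2]]) == 0) next
          pc <- pearson_corr(pair[[1]], pair[[2]])
          cor_rows[[length(cor_rows) + 1L]] <- data.frame(
            metric = metric, group = g, sex = sx,
            week_a = wks[i], week_b = wks[j],
            r = pc$r, p = pc$p.value, n = pc$n)
        }
      }
    }
  }
  anova_tab <- if (length(anova_rows)) do.call(rbind, anova_rows) else
    data.frame(metric = character(), week = integer(), F = numeric(),
               df1 = numeric(), df2 = numeric(), p = numeric())
  m <- max(1L, nrow(anova_tab))
  if (nrow(anova_tab)) {
    anova_tab$alpha_bonferroni <- bonferroni_adjust(alpha, m)
    anova_tab$significant <- anova_tab$p < anova_tab$alpha_bonferroni
  }
  structure(list(
    anova = anova_tab,
    tukey = if (length(tukey_rows)) do.call(rbind, tukey_rows) else NULL,
    correlations = if (length(cor_rows)) do.call(rbind, cor_rows) else NULL,
    alpha = alpha, n_tests = m), class = "cohort_stats")
}

#' @export
print.cohort_stats <- function(x, ...) {
  cat("Cohort statistics:", nrow(x$anova), "ANOVA tests,",
      "Bonferroni per-test alpha =",
      format(bonferroni_adjust(x$alpha, x$n_tests), digits = 3), "\n")
  if (nrow(x$anova)) print(x$anova, row.names = FALSE)
  if (!is.null(x$correlations)) {
    cat("\nBetween-week Pearson correlations:\n")
    print(utils::head(x$correlations, 20), row.names = FALSE)
    if (nrow(x$correlations) > 20) cat("...\n")
  }
  invisible(x)
}
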