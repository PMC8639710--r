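test_that("summary ANOVA equals a raw-data one-way ANOVA", {
  set.seed(2)
  groups <- rep(c("a", "b", "c"), times = c(8, 11, 7))
  y <- rnorm(length(groups), mean = c(a = 10, b = 12, c = 9)[groups], sd = 2)
  sm <- tapply(y, groups, mean)
  ss <- tapply(y, groups, sd)
  sn <- tapply(y, groups, length)
  res <- anova_from_summary(sm, ss, sn)
  raw <- anova(lm(y ~ groups))
  expect_equal(res$F, raw$`F value`[1], tolerance = 1e-10)
  expect_equal(res$p, raw$`Pr(>F)`[1], tolerance = 1e-10)
  expect_equal(c(res$df_between, res$df_within), raw$Df)
  # equal means -> F = 0
  expect_equal(anova_from_summary(c(5, 5, 5), c(1, 2, 1), c(4, 4, 4))$F, 0)
  expect_error(anova_from_summary(c(5, 6), c(1, 1), c(1, 5)), "n >= 2")
})

test_that("chi-squared independence test is Pearson without correction", {
  tab <- matrix(c(10, 20, 15, 25, 12, 18), nrow = 2)
  res <- chi_square_independence(tab)
  ref <- suppressWarnings(chisq.test(tab, correct = FALSE))
  expect_equal(res$chisq, unname(ref$statistic), tolerance = 1e-12)
  expect_equal(res$df, unname(ref$parameter))
  # invariance to row/column permutation
  expect_equal(chi_square_independence(tab[2:1, ])$chisq, res$chisq)
  expect_equal(chi_square_independence(tab[, c(3, 1, 2)])$chisq, res$chisq)
  # perfectly proportional table -> 0
  prop <- rbind(c(10, 20, 30), c(5, 10, 15))
  expect_equal(chi_square_independence(prop)$chisq, 0, tolerance = 1e-12)
  expect_error(chi_square_independence(rbind(c(0, 0), c(1, 2))),
               "zero marginal")
})

test_that("vascular risk scoring and thresholding", {
  res <- vascular_risk_score(c(FALSE, TRUE, TRUE),
                             c(FALSE, TRUE, FALSE),
                             c(FALSE, TRUE, FALSE),
                             c(FALSE, TRUE, TRUE))
  expect_equal(res$score, c(0L, 4L, 2L))
  expect_equal(res$at_risk, c(FALSE, TRUE, TRUE))
  expect_error(vascular_risk_score(NA, TRUE, TRUE, TRUE), "TRUE/FALSE")
})

test_that("Pearson correlation matches the closed form and cor.test", {
  x <- c(1, 2, 3, 4); y <- c(2, 1, 4, 3)
  res <- pearson_corr(x, y)
  r_hand <- sum((x - mean(x)) * (y - mean(y))) /
    sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
  expect_equal(res$r, r_hand, tolerance = 1e-12)
  ref <- cor.test(x, y)
  expect_equal(res$p, ref$p.value, tolerance = 1e-12)
  expect_equal(pearson_corr(x, x)$r, 1)
  expect_equal(pearson_corr(x, -x)$r, -1)
  expect_error(pearson_corr(x, rep(1, 4)), "constant")
})

test_that("partial correlation equals the two-stage residual oracle", {
  set.seed(9)
  n <- 40
  cov1 <- rnorm(n); cov2 <- factor(sample(c("a", "b"), n, TRUE))
  x <- 0.5 * cov1 + rnorm(n)
  y <- -0.3 * cov1 + 0.4 * x + rnorm(n)
  covs <- data.frame(c1 = cov1, c2 = cov2)
  res <- partial_corr(x, y, covs)
  mm <- model.matrix(~ c1 + c2, covs)
  rx <- residuals(lm(x ~ mm - 1))
  ry <- residuals(lm(y ~ mm - 1))
  expect_equal(res$r, cor(rx, ry), tolerance = 1e-10)
  # reduction to Pearson with no covariates
  expect_equal(partial_corr(x, y)$r, pearson_corr(x, y)$r)
  # affine rescaling of covariates changes nothing
  covs2 <- data.frame(c1 = 100 + 7 * cov1, c2 = cov2)
  expect_equal(partial_corr(x, y, covs2)$r, res$r, tolerance = 1e-10)
  expect_error(partial_corr(x, y, data.frame(c1 = cov1, c1b = 2 * cov1)),
               "singular")
  expect_error(partial_corr(x, y, data.frame(c1 = x)), "collinear")
})

test_that("post-hoc pairwise t tests from summaries behave as documented", {
  # identical groups -> corrected p = 1
  eq <- pairwise_posthoc(c(5, 5, 5), c(1, 1, 1), c(10, 10, 10))
  expect_true(all(eq$p_bonferroni == 1))
  # two groups -> single comparison, no correction
  two <- pairwise_posthoc(c(5, 6), c(1, 1), c(10, 10))
  expect_equal(nrow(two), 1)
  expect_equal(two$p_bonferroni, two$p)
  # oldest-vs-youngest age contrast from the bundled cohort summary:
  # pooled t should be clearly significant before correction
  s <- example_cohort_summary()$age
  res <- pairwise_posthoc(s$mean, s$sd, s$n, labels = s$group)
  ctl_ad <- res[res$group1 == "control" & res$group2 == "ad", ]
  sp2 <- ((20 - 1) * 8.3^2 + (13 - 1) * 6.2^2) / (20 + 13 - 2)
  t_hand <- (67.4 - 74.9) / sqrt(sp2 * (1 / 20 + 1 / 13))
  expect_equal(ctl_ad$t, t_hand, tolerance = 1e-12)
  expect_lt(ctl_ad$p, 0.05)
})

test_that("percent-to-count conversion rounds to whole subjects", {
  expect_equal(counts_from_percent(c(80, 59, 51, 23), c(20, 44, 45, 13)),
               c(16L, 26L, 23L, 3L))
  expect_equal(counts_from_percent(c(30, 36, 31, 46), c(20, 44, 45, 13)),
               c(6L, 16L, 14L, 6L))
  expect_error(counts_from_percent(120, 10), "\\[0,100\\]")
})
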