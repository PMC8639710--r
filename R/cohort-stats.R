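#' One-way ANOVA from group summary statistics
#'
#' Recovers the one-way ANOVA F test from per-group means, standard
#' deviations and sizes alone:
#' `F = [sum n_i (m_i - m)^2 / (k-1)] / [sum (n_i - 1) s_i^2 / (N-k)]`
#' with `m` the size-weighted grand mean. Identical to a raw-data
#' one-way ANOVA whenever the summaries were computed with the sample
#' (n-1) SD.
#'
#' @param means,sds,ns numeric vectors of per-group mean, SD and size
#'   (all the same length, every `ns >= 2`).
#' @return list with `F`, `df_between`, `df_within`, `p`.
#' @export
anova_from_summary <- function(means, sds, ns) {
  k <- length(means)
  if (k < 2) stop("need at least two groups")
  if (length(sds) != k || length(ns) != k)
    stop("means, sds and ns must have equal length")
  if (any(ns < 2)) stop("every group needs n >= 2")
  N <- sum(ns)
  grand <- sum(ns * means) / N
  ms_between <- sum(ns * (means - grand)^2) / (k - 1)
  ms_within <- sum((ns - 1) * sds^2) / (N - k)
  f <- ms_between / ms_within
  list(F = f, df_between = k - 1, df_within = N - k,
       p = pf(f, k - 1, N - k, lower.tail = FALSE))
}

#' Pearson chi-squared test of independence for a 2 x k table
#'
#' Plain Pearson statistic without continuity correction, as used for
#' comparing sex and vascular-risk frequencies across groups.
#'
#' @param counts 2 x k matrix of counts.
#' @return list with `chisq`, `df`, `p`.
#' @export
chi_square_independence <- function(counts) {
  counts <- as.matrix(counts)
  if (nrow(counts) != 2) stop("counts must be a 2 x k table")
  if (any(rowSums(counts) == 0) || any(colSums(counts) == 0))
    stop("zero marginal in the contingency table")
  expected <- outer(rowSums(counts), colSums(counts)) / sum(counts)
  if (any(expected <= 0)) stop("expected counts must be positive")
  stat <- sum((counts - expected)^2 / expected)
  df <- (nrow(counts) - 1) * (ncol(counts) - 1)
  list(chisq = stat, df = df, p = pchisq(stat, df, lower.tail = FALSE))
}

#' Aggregated vascular risk score
#'
#' One point each for hypertension, dyslipidaemia, diabetes and smoking
#' history (score range 0-4); subjects at or above the threshold of 2
#' are flagged as carrying overall vascular risk.
#'
#' @param hypertension,dyslipidaemia,diabetes,smoking logical vectors
#'   (recycled to a common length).
#' @param threshold score at or above which the risk indicator is TRUE.
#' @return data.frame with integer `score` (0-4) and logical `at_risk`.
#' @export
vascular_risk_score <- function(hypertension, dyslipidaemia, diabetes,
                                smoking, threshold = 2L) {
  flags <- cbind(as.logical(hypertension), as.logical(dyslipidaemia),
                 as.logical(diabetes), as.logical(smoking))
  if (any(is.na(flags))) stop("risk flags must be TRUE/FALSE")
  score <- as.integer(rowSums(flags))
  data.frame(score = score, at_risk = score >= threshold)
}

#' Pearson correlation with two-sided t test
#'
#' @param x,y numeric vectors (n >= 3, non-constant).
#' @return list with `r`, `p`, `df`.
#' @export
pearson_corr <- function(x, y) {
  n <- length(x)
  if (length(y) != n) stop("x and y must have equal length")
  if (n < 3) stop("need at least 3 observations")
  if (sd(x) == 0 || sd(y) == 0) stop("constant input has no correlation")
  r <- cor(x, y)
  df <- n - 2
  tstat <- r * sqrt(df / (1 - r^2))
  list(r = r, p = 2 * pt(-abs(tstat), df), df = df)
}

#' Partial correlation controlling for covariates
#'
#' Correlation of the residuals of `x` and `y` after linear projection
#' onto the covariates (with intercept); the t-based p-value uses
#' `n - 2 - #covariate columns` degrees of freedom. With no covariates
#' this reduces exactly to [pearson_corr()].
#'
#' @param x,y numeric vectors.
#' @param covariates data.frame (or matrix) of covariate columns;
#'   factors are expanded to dummies.
#' @return list with `r`, `p`, `df`.
#' @export
partial_corr <- function(x, y, covariates = NULL) {
  n <- length(x)
  if (length(y) != n) stop("x and y must have equal length")
  if (is.null(covariates) || ncol(as.data.frame(covariates)) == 0)
    return(pearson_corr(x, y))
  cdf <- as.data.frame(covariates)
  mm <- model.matrix(~., data = cdf)
  if (qr(mm)$rank < ncol(mm))
    stop("singular covariate design")
  ncov <- ncol(mm) - 1
  if (n <= ncov + 2) stop("too few observations for the covariate set")
  rx <- lm.fit(mm, x)$residuals
  ry <- lm.fit(mm, y)$residuals
  if (sd(rx) < 1e-12 * max(sd(x), 1) || sd(ry) < 1e-12 * max(sd(y), 1))
    stop("a variable is collinear with the covariates")
  r <- cor(rx, ry)
  df <- n - 2 - ncov
  tstat <- r * sqrt(df / (1 - r^2))
  list(r = r, p = 2 * pt(-abs(tstat), df), df = df)
}

#' Pairwise post-hoc t tests from summary statistics
#'
#' Two-sample pooled-variance t tests for every pair of groups, computed
#' from per-group mean/SD/n, with Bonferroni multiplication by the
#' number of pairs (capped at 1).
#'
#' @inheritParams anova_from_summary
#' @param labels optional group labels.
#' @param welch use Welch (unequal-variance) tests instead of pooled.
#' @return data.frame with one row per pair: `group1`, `group2`, `t`,
#'   `df`, `p`, `p_bonferroni`.
#' @export
pairwise_posthoc <- function(means, sds, ns, labels = NULL, welch = FALSE) {
  k <- length(means)
  if (k < 2) stop("need at least two groups")
  if (any(ns < 2)) stop("every tested group needs n >= 2")
  if (is.null(labels)) labels <- paste0("g", seq_len(k))
  pairs <- utils::combn(k, 2)
  n_pairs <- ncol(pairs)
  rows <- lapply(seq_len(n_pairs), function(j) {
    i1 <- pairs[1, j]; i2 <- pairs[2, j]
    if (welch) {
      v1 <- sds[i1]^2 / ns[i1]; v2 <- sds[i2]^2 / ns[i2]
      tstat <- (means[i1] - means[i2]) / sqrt(v1 + v2)
      df <- (v1 + v2)^2 / (v1^2 / (ns[i1] - 1) + v2^2 / (ns[i2] - 1))
    } else {
      sp2 <- ((ns[i1] - 1) * sds[i1]^2 + (ns[i2] - 1) * sds[i2]^2) /
        (ns[i1] + ns[i2] - 2)
      tstat <- (means[i1] - means[i2]) /
        sqrt(sp2 * (1 / ns[i1] + 1 / ns[i2]))
      df <- ns[i1] + ns[i2] - 2
    }
    p <- 2 * pt(-abs(tstat), df)
    data.frame(group1 = labels[i1], group2 = labels[i2],
               t = tstat, df = df, p = p,
               p_bonferroni = min(1, p * n_pairs),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Convert printed group percentages to integer counts
#'
#' @param percent vector of percentages (0-100).
#' @param ns group sizes.
#' @return integer counts, rounded to the nearest whole subject.
#' @export
counts_from_percent <- function(percent, ns) {
  if (any(percent < 0 | percent > 100)) stop("percentages must be in [0,100]")
  as.integer(round(percent / 100 * ns))
}

#' Bundled demographic summary of a three-site cognitive-decline cohort
#'
#' Printed group-level summary statistics (means, SDs, sizes and
#' percentages) for a 122-participant cohort spanning controls,
#' subjective cognitive decline, mild cognitive impairment and probable
#' Alzheimer's dementia, used in examples and for validating the
#' summary-statistic tests: global cognition (ACE-III, 0-100), age,
#' percent female, and percent with aggregated vascular risk score >= 2.
#'
#' @return list of data.frames: `ace` and `age` (group, mean, sd, n),
#'   `sex_pct_female` and `vascular_pct` (group, percent, n).
#' @export
example_cohort_summary <- function() {
  groups <- c("control", "scd", "mci", "ad")
  n <- c(20L, 44L, 45L, 13L)
  list(
    ace = data.frame(group = groups, mean = c(94.6, 91.7, 85.2, 79.2),
                     sd = c(3.8, 4.9, 7.1, 6.2), n = n),
    age = data.frame(group = groups, mean = c(67.4, 69.0, 71.1, 74.9),
                     sd = c(8.3, 7.7, 7.1, 6.2), n = n),
    sex_pct_female = data.frame(group = groups,
                                percent = c(80, 59, 51, 23), n = n),
    vascular_pct = data.frame(group = groups,
                              percent = c(30, 36, 31, 46), n = n))
}
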