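test_that("restriction parsing and display round-trip", {
  r <- parse_restriction("[control=scd]<mci<ad")
  expect_s3_class(r, "order_restriction")
  expect_equal(r$blocks, list(c("control", "scd"), "mci", "ad"))
  expect_equal(r$label, "[control=scd]<mci<ad")
  expect_error(order_restriction(list(c("a", "b"), "a")), "more than one block")
  expect_length(default_restrictions(), 4)
})

test_that("prior constraint probabilities are 1/k! and match prior sampling", {
  r <- default_restrictions()
  expect_equal(prior_constraint_probability(r$M1), 1 / 24)
  expect_equal(prior_constraint_probability(r$M2), 1 / 6)
  expect_equal(prior_constraint_probability(r$M3), 1 / 6)
  expect_equal(prior_constraint_probability(r$M4), 1 / 2)
  # Monte-Carlo oracle: exchangeable draws, count orderings
  set.seed(11)
  for (k in c(2, 4)) {
    n <- 2e5
    draws <- matrix(rnorm(n * k), n, k)
    p_hat <- mean(apply(draws, 1, function(a) all(diff(a) > 0)))
    se <- sqrt(p_hat * (1 - p_hat) / n)
    expect_lt(abs(p_hat - 1 / factorial(k)), 3 * se + 1e-12)
  }
})

test_that("equality-block merging collapses the factor as specified", {
  d <- data.frame(group = rep(c("control", "scd", "mci", "ad"),
                              times = c(20, 44, 45, 13)),
                  scov = 0)
  r <- default_restrictions()
  m1 <- merge_equality_blocks(d, r$M1)
  expect_equal(nlevels(m1$group), 4)
  expect_equal(nrow(m1), nrow(d))
  m4 <- merge_equality_blocks(d, r$M4)
  expect_equal(nlevels(m4$group), 2)
  expect_equal(unname(table(m4$group)), array(c(64L, 58L)))
  expect_warning(merge_equality_blocks(
    d, order_restriction(list(c("control", "scd", "mci", "ad")))),
    "degenerate")
  expect_error(merge_equality_blocks(d, parse_restriction("control<scd<mci")),
               "absent from the restriction")
})

test_that("quadrature BF matches a brute-force 2-D numerical integration", {
  d <- tiny_ancova_data()
  impl <- bf_groups_vs_null(d, "scov", covariates = "age")
  # independent oracle: explicit Gaussian integrals over coefficients,
  # then log-grid integration over (g, sigma^2)
  h <- 0.5
  W <- cbind(1, (d$age - mean(d$age)) / sd(d$age))
  k <- 4
  Cm <- model.matrix(~ group - 1, d)
  ev <- eigen(diag(k) - 1 / k, symmetric = TRUE)
  Z <- Cm %*% ev$vectors[, ev$values > 0.5]
  y <- d$scov; n <- length(y); p <- ncol(W); q <- ncol(Z)
  X <- cbind(W, Z)
  lg <- seq(log(1e-8), log(1e4), length.out = 400)
  ls <- seq(log(1e-1), log(1e4), length.out = 600)
  gs <- exp(lg); ss <- exp(ls)
  dg <- diff(lg)[1]; dsv <- diff(ls)[1]
  S0 <- sum(y^2) - drop(t(crossprod(W, y)) %*%
                          solve(crossprod(W), crossprod(W, y)))
  ldW <- as.numeric(determinant(crossprod(W))$modulus)
  num <- 0
  for (g in gs) {
    G <- crossprod(X) + diag(c(rep(0, p), rep(1 / g, q)))
    S <- sum(y^2) - drop(t(crossprod(X, y)) %*% solve(G, crossprod(X, y)))
    ldG <- as.numeric(determinant(G)$modulus)
    lpg <- log(h) - 0.5 * log(2 * pi) - 1.5 * log(g) - h^2 / (2 * g)
    lv <- -(n - p) / 2 * log(2 * pi * ss) - q / 2 * log(g) - 0.5 * ldG -
      S / (2 * ss) - log(ss) + lpg + log(g) + log(ss)
    num <- num + sum(exp(lv - 100)) * dg * dsv
  }
  den <- sum(exp(-(n - p) / 2 * log(2 * pi * ss) - 0.5 * ldW -
                   S0 / (2 * ss) - 100)) * dsv
  expect_equal(impl$bf, num / den, tolerance = 5e-4)
})

test_that("rank-deficient designs are rejected, not silently dropped", {
  d <- tiny_ancova_data()
  d$age2 <- d$age
  expect_error(bf_groups_vs_null(d, "scov", covariates = c("age", "age2")),
               "rank-deficient")
  # one subject per two groups, five parameters, five rows: under-determined
  expect_error(bf_groups_vs_null(d[c(1, 2, 4, 7, 10), ], "scov",
                                 covariates = c("age")),
               "fewer subjects|rank-deficient")
})

test_that("the Gibbs sampler is reproducible, convergent, and matches quadrature", {
  d <- simulate_metric_cohort(
    c(control = 40, scd = 40, mci = 40, ad = 40),
    c(control = 40, scd = 41, mci = 45, ad = 49), sigma = 6, seed = 3)
  s1 <- sample_posterior(d, "scov", n_draws = 4000, seed = 21)
  s2 <- sample_posterior(d, "scov", n_draws = 4000, seed = 21)
  expect_identical(s1$alpha, s2$alpha)
  expect_lte(max(s1$rhat), 1.01)
  # Rao-Blackwell oracle: E[alpha | y] by 1-D quadrature over p(g | y)
  des_d <- merge_equality_blocks(d, default_restrictions()$M1)
  W <- cbind(1, (d$age - mean(d$age)) / sd(d$age),
             stats::model.matrix(~ f, data.frame(f = factor(d$sex)),
                                 contrasts.arg = list(f = "contr.sum"))[, -1],
             stats::model.matrix(~ f, data.frame(f = factor(d$site)),
                                 contrasts.arg = list(f = "contr.sum"))[, -1])
  k <- 4
  ev <- eigen(diag(k) - 1 / k, symmetric = TRUE)
  Q <- ev$vectors[, ev$values > 0.5]
  Z <- model.matrix(~ group - 1, d) %*% Q
  X <- cbind(W, Z); y <- d$scov
  n <- length(y); p <- ncol(W); q <- ncol(Z); h <- 0.5
  lg <- seq(log(1e-7), log(1e4), length.out = 900)
  wts <- numeric(length(lg)); means <- matrix(0, length(lg), q)
  S0 <- sum(y^2) - drop(t(crossprod(W, y)) %*%
                          solve(crossprod(W), crossprod(W, y)))
  for (i in seq_along(lg)) {
    g <- exp(lg[i])
    G <- crossprod(X) + diag(c(rep(0, p), rep(1 / g, q)))
    b <- solve(G, crossprod(X, y))
    S <- sum(y^2) - drop(t(crossprod(X, y)) %*% b)
    ldG <- as.numeric(determinant(G)$modulus)
    lw <- -q / 2 * log(g) - 0.5 * ldG - (n - p) / 2 * log(S) +
      log(h) - 0.5 * log(2 * pi) - 1.5 * log(g) - h^2 / (2 * g) + lg[i]
    wts[i] <- lw
    means[i, ] <- b[(p + 1):(p + q)]
  }
  wts <- exp(wts - max(wts)); wts <- wts / sum(wts)
  alpha_expected <- drop(Q %*% colSums(means * wts))
  alpha_mc <- colMeans(s1$alpha)
  mc_se <- apply(s1$alpha, 2, sd) / sqrt(s1$ess)
  expect_true(all(abs(alpha_mc - alpha_expected) < 3.5 * mc_se + 1e-8))
})

test_that("the encompassing identity holds and agrees with draw counting", {
  d <- simulate_metric_cohort(
    c(control = 50, scd = 50, mci = 50, ad = 50),
    c(control = 40, scd = 40, mci = 45, ad = 50), sigma = 8, seed = 8)
  r2 <- default_restrictions()$M2
  res <- bf_order_restricted(d, "scov", r2, n_draws = 4000, seed = 5)
  expect_equal(res$bf_vs_null,
               res$bf_full_vs_null * res$posterior_constraint_prob /
                 res$prior_constraint_prob)
  # counting oracle for the prior proportion (exchangeable draws)
  set.seed(99)
  ndr <- 2e5
  kb <- length(r2$blocks)
  pri <- matrix(rnorm(ndr * kb), ndr, kb)
  p_hat <- mean(apply(pri, 1, function(a) all(diff(a) > 0)))
  se_hat <- sqrt(p_hat * (1 - p_hat) / ndr)
  expect_lt(abs(p_hat - res$prior_constraint_prob), 3 * se_hat)
  # independent posterior counting run (different seed) agrees within MC error
  res_b <- bf_order_restricted(d, "scov", r2, n_draws = 4000, seed = 31)
  se_comb <- sqrt(res$mc_standard_error^2 + res_b$mc_standard_error^2)
  expect_lt(abs(res$bf_vs_null - res_b$bf_vs_null), 3 * se_comb + 1e-9)
})

test_that("overwhelming ordering drives the restricted/full BF ratio to k!", {
  d <- simulate_metric_cohort(
    c(control = 60, scd = 60, mci = 60, ad = 60),
    c(control = 10, scd = 30, mci = 50, ad = 70), sigma = 3, seed = 12)
  res <- bf_order_restricted(d, "scov", default_restrictions()$M1,
                             n_draws = 3000, seed = 2)
  expect_equal(res$posterior_constraint_prob, 1)
  expect_equal(res$bf_vs_null / res$bf_full_vs_null, factorial(4))
})

test_that("pairwise BF comparison obeys the ratio identities", {
  d <- simulate_metric_cohort(
    c(control = 40, scd = 40, mci = 40, ad = 40),
    c(control = 40, scd = 40, mci = 45, ad = 49), sigma = 8, seed = 4)
  rs <- default_restrictions()[c("M1", "M2", "M3")]
  res <- lapply(seq_along(rs), function(i)
    bf_order_restricted(d, "scov", rs[[i]], n_draws = 2000,
                        seed = 100 + i))
  names(res) <- names(rs)
  pb <- compare_restrictions(res)
  expect_equal(unname(diag(pb)), rep(1, 3))
  expect_equal(pb["M1", "M2"] * pb["M2", "M3"], pb["M1", "M3"],
               tolerance = 1e-12)
  expect_equal(pb["M2", "M1"],
               res$M2$bf_vs_null / res$M1$bf_vs_null, tolerance = 1e-12)
  other <- simulate_metric_cohort(
    c(control = 40, scd = 40, mci = 40, ad = 40),
    c(control = 40, scd = 40, mci = 45, ad = 49), sigma = 8, seed = 77)
  res_other <- bf_order_restricted(other, "scov", rs$M1, n_draws = 2000,
                                   seed = 1)
  expect_error(compare_restrictions(list(res$M1, res_other)),
               "same dataset")
})

test_that("five-group restrictions run through the same machinery", {
  d5 <- simulate_metric_cohort(
    c(control = 30, scd = 30, amci = 30, mmci = 30, ad = 30),
    c(control = 40, scd = 40, amci = 44, mmci = 46, ad = 50),
    sigma = 7, seed = 6)
  r5 <- parse_restriction("[control=scd]<amci<mmci<ad")
  res <- bf_order_restricted(d5, "scov", r5, n_draws = 2000, seed = 3)
  expect_equal(length(r5$blocks), 4)
  expect_equal(res$prior_constraint_prob, 1 / 24)
  expect_equal(res$bf_vs_null,
               res$bf_full_vs_null * res$posterior_constraint_prob /
                 res$prior_constraint_prob)
})

test_that("null-generated data yields evidence for the null", {
  bfs <- sapply(1:8, function(i) {
    d <- simulate_metric_cohort(
      c(control = 50, scd = 50, mci = 50, ad = 50),
      c(control = 42, scd = 42, mci = 42, ad = 42), sigma = 8,
      seed = 500 + i)
    bf_order_restricted(d, "scov", default_restrictions()$M2,
                        n_draws = 2000, seed = i)$bf_vs_null
  })
  expect_lt(median(bfs), 1)
})
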