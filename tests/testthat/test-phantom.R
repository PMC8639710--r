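test_that("partial volume fractions are valid on every grid", {
  for (gd in list(c(16L, 16L, 16L), c(32L, 32L, 24L))) {
    ph <- build_phantom(quiet_config(grid_dim = gd), "control",
                        default_covariates())
    for (pv in list(ph$pv_gm, ph$pv_wm, ph$pv_csf)) {
      expect_true(all(pv >= 0 & pv <= 1))
    }
    expect_true(all(ph$pv_gm + ph$pv_wm + ph$pv_csf <= 1 + 1e-9))
    expect_true(all(ph$cbf_true >= 0))
    expect_true(all(ph$att_true[(ph$pv_gm + ph$pv_wm) > 0] > 0))
    expect_true(all(ph$abv >= 0 & ph$abv <= 1))
  }
})

test_that("ROI label map contains all nine named regions", {
  for (gd in list(c(16L, 16L, 16L), c(32L, 32L, 24L))) {
    ph <- build_phantom(quiet_config(grid_dim = gd), "ad",
                        default_covariates())
    rois <- roi_set_from_phantom(ph)
    expect_setequal(names(rois), roi_names())
    for (nm in names(rois)) expect_gt(sum(rois[[nm]]), 0)
    for (nm in setdiff(roi_names(), "gm"))
      expect_true(all(rois$gm[rois[[nm]]]))
  }
})

test_that("a no-effect configuration yields constant ATT on tissue", {
  cfg <- quiet_config(posterior_att_increment = 0, att_gradient = 0)
  ph <- build_phantom(cfg, "scd", default_covariates())
  tissue <- (ph$pv_gm + ph$pv_wm) > 0
  expect_equal(diff(range(ph$att_true[tissue])), 0)
})

test_that("group ATT offsets are recovered from the generated maps", {
  cfg <- quiet_config(att_offsets = c(control = 0, scd = 0, amci = 0,
                                      mmci = 0, ad = 0.3))
  cov <- default_covariates()
  ctl <- build_phantom(cfg, "control", cov)
  ad <- build_phantom(cfg, "ad", cov)
  gm <- binarise_mask(ctl$pv_gm)
  expect_equal(mean(ad$att_true[gm]) - mean(ctl$att_true[gm]), 0.3,
               tolerance = 1e-10)
})

test_that("mean GM ATT matches the configured subject-level value", {
  cfg <- quiet_config(age_att_slope = 0.005)
  ph <- build_phantom(cfg, "amci", list(age = 78, sex = "m", site = "site1"))
  expected <- cfg$base_att + cfg$att_offsets[["amci"]] +
    cfg$age_att_slope * (78 - cfg$reference_age)
  expect_equal(ph$mean_gm_att, expected, tolerance = 1e-10)
})

test_that("unknown group or bad grid is rejected", {
  expect_error(build_phantom(quiet_config(), "dementia",
                             default_covariates()), "unknown group")
  expect_error(cohort_config(grid_dim = c(8L, 8L, 8L)), ">= 16")
  expect_error(cohort_config(site_probs = c(site1 = 0.5, site2 = 0.2,
                                            site3 = 0.2)), "sum to 1")
})

test_that("cohort simulation is deterministic and sized exactly", {
  cfg <- cohort_config(grid_dim = c(16L, 16L, 16L), seed = 7L,
                       group_sizes = c(control = 3L, scd = 2L, amci = 2L,
                                       mmci = 1L, ad = 2L))
  sim1 <- simulate_cohort(cfg)
  sim2 <- simulate_cohort(cfg)
  expect_identical(sim1$records, sim2$records)
  expect_identical(sim1$subjects[[5]], sim2$subjects[[5]])
  expect_equal(as.vector(table(sim1$records$group)), c(3, 2, 2, 1, 2))
  expect_equal(nrow(sim1$records), 10)
})

test_that("default cohort has 122 subjects with the published group sizes", {
  cfg <- cohort_config()
  expect_equal(sum(cfg$group_sizes), 122)
  expect_equal(unname(cfg$group_sizes[c("control", "scd", "ad")]),
               c(20L, 44L, 13L))
  expect_equal(sum(cfg$group_sizes[c("amci", "mmci")]), 45L)
  g4 <- collapse_mci(rep(names(cfg$group_sizes), cfg$group_sizes))
  expect_equal(unname(table(g4)[["mci"]]), 45L)
})

test_that("covariate sampling follows the configured distributions", {
  cfg <- cohort_config()
  # degenerate age distribution
  cfg0 <- cohort_config(age_sd = c(control = 0, scd = 0, amci = 0,
                                   mmci = 0, ad = 0))
  set.seed(1)
  ages <- replicate(20, sample_covariates("ad", cfg0)$age)
  expect_true(all(ages == 74.9))
  # Monte-Carlo mean within 3 SD/sqrt(n) of the configured mean
  n <- 4000
  set.seed(2)
  draws <- replicate(n, sample_covariates("control", cfg)$age)
  expect_lt(abs(mean(draws) - 67.4), 3 * 8.3 / sqrt(n))
  # sex proportion within exact binomial 99% bounds
  cfg8 <- cohort_config(sex_prop_female = c(control = 0.8, scd = 0.5,
                                            amci = 0.5, mmci = 0.5,
                                            ad = 0.5))
  set.seed(3)
  nf <- sum(replicate(200, sample_covariates("control", cfg8)$sex) == "f")
  bounds <- qbinom(c(0.005, 0.995), 200, 0.8)
  expect_gte(nf, bounds[1])
  expect_lte(nf, bounds[2])
})

test_that("collapse_mci validates its input", {
  expect_error(collapse_mci(c("control", "severe")), "unknown group")
  expect_equal(levels(collapse_mci("amci")), c("control", "scd", "mci", "ad"))
})
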