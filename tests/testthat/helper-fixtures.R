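# Shared fixtures: small, fast configurations used across test files.

# Deterministic tissue-only configuration: no noise, no arterial signal,
# no subject-level ATT randomness, single site.
quiet_config <- function(...) {
  args <- list(att_subject_sd = 0, noise_sd = 0,
               abv_background = 0, abv_vessel = 0,
               site_probs = c(site1 = 1, site2 = 0, site3 = 0),
               age_att_slope = 0, seed = 42L)
  do.call(cohort_config, utils::modifyList(args, list(...)))
}

# A control phantom whose transit times all lie below the PLD, so the
# white-paper quantification is an exact inverse of the forward model.
short_att_phantom <- function(grid_dim = c(16L, 16L, 16L)) {
  cfg <- quiet_config(base_att = 1.0, posterior_att_increment = 0,
                      att_gradient = 0.2, grid_dim = grid_dim)
  build_phantom(cfg, "control", list(age = 70, sex = "f", site = "site1"))
}

default_covariates <- function() list(age = 70, sex = "f", site = "site1")

# Fixed tiny ANCOVA dataset for Bayes-factor oracle comparisons.
tiny_ancova_data <- function() {
  data.frame(
    scov = c(35.1, 38.2, 33.9, 40.5, 41.2, 39.8,
             44.0, 42.5, 47.1, 45.3, 48.8, 50.2),
    group = factor(rep(c("control", "scd", "mci", "ad"), each = 3),
                   levels = c("control", "scd", "mci", "ad")),
    age = c(61, 70, 66, 72, 68, 75, 71, 69, 74, 77, 73, 80))
}
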