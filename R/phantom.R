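#' Cohort configuration for synthetic phantom generation
#'
#' Builds the configuration object that drives [simulate_cohort()]. The
#' defaults emulate a three-site memory-clinic cohort of five ordered
#' groups (control, SCD, aMCI, mMCI, AD) in which arterial transit time
#' (ATT) is progressively prolonged with cognitive decline while regional
#' grey-matter CBF is mildly reduced. Group sizes, ages and sex
#' proportions follow the demographic composition of a published
#' multi-site cognitive-decline cohort (n = 20/44/45/13 with the MCI
#' group split into amnestic and multi-domain halves); ATT and CBF effect
#' sizes are simulation choices, not measured quantities.
#'
#' @param group_sizes named integer vector of subjects per group; names
#'   must be `control, scd, amci, mmci, ad`.
#' @param att_offsets named numeric vector, seconds added to the tissue
#'   ATT of every subject in a group. The default encodes the
#'   "control = SCD < MCI < AD" prolongation pattern.
#' @param att_subject_sd between-subject SD of a random ATT shift
#'   (seconds); set to 0 for fully deterministic group means.
#' @param cbf_effects named list (by group) of named numeric vectors
#'   (by ROI) giving additive changes to pure-GM CBF in ml/100g/min.
#' @param age_mean,age_sd per-group age distributions (years).
#' @param sex_prop_female per-group probability of female sex.
#' @param site_probs probabilities of the three sites (must sum to 1).
#' @param site_att_offsets,site_cbf_offsets additive per-site offsets on
#'   ATT (s) and on tissue CBF (ml/100g/min).
#' @param age_att_slope ATT prolongation with age, seconds per year
#'   (default 0.005 = 5 ms/year).
#' @param reference_age years; age at which the age term vanishes.
#' @param base_att baseline grey-matter ATT in seconds.
#' @param posterior_att_increment extra ATT (s) in the posterior vascular
#'   territory, producing the high-sCoV posterior phenotype.
#' @param att_gradient proximal-to-distal ATT increase (s) across the
#'   brain radius.
#' @param gm_cbf,wm_cbf pure-tissue CBF in ml/100g/min.
#' @param abv_background,abv_vessel arterial blood-volume fraction
#'   outside/inside the macrovascular mask.
#' @param m0_scale equilibrium-magnetisation scale (signal units).
#' @param noise_sd additive Gaussian noise SD per acquired difference
#'   volume (signal units).
#' @param grid_dim integer length-3 grid size (each entry >= 16).
#' @param voxel_dim voxel size in mm.
#' @param seed master seed; every random stream is derived from it.
#' @return object of class `cohort_config` (a validated list).
#' @export
cohort_config <- function(group_sizes = c(control = 20L, scd = 44L,
                                          amci = 23L, mmci = 22L, ad = 13L),
                          att_offsets = c(control = 0, scd = 0,
                                          amci = 0.15, mmci = 0.15, ad = 0.30),
                          att_subject_sd = 0.25,
                          cbf_effects = list(
                            amci = c(pcc = -5, precuneus = -5, hippocampus = -5),
                            mmci = c(pcc = -5, precuneus = -5, hippocampus = -5),
                            ad = c(pcc = -10, precuneus = -10, hippocampus = -8,
                                   angular = -5, temporal = -5)),
                          age_mean = c(control = 67.4, scd = 69.0,
                                       amci = 71.1, mmci = 71.1, ad = 74.9),
                          age_sd = c(control = 8.3, scd = 7.7,
                                     amci = 7.1, mmci = 7.1, ad = 6.2),
                          sex_prop_female = c(control = 0.80, scd = 0.59,
                                              amci = 0.51, mmci = 0.51,
                                              ad = 0.23),
                          site_probs = c(site1 = 0.746, site2 = 0.131,
                                         site3 = 0.123),
                          site_att_offsets = c(site1 = 0, site2 = 0.02,
                                               site3 = -0.02),
                          site_cbf_offsets = c(site1 = 0, site2 = 2,
                                               site3 = -2),
                          age_att_slope = 0.005,
                          reference_age = 70,
                          base_att = 1.4,
                          posterior_att_increment = 0.2,
                          att_gradient = 0.3,
                          gm_cbf = 60, wm_cbf = 20,
                          abv_background = 0.001, abv_vessel = 0.005,
                          m0_scale = 1000,
                          noise_sd = 2,
                          grid_dim = c(32L, 32L, 24L),
                          voxel_dim = c(3, 3, 4),
                          seed = 1L) {
  lv <- group_levels()
  if (!all(lv %in% names(group_sizes)))
    stop("group_sizes must name all of: ", paste(lv, collapse = ", "))
  if (any(group_sizes < 0)) stop("group sizes must be >= 0")
  for (nm in c("att_offsets", "age_mean", "age_sd", "sex_prop_female")) {
    v <- get(nm)
    if (!all(lv %in% names(v)))
      stop(sprintf("'%s' must be named for every group level", nm))
  }
  if (any(sex_prop_female < 0 | sex_prop_female > 1))
    stop("sex proportions must lie in [0,1]")
  if (abs(sum(site_probs) - 1) > 1e-8 || any(site_probs < 0))
    stop("site_probs must be non-negative and sum to 1")
  if (length(grid_dim) != 3L || any(grid_dim < 16))
    stop("grid_dim must be three values, each >= 16")
  cfg <- list(group_sizes = group_sizes[lv], att_offsets = att_offsets[lv],
              att_subject_sd = att_subject_sd, cbf_effects = cbf_effects,
              age_mean = age_mean[lv], age_sd = age_sd[lv],
              sex_prop_female = sex_prop_female[lv],
              site_probs = site_probs, site_att_offsets = site_att_offsets,
              site_cbf_offsets = site_cbf_offsets,
              age_att_slope = age_att_slope, reference_age = reference_age,
              base_att = base_att,
              posterior_att_increment = posterior_att_increment,
              att_gradient = att_gradient,
              gm_cbf = gm_cbf, wm_cbf = wm_cbf,
              abv_background = abv_background, abv_vessel = abv_vessel,
              m0_scale = m0_scale, noise_sd = noise_sd,
              grid_dim = as.integer(grid_dim), voxel_dim = voxel_dim,
              seed = as.integer(seed))
  class(cfg) <- "cohort_config"
  cfg
}

#' Group levels of the simulated cohort
#'
#' @return the five ordered severity levels.
#' @export
group_levels <- function() c("control", "scd", "amci", "mmci", "ad")

#' Collapse the five-level group factor to four levels
#'
#' Merges amnestic and multi-domain MCI into a single `mci` level, the
#' coding used for the primary group comparisons.
#'
#' @param group character vector or factor of five-level group labels.
#' @return factor with levels `control, scd, mci, ad`.
#' @export
collapse_mci <- function(group) {
  g <- as.character(group)
  bad <- setdiff(unique(g), group_levels())
  if (length(bad)) stop("unknown group level(s): ", paste(bad, collapse = ", "))
  g[g %in% c("amci", "mmci")] <- "mci"
  factor(g, levels = c("control", "scd", "mci", "ad"))
}

# Normalised ellipsoidal radius and direction cosines for a grid.
phantom_geometry <- function(grid_dim) {
  nx <- grid_dim[1]; ny <- grid_dim[2]; nz <- grid_dim[3]
  cx <- (seq_len(nx) - (nx + 1) / 2) / (nx / 2)
  cy <- (seq_len(ny) - (ny + 1) / 2) / (ny / 2)
  cz <- (seq_len(nz) - (nz + 1) / 2) / (nz / 2)
  x <- array(rep(cx, times = ny * nz), dim = grid_dim)
  y <- array(rep(rep(cy, each = nx), times = nz), dim = grid_dim)
  z <- array(rep(cz, each = nx * ny), dim = grid_dim)
  u <- sqrt((x / 0.95)^2 + (y / 0.95)^2 + (z / 0.90)^2)
  r <- pmax(u, 1e-9)
  list(x = x, y = y, z = z, u = u,
       dx = x / r, dy = y / r, dz = z / r)
}

# Linear one-voxel ramp: fraction of a voxel lying inside radius b.
pv_ramp <- function(u, b, w) pmin(pmax((b - u) / w + 0.5, 0), 1)

# Integer ROI label codes used in phantom label maps.
roi_label_codes <- function() {
  c(frontal = 1L, parietal = 2L, temporal = 3L, occipital = 4L,
    pcc = 5L, precuneus = 6L, hippocampus = 7L, angular = 8L)
}

# Assign ROI labels on GM voxels from direction cosines.
assign_roi_labels <- function(geom, gm_mask) {
  lab <- array(0L, dim = dim(gm_mask))
  dx <- geom$dx; dy <- geom$dy; dz <- geom$dz
  lob <- ifelse(dy <= -0.6, 4L,
         ifelse(dy >= 0.45, 1L,
         ifelse(dz > 0.35, 2L, 3L)))
  lab[gm_mask] <- lob[gm_mask]
  post_med <- abs(dx) < 0.35
  lab[gm_mask & post_med & dy > -0.8 & dy < -0.55 &
        dz > 0.05 & dz <= 0.6] <- 5L                      # PCC
  lab[gm_mask & post_med & dy > -0.8 & dy < -0.45 &
        dz > 0.6] <- 6L                                   # precuneus
  lab[gm_mask & abs(dx) >= 0.3 & dy > -0.2 & dy < 0.2 &
        dz <= -0.45] <- 7L                                # hippocampus
  lab[gm_mask & abs(dx) >= 0.55 & dy > -0.6 & dy < -0.2 &
        dz > -0.1 & dz <= 0.45] <- 8L                     # angular gyrus
  lab
}

#' Build one digital brain phantom
#'
#' Generates a stylised three-shell "brain" (CSF rim, GM ribbon, WM core)
#' on a regular grid, with partial-volume fractions mixed linearly over
#' one voxel at tissue boundaries, ground-truth CBF and ATT maps, a
#' macrovascular compartment, an equilibrium-magnetisation map and an
#' integer ROI label map (four lobes plus PCC, precuneus, hippocampus and
#' angular gyrus parcels).
#'
#' The tissue ATT map is
#' `base_att + group offset + site offset + age_att_slope * (age - reference_age)`
#' plus a zero-GM-mean spatial pattern (posterior-territory increment and
#' proximal-to-distal gradient) and an optional subject-level random
#' shift, so the spatial mean over the GM mask equals the configured
#' subject-level ATT exactly when `att_subject_sd = 0`.
#'
#' @param config a [cohort_config()].
#' @param group one of the five group levels.
#' @param covariates list with elements `age` (years), `sex`
#'   (`"f"`/`"m"`) and `site` (a name of `config$site_probs`).
#' @param seed integer stream seed for the subject-level ATT shift.
#' @return object of class `phantom`: partial-volume maps `pv_gm`,
#'   `pv_wm`, `pv_csf`; pure-tissue CBF maps `cbf_gm`, `cbf_wm`;
#'   per-voxel delivered CBF `cbf_true = pv_gm*cbf_gm + pv_wm*cbf_wm`;
#'   tissue and arterial transit maps `att_true`, `att_arterial`;
#'   `arterial_mask`, `abv`, `m0_tissue`, `roi_labels`, plus grid
#'   metadata and subject-level ground truth `mean_gm_att`.
#' @export
build_phantom <- function(config, group, covariates, seed = config$seed) {
  if (!inherits(config, "cohort_config")) stop("config must be a cohort_config")
  if (!group %in% group_levels())
    stop("unknown group level: ", group)
  if (any(config$grid_dim <= 0)) stop("grid dimensions must be positive")
  age <- covariates$age; sex <- covariates$sex; site <- covariates$site
  if (!site %in% names(config$site_probs)) stop("unknown site: ", site)

  geom <- phantom_geometry(config$grid_dim)
  w <- 2 / min(config$grid_dim)         # one-voxel ramp width (radial units)
  pv_wm <- pv_ramp(geom$u, 0.55, w)
  pv_gm <- pv_ramp(geom$u, 0.82, w) - pv_wm
  pv_csf <- pv_ramp(geom$u, 0.92, w) - pv_ramp(geom$u, 0.82, w)
  gm_mask <- pv_gm >= 0.25
  tissue <- (pv_gm + pv_wm) > 0

  # ATT: subject-level value plus a spatial pattern centred on the GM mask
  subject_att <- config$base_att +
    config$att_offsets[[group]] +
    config$site_att_offsets[[site]] +
    config$age_att_slope * (age - config$reference_age)
  if (config$att_subject_sd > 0)
    subject_att <- subject_att +
      with_seed(seed, rnorm(1, 0, config$att_subject_sd))
  pattern <- config$posterior_att_increment * (geom$dy < -0.35) +
    config$att_gradient * geom$u
  pattern <- pattern - mean(pattern[gm_mask])
  att_true <- pmax(subject_att + pattern, 0.3)
  att_true[!tissue] <- 0.3

  # CBF: pure-tissue maps with regional group effects on GM
  labels <- assign_roi_labels(geom, gm_mask)
  cbf_gm <- array(config$gm_cbf + config$site_cbf_offsets[[site]],
                  dim = config$grid_dim)
  eff <- config$cbf_effects[[group]]
  if (!is.null(eff)) {
    codes <- roi_label_codes()
    for (nm in names(eff)) {
      if (!nm %in% names(codes))
        stop("cbf_effects names must be ROI names; got: ", nm)
      cbf_gm[labels == codes[[nm]]] <- cbf_gm[labels == codes[[nm]]] + eff[[nm]]
    }
  }
  cbf_gm <- pmax(cbf_gm, 0)
  cbf_wm <- array(pmax(config$wm_cbf + config$site_cbf_offsets[[site]], 0),
                  dim = config$grid_dim)
  cbf_true <- pv_gm * cbf_gm + pv_wm * cbf_wm

  # Macrovascular compartment: two feeding columns entering inferiorly
  arterial_mask <- geom$u < 0.92 & geom$dz < 0 &
    ((geom$x - 0.25)^2 + (geom$y + 0.25)^2 < 0.012 |
     (geom$x + 0.25)^2 + (geom$y + 0.25)^2 < 0.012)
  abv <- array(0, dim = config$grid_dim)
  abv[tissue] <- config$abv_background
  abv[arterial_mask] <- config$abv_vessel
  att_arterial <- pmax(att_true - 0.3, 0.2)

  m0_tissue <- config$m0_scale * (pv_gm + pv_wm + 0.3 * pv_csf)

  structure(list(pv_gm = pv_gm, pv_wm = pv_wm, pv_csf = pv_csf,
                 cbf_gm = cbf_gm, cbf_wm = cbf_wm, cbf_true = cbf_true,
                 att_true = att_true, att_arterial = att_arterial,
                 arterial_mask = arterial_mask, abv = abv,
                 m0_tissue = m0_tissue, roi_labels = labels,
                 grid_dim = config$grid_dim, voxel_dim = config$voxel_dim,
                 group = group, age = age, sex = sex, site = site,
                 mean_gm_att = mean(att_true[gm_mask]), seed = seed),
            class = "phantom")
}

#' @export
print.phantom <- function(x, ...) {
  cat(sprintf("<phantom> %s grid, group=%s, site=%s, age=%.1f\n",
              paste(x$grid_dim, collapse = "x"), x$group, x$site, x$age))
  cat(sprintf("  mean GM ATT %.3f s; GM voxels %d; arterial voxels %d\n",
              x$mean_gm_att, sum(x$pv_gm >= 0.25), sum(x$arterial_mask)))
  invisible(x)
}

#' Draw subject covariates for a group
#'
#' Samples age from the configured per-group normal distribution, sex
#' from the per-group female proportion, and site from the configured
#' site probabilities. Uses the current RNG state.
#'
#' @param group group level.
#' @param config a [cohort_config()].
#' @return list with `age`, `sex` (`"f"`/`"m"`), `site`.
#' @export
sample_covariates <- function(group, config) {
  if (!group %in% names(config$age_mean))
    stop("group not configured: ", group)
  age <- rnorm(1, config$age_mean[[group]], config$age_sd[[group]])
  sex <- if (runif(1) < config$sex_prop_female[[group]]) "f" else "m"
  site <- sample(names(config$site_probs), 1, prob = config$site_probs)
  list(age = age, sex = sex, site = site)
}

#' Simulate a full phantom cohort
#'
#' Generates one phantom per subject with group sizes exactly as
#' configured; all randomness derives from `config$seed`, so identical
#' configurations reproduce identical cohorts.
#'
#' @param config a [cohort_config()].
#' @param per_subject optional function `f(phantom, record)`; when given,
#'   its return value is stored in place of the phantom (e.g. to stream
#'   per-subject metrics without holding every phantom in memory).
#' @return list with `records` (data.frame: id, group, group4, age, sex,
#'   site, seed, mean_gm_att) and `subjects` (list of phantoms or
#'   `per_subject` results, in record order).
#' @export
simulate_cohort <- function(config, per_subject = NULL) {
  if (!inherits(config, "cohort_config")) stop("config must be a cohort_config")
  n_total <- sum(config$group_sizes)
  if (n_total == 0) stop("cohort has zero subjects")
  groups <- rep(names(config$group_sizes), times = config$group_sizes)
  subjects <- vector("list", n_total)
  rec <- vector("list", n_total)
  for (i in seq_len(n_total)) {
    seed_i <- derive_seed(config$seed, i)
    cov <- with_seed(seed_i, sample_covariates(groups[i], config))
    ph <- build_phantom(config, groups[i], cov, seed = derive_seed(seed_i, 1L))
    rec[[i]] <- data.frame(id = sprintf("sub-%03d", i), group = groups[i],
                           age = cov$age, sex = cov$sex, site = cov$site,
                           seed = seed_i, mean_gm_att = ph$mean_gm_att,
                           stringsAsFactors = FALSE)
    subjects[[i]] <- if (is.null(per_subject)) ph else per_subject(ph, rec[[i]])
  }
  records <- do.call(rbind, rec)
  records$group <- factor(records$group, levels = group_levels())
  records$group4 <- collapse_mci(records$group)
  list(records = records, subjects = subjects)
}
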