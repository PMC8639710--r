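#' Write a 3-D or 4-D map as NIfTI
#'
#' @param map numeric/logical array (repeat lists are stacked along the
#'   4th axis).
#' @param path output `.nii` / `.nii.gz` path.
#' @param voxel_dim voxel size in mm (used for the affine diagonal).
#' @return the path, invisibly.
#' @export
write_map_nifti <- function(map, path, voxel_dim = c(3, 3, 4)) {
  if (is.list(map)) map <- array(unlist(map), dim = c(dim(map[[1]]),
                                                      length(map)))
  img <- RNifti::asNifti(map * 1)
  RNifti::pixdim(img) <- c(voxel_dim, rep(1, length(dim(map)) - 3))
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' Read a NIfTI map as a plain array
#'
#' @param path NIfTI file path.
#' @return numeric array.
#' @export
read_map_nifti <- function(path) {
  if (!file.exists(path)) stop("cannot read NIfTI file: ", path)
  arr <- RNifti::readNifti(path)
  array(as.numeric(arr), dim = dim(arr))
}

#' Quantify one subject end-to-end
#'
#' Synthesise the pCASL dataset for a phantom, average the repeats,
#' calibrate M0, quantify non-PVC CBF, run linear-regression PVC, and
#' extract the per-subject ROI metrics.
#'
#' @param phantom a [build_phantom()] result.
#' @param params an [acq_params()].
#' @param meta subject metadata list/row (id, group, age, sex, site).
#' @param seed noise-stream seed.
#' @param keep_maps also return the CBF map objects (default FALSE).
#' @return one-row metrics data.frame (see [extract_subject_metrics()]);
#'   with `keep_maps`, a list `(metrics, cbf_nonpvc, cbf_pvc_gm, asl)`.
#' @export
process_subject <- function(phantom, params, meta = list(id = "sub-001",
                                                         group = phantom$group,
                                                         age = phantom$age,
                                                         sex = phantom$sex,
                                                         site = phantom$site),
                            seed = 1L, keep_maps = FALSE) {
  asl <- synthesize_asl(phantom, params, seed = seed)
  mean_diff <- average_repeats(asl$diff_volumes)
  m0b <- calibrate_m0(asl$m0_volume, params)
  cbf <- quantify_cbf(mean_diff, m0b, params)
  pvc <- pvc_regress(cbf, phantom$pv_gm, phantom$pv_wm)
  rois <- roi_set_from_phantom(phantom)
  metrics <- extract_subject_metrics(cbf, pvc$gm, rois, meta)
  if (keep_maps)
    list(metrics = metrics, cbf_nonpvc = cbf, cbf_pvc_gm = pvc$gm, asl = asl)
  else metrics
}

#' Pipeline configuration
#'
#' @param cohort a [cohort_config()].
#' @param acq an [acq_params()].
#' @param restrictions named list of [order_restriction()]s to test.
#' @param metric metrics-table column the Bayesian comparison uses.
#' @param covariates covariate columns for the ANCOVA.
#' @param n_draws,n_chains sampler settings.
#' @param out_dir output directory.
#' @param seed master seed (mandatory; all stages derive streams from
#'   it).
#' @param write_nifti write per-subject NIfTI artifacts (CBF maps).
#' @return object of class `pipeline_config`.
#' @export
pipeline_config <- function(cohort = cohort_config(), acq = acq_params(),
                            restrictions = default_restrictions(),
                            metric = "scov_gm",
                            covariates = c("age", "sex", "site"),
                            n_draws = 4000L, n_chains = 4L,
                            out_dir = tempfile("aslcov_run_"),
                            seed = 1L, write_nifti = FALSE) {
  problems <- character()
  if (!inherits(cohort, "cohort_config"))
    problems <- c(problems, "cohort: not a cohort_config")
  if (!inherits(acq, "acq_params"))
    problems <- c(problems, "acq: not an acq_params")
  if (!length(restrictions) ||
      !all(vapply(restrictions, inherits, TRUE, "order_restriction")))
    problems <- c(problems, "restrictions: must be order_restriction objects")
  if (!is.numeric(seed) || length(seed) != 1)
    problems <- c(problems, "seed: a single integer seed is mandatory")
  if (length(problems))
    stop("invalid pipeline configuration:\n  ",
         paste(problems, collapse = "\n  "), call. = FALSE)
  structure(list(cohort = cohort, acq = acq, restrictions = restrictions,
                 metric = metric, covariates = covariates,
                 n_draws = as.integer(n_draws), n_chains = as.integer(n_chains),
                 out_dir = out_dir, seed = as.integer(seed),
                 write_nifti = isTRUE(write_nifti)),
            class = "pipeline_config")
}

#' Run the full simulation and analysis pipeline
#'
#' Simulates the phantom cohort, synthesises and quantifies every
#' subject, writes the per-subject metrics table, runs the
#' order-restricted Bayesian ANCOVA for each configured restriction on
#' the chosen metric (on the four-level collapsed group factor), computes
#' the classical cohort statistics, and writes a manifest recording the
#' seed and configuration digest. Identical configuration and seed
#' reproduce byte-identical metric tables.
#'
#' @param config a [pipeline_config()].
#' @param dry_run validate the configuration and return without writing
#'   anything.
#' @return invisible list with `metrics` (data.frame), `bf_report`
#'   (data.frame), `pairwise_bf` (matrix), `cohort_stats` (data.frame),
#'   `manifest` and the output paths.
#' @export
run_pipeline <- function(config, dry_run = FALSE) {
  if (!inherits(config, "pipeline_config"))
    stop("config must be a pipeline_config")
  if (dry_run) return(invisible(list(validated = TRUE)))
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)

  cohort <- config$cohort
  sim <- simulate_cohort(cohort, per_subject = function(ph, rec) {
    res <- process_subject(ph, config$acq, meta = rec,
                           seed = derive_seed(rec$seed, 2L),
                           keep_maps = config$write_nifti)
    if (config$write_nifti) {
      write_map_nifti(res$cbf_nonpvc$values,
                      file.path(config$out_dir,
                                paste0(rec$id, "_cbf.nii.gz")),
                      cohort$voxel_dim)
      write_map_nifti(res$cbf_pvc_gm$values,
                      file.path(config$out_dir,
                                paste0(rec$id, "_cbf_pvc_gm.nii.gz")),
                      cohort$voxel_dim)
      res <- res$metrics
    }
    res
  })
  metrics <- do.call(rbind, sim$subjects)
  metrics$group <- factor(metrics$group, levels = group_levels())
  metrics$group4 <- collapse_mci(metrics$group)
  metrics_path <- file.path(config$out_dir, "subject_metrics.csv")
  write.csv(metrics, metrics_path, row.names = FALSE)

  # Bayesian model comparison on the collapsed 4-level factor
  bdat <- metrics
  bdat$group <- bdat$group4
  bf_results <- lapply(seq_along(config$restrictions), function(i) {
    bf_order_restricted(bdat, config$metric, config$restrictions[[i]],
                        covariates = config$covariates,
                        n_draws = config$n_draws,
                        n_chains = config$n_chains,
                        seed = derive_seed(config$seed, 1000L + i))
  })
  names(bf_results) <- names(config$restrictions)
  bf_report <- do.call(rbind, lapply(names(bf_results), function(nm) {
    r <- bf_results[[nm]]
    data.frame(model = nm, restriction = r$restriction$label,
               metric = config$metric, bf_vs_null = r$bf_vs_null,
               bf_full_vs_null = r$bf_full_vs_null,
               posterior_constraint_prob = r$posterior_constraint_prob,
               prior_constraint_prob = r$prior_constraint_prob,
               mc_standard_error = r$mc_standard_error,
               ess_min = r$ess_min, rhat_max = r$rhat_max,
               stringsAsFactors = FALSE)
  }))
  write.csv(bf_report, file.path(config$out_dir, "bf_report.csv"),
            row.names = FALSE)
  pairwise <- compare_restrictions(bf_results)

  # Classical cohort statistics on the simulated records
  ag <- aggregate(age ~ group4, metrics, function(v) c(mean(v), sd(v), length(v)))
  age_stats <- anova_from_summary(ag$age[, 1], ag$age[, 2], ag$age[, 3])
  sex_tab <- table(metrics$sex, metrics$group4)
  sex_stats <- chi_square_independence(as.matrix(sex_tab)[1:2, , drop = FALSE])
  corr <- pearson_corr(metrics$scov_gm, metrics$cbf_pvc_gm)
  cohort_stats <- data.frame(
    statistic = c("age_anova_F", "age_anova_p", "sex_chisq", "sex_chisq_p",
                  "scov_cbf_r", "scov_cbf_p"),
    value = c(age_stats$F, age_stats$p, sex_stats$chisq, sex_stats$p,
              corr$r, corr$p))
  write.csv(cohort_stats, file.path(config$out_dir, "cohort_stats.csv"),
            row.names = FALSE)

  manifest <- list(seed = config$seed,
                   n_subjects = nrow(metrics),
                   metric = config$metric,
                   grid_dim = cohort$grid_dim,
                   restrictions = vapply(config$restrictions,
                                         function(r) r$label, ""),
                   r_version = as.character(getRversion()),
                   outputs = c("subject_metrics.csv", "bf_report.csv",
                               "cohort_stats.csv"))
  jsonlite::write_json(manifest, file.path(config$out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(list(metrics = metrics, bf_report = bf_report,
                 bf_results = bf_results, pairwise_bf = pairwise,
                 cohort_stats = cohort_stats, manifest = manifest,
                 out_dir = config$out_dir))
}

#' Validate external pipeline inputs
#'
#' Checks that supplied NIfTI maps share one grid, that mask files are
#' non-empty, and that a cohort table carries the required columns.
#' Never mutates its inputs.
#'
#' @param nifti_paths named character vector of NIfTI file paths; all
#'   must share one 3-D grid.
#' @param mask_paths character vector of NIfTI mask paths (checked
#'   non-empty).
#' @param cohort_csv path to a cohort table; must contain columns
#'   `id, group, age, sex, site`.
#' @return character vector of problems (empty when everything is
#'   valid), one entry per failed check, each naming the file and stage.
#' @export
validate_inputs <- function(nifti_paths = character(),
                            mask_paths = character(),
                            cohort_csv = NULL) {
  problems <- character()
  dims <- NULL
  for (p in c(nifti_paths, mask_paths)) {
    if (!file.exists(p)) {
      problems <- c(problems, sprintf("unreadable file [load]: %s", p))
      next
    }
    d <- dim(RNifti::readNifti(p))[1:3]
    if (is.null(dims)) dims <- d
    else if (!identical(d, dims))
      problems <- c(problems,
                    sprintf("grid mismatch [geometry]: %s is %s, expected %s",
                            p, paste(d, collapse = "x"),
                            paste(dims, collapse = "x")))
  }
  for (p in mask_paths) {
    if (!file.exists(p)) next
    if (!any(as.numeric(RNifti::readNifti(p)) != 0))
      problems <- c(problems, sprintf("empty mask [masks]: %s", p))
  }
  if (!is.null(cohort_csv)) {
    if (!file.exists(cohort_csv)) {
      problems <- c(problems,
                    sprintf("unreadable file [cohort]: %s", cohort_csv))
    } else {
      tab <- read.csv(cohort_csv, stringsAsFactors = FALSE)
      need <- c("id", "group", "age", "sex", "site")
      miss <- setdiff(need, names(tab))
      if (length(miss))
        problems <- c(problems,
                      sprintf("missing column(s) [cohort]: %s in %s",
                              paste(miss, collapse = ", "), cohort_csv))
    }
  }
  problems
}
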