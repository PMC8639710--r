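#' Binarise a partial-volume map
#'
#' @param pv_map array of tissue fractions in `[0,1]`.
#' @param threshold inclusion threshold in `(0,1)`; the comparison is
#'   inclusive (`pv >= threshold`), so a voxel exactly at the threshold
#'   is kept. Default 0.25, the conventional GM cut-off.
#' @return logical array.
#' @export
binarise_mask <- function(pv_map, threshold = 0.25) {
  if (!is.numeric(threshold) || length(threshold) != 1 ||
      threshold <= 0 || threshold >= 1)
    stop("threshold must lie strictly inside (0,1)")
  if (any(pv_map < -1e-9 | pv_map > 1 + 1e-9))
    stop("partial volume fractions must lie in [0,1]")
  pv_map >= threshold
}

#' Spatial coefficient of variation over an ROI
#'
#' `sCoV = sd / mean * 100` over the masked voxels, using the sample
#' (n-1) standard deviation. Computed on non-PVC CBF maps, where spatial
#' heterogeneity acts as a surrogate for arterial transit time.
#'
#' @param values numeric array.
#' @param mask logical array, at least 2 voxels TRUE.
#' @return sCoV in percent.
#' @export
spatial_cov <- function(values, mask) {
  check_same_grid(values, mask, "values and mask")
  v <- values[mask]
  if (length(v) < 2) stop("sCoV needs at least 2 voxels in the ROI")
  mu <- mean(v)
  if (mu == 0) stop("sCoV undefined: ROI mean is zero")
  sd(v) / mu * 100
}

#' Mean value over an ROI
#'
#' @param values numeric array.
#' @param mask logical array with at least one TRUE voxel.
#' @return arithmetic mean over the mask.
#' @export
roi_mean <- function(values, mask) {
  check_same_grid(values, mask, "values and mask")
  if (!any(mask)) stop("empty ROI mask")
  mean(values[mask])
}

#' ROI names reported per subject
#'
#' @return character vector: total GM, the four lobes, and the four
#'   focal regions.
#' @export
roi_names <- function() {
  c("gm", "frontal", "parietal", "temporal", "occipital",
    "pcc", "precuneus", "hippocampus", "angular")
}

#' Build the ROI mask set from a phantom
#'
#' Lobe and parcel masks come from the phantom's integer label map,
#' intersected with the binarised GM mask (lobe masks include the
#' parcels that anatomically belong to them: PCC, precuneus and angular
#' gyrus with the parietal lobe, hippocampus with the temporal lobe).
#'
#' @param phantom a [build_phantom()] result.
#' @param gm_threshold GM partial-volume threshold for the total-GM mask.
#' @param lobe_gm_intersect intersect lobe masks with the GM mask
#'   (default TRUE).
#' @return object of class `roi_set`: a named list of logical arrays.
#' @export
roi_set_from_phantom <- function(phantom, gm_threshold = 0.25,
                                 lobe_gm_intersect = TRUE) {
  gm <- binarise_mask(phantom$pv_gm, gm_threshold)
  lab <- phantom$roi_labels
  codes <- roi_label_codes()
  lobe_members <- list(frontal = "frontal",
                       parietal = c("parietal", "pcc", "precuneus", "angular"),
                       temporal = c("temporal", "hippocampus"),
                       occipital = "occipital")
  masks <- list(gm = gm)
  for (nm in names(lobe_members)) {
    m <- array(FALSE, dim = dim(lab))
    for (member in lobe_members[[nm]]) m <- m | (lab == codes[[member]])
    masks[[nm]] <- if (lobe_gm_intersect) m & gm else m
  }
  for (nm in c("pcc", "precuneus", "hippocampus", "angular")) {
    m <- lab == codes[[nm]]
    masks[[nm]] <- if (lobe_gm_intersect) m & gm else m
  }
  roi_set(masks)
}

#' Construct and validate an ROI set
#'
#' @param masks named list of logical arrays on one grid; must contain
#'   every name in [roi_names()], each mask non-empty, lobe masks
#'   contained in the total-GM ("brain") mask when it is present.
#' @return object of class `roi_set`.
#' @export
roi_set <- function(masks) {
  missing_rois <- setdiff(roi_names(), names(masks))
  if (length(missing_rois))
    stop("missing ROI masks: ", paste(missing_rois, collapse = ", "))
  if (anyDuplicated(names(masks))) stop("ROI names must be unique")
  d <- dim(masks[[1]])
  for (nm in names(masks)) {
    if (!identical(dim(masks[[nm]]), d))
      stop("ROI mask grid mismatch: ", nm)
    if (!any(masks[[nm]])) stop("empty ROI mask: ", nm)
  }
  structure(masks[roi_names()], class = "roi_set")
}

#' Per-subject ROI metrics
#'
#' Computes, for every ROI, the spatial CoV of the non-PVC CBF map and
#' the mean CBF from both the non-PVC map and the PVC pure-GM map. The
#' sCoV is defined on the uncorrected map only (partial volume correction
#' would smooth the very heterogeneity the statistic measures), and the
#' interface enforces this via the maps' `pvc` flags.
#'
#' @param cbf_nonpvc non-PVC [cbf_map()].
#' @param cbf_pvc_gm PVC pure-GM [cbf_map()].
#' @param rois a [roi_set()].
#' @param meta list/row with subject metadata (`id`, `group`, `age`,
#'   `sex`, `site`); carried through to the output.
#' @return one-row data.frame: metadata columns plus `scov_<roi>`,
#'   `cbf_<roi>` (non-PVC mean) and `cbf_pvc_<roi>` columns.
#' @export
extract_subject_metrics <- function(cbf_nonpvc, cbf_pvc_gm, rois, meta) {
  if (!inherits(cbf_nonpvc, "cbf_map") || !inherits(cbf_pvc_gm, "cbf_map"))
    stop("CBF inputs must be cbf_map objects")
  if (cbf_nonpvc$pvc)
    stop("sCoV must be computed from the non-PVC map (pvc flag is set)")
  if (!cbf_pvc_gm$pvc)
    stop("cbf_pvc_gm must be a PVC map (pvc flag unset)")
  check_same_grid(cbf_nonpvc$values, cbf_pvc_gm$values, "CBF maps")
  check_same_grid(cbf_nonpvc$values, rois$gm, "CBF map and ROI set")
  out <- data.frame(id = meta$id %||% NA_character_,
                    group = as.character(meta$group %||% NA_character_),
                    age = meta$age %||% NA_real_,
                    sex = meta$sex %||% NA_character_,
                    site = meta$site %||% NA_character_,
                    stringsAsFactors = FALSE)
  for (nm in roi_names()) {
    m <- rois[[nm]]
    mv <- m & cbf_nonpvc$mask
    mp <- m & cbf_pvc_gm$mask
    if (!any(mv)) stop("ROI has no valid voxels: ", nm)
    out[[paste0("scov_", nm)]] <- spatial_cov(cbf_nonpvc$values, mv)
    out[[paste0("cbf_", nm)]] <- roi_mean(cbf_nonpvc$values, mv)
    out[[paste0("cbf_pvc_", nm)]] <-
      if (any(mp)) roi_mean(cbf_pvc_gm$values, mp) else NA_real_
  }
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a
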