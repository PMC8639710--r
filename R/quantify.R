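#' Construct a CBF map object
#'
#' @param values 3-D array of perfusion values, ml/100g/min.
#' @param mask logical 3-D array of valid voxels.
#' @param pvc whether the map is partial-volume corrected.
#' @return object of class `cbf_map`.
#' @export
cbf_map <- function(values, mask, pvc = FALSE) {
  check_same_grid(values, mask, "CBF values and mask")
  if (any(!is.finite(values[mask])))
    stop("CBF values must be finite on the mask")
  structure(list(values = values, mask = mask, pvc = isTRUE(pvc)),
            class = "cbf_map")
}

#' @export
print.cbf_map <- function(x, ...) {
  cat(sprintf("<cbf_map> %s grid, %s, %d valid voxels, mean %.1f ml/100g/min\n",
              paste(dim(x$values), collapse = "x"),
              if (x$pvc) "PVC" else "non-PVC",
              sum(x$mask), mean(x$values[x$mask])))
  invisible(x)
}

#' Average repeated difference volumes
#'
#' @param diff_volumes list of 3-D arrays on a common grid.
#' @return voxelwise arithmetic mean (3-D array).
#' @export
average_repeats <- function(diff_volumes) {
  if (length(diff_volumes) == 0) stop("no difference volumes supplied")
  d <- dim(diff_volumes[[1]])
  for (v in diff_volumes) check_same_grid(v, diff_volumes[[1]])
  Reduce(`+`, diff_volumes) / length(diff_volumes)
}

#' Calibrate M0 to arterial-blood magnetisation
#'
#' Applies the T1 saturation correction for the finite M0 repetition time
#' and divides by the blood-brain partition coefficient:
#' `m0b = m0 / (1 - exp(-tr_m0 / t1_tissue)) / lambda`.
#'
#' @param m0_volume 3-D M0 array (signal units).
#' @param params an [acq_params()].
#' @return arterial-blood magnetisation map on the same grid.
#' @export
calibrate_m0 <- function(m0_volume, params) {
  if (params$tr_m0 <= 0 || params$t1_tissue <= 0)
    stop("tr_m0 and t1_tissue must be > 0")
  m0_volume / (1 - exp(-params$tr_m0 / params$t1_tissue)) / params$lambda_bbp
}

#' Quantify CBF from the mean difference signal
#'
#' White-paper single-compartment single-PLD quantification:
#' `f = 6000 * dM * exp(pld/T1b) / (2 * alpha * T1b * m0b * (1 - exp(-tau/T1b)))`.
#' This inverts [tissue_delta_m()] exactly whenever the transit time does
#' not exceed the post-labelling delay. Voxels whose `m0b` falls below
#' `mask_frac` of its robust (98th percentile) maximum are excluded from
#' the validity mask to avoid division blow-ups.
#'
#' @param mean_diff 3-D mean difference array.
#' @param m0b_map arterial-blood magnetisation array from [calibrate_m0()].
#' @param params an [acq_params()].
#' @param mask_frac exclusion threshold as a fraction of the robust m0b
#'   maximum (default 0.05).
#' @return a non-PVC [cbf_map()].
#' @export
quantify_cbf <- function(mean_diff, m0b_map, params, mask_frac = 0.05) {
  check_same_grid(mean_diff, m0b_map, "difference and m0b")
  robust_max <- quantile(m0b_map, 0.98, names = FALSE)
  if (robust_max <= 0) stop("m0b map contains no positive signal")
  mask <- m0b_map > mask_frac * robust_max
  t1b <- params$t1_blood
  denom <- 2 * params$alpha * t1b * m0b_map * (1 - exp(-params$tau / t1b))
  f <- array(0, dim = dim(mean_diff))
  f[mask] <- 6000 * mean_diff[mask] * exp(params$pld / t1b) / denom[mask]
  cbf_map(f, mask, pvc = FALSE)
}

# Separable moving-window (box) sum with radii (rx, ry, rz), zero-padded.
box_sum <- function(a, radii) {
  d <- dim(a)
  for (ax in 1:3) {
    r <- radii[ax]
    if (r == 0) next
    perm <- switch(ax, c(1, 2, 3), c(2, 1, 3), c(3, 1, 2))
    b <- aperm(a, perm)
    db <- dim(b)
    m <- matrix(b, nrow = db[1])
    cs <- apply(m, 2, cumsum)
    n <- db[1]
    upper <- pmin(seq_len(n) + r, n)
    lower <- seq_len(n) - r - 1L
    if (is.null(dim(cs))) cs <- matrix(cs, nrow = n)
    win <- cs[upper, , drop = FALSE] -
      rbind(matrix(0, nrow = sum(lower < 1), ncol = ncol(cs)),
            cs[lower[lower >= 1], , drop = FALSE])
    a <- aperm(array(win, dim = db), order(perm))
  }
  a
}

#' Partial volume correction by local linear regression
#'
#' For every voxel, the non-PVC CBF values in a box neighbourhood are
#' regressed on the GM and WM partial-volume fractions,
#' `cbf ~ pv_gm * f_gm + pv_wm * f_wm` (no intercept), and the local
#' least-squares solution gives pure-GM and pure-WM perfusion estimates.
#' Voxels whose local 2x2 normal matrix is (near-)rank-deficient — e.g.
#' pure single-tissue neighbourhoods or colinear fraction profiles — are
#' masked out of the corresponding output rather than extrapolated; a
#' pure-GM neighbourhood still yields a valid `f_gm` (the design is then
#' rank 1 in GM only).
#'
#' @param cbf a non-PVC [cbf_map()].
#' @param pv_gm,pv_wm partial-volume fraction arrays on the same grid.
#' @param kernel_radius integer radii (in voxels) of the box
#'   neighbourhood along x, y, z; default `c(2, 2, 1)` (5x5x3 window).
#' @param rcond_tol relative tolerance below which the local normal
#'   matrix is treated as rank deficient.
#' @return list with `gm` and `wm` [cbf_map()]s (flagged PVC).
#' @export
pvc_regress <- function(cbf, pv_gm, pv_wm, kernel_radius = c(2L, 2L, 1L),
                        rcond_tol = 1e-8) {
  if (!inherits(cbf, "cbf_map")) stop("cbf must be a cbf_map")
  if (cbf$pvc) stop("pvc_regress expects a non-PVC map")
  check_same_grid(cbf$values, pv_gm, "CBF and pv_gm")
  check_same_grid(cbf$values, pv_wm, "CBF and pv_wm")
  if (length(kernel_radius) == 1) kernel_radius <- rep(kernel_radius, 3)
  if (any(kernel_radius < 0) || all(kernel_radius == 0))
    stop("kernel_radius must be non-negative with at least one positive entry")
  if (any(2 * kernel_radius + 1 > dim(cbf$values)))
    stop("kernel larger than the image grid")

  # Only in-mask voxels contribute to the local sums
  w <- cbf$mask * 1
  y <- cbf$values * w
  g <- pv_gm * w
  m <- pv_wm * w
  s_gg <- box_sum(g * g, kernel_radius)
  s_mm <- box_sum(m * m, kernel_radius)
  s_gm <- box_sum(g * m, kernel_radius)
  s_gy <- box_sum(g * y, kernel_radius)
  s_my <- box_sum(m * y, kernel_radius)

  det2 <- s_gg * s_mm - s_gm^2
  scale2 <- s_gg * s_mm
  full_rank <- scale2 > 0 & det2 > rcond_tol * scale2
  # rank-1 neighbourhoods are usable only when a single tissue is present;
  # colinear mixed-tissue designs are masked, never extrapolated
  eps <- rcond_tol * max(s_gg + s_mm)
  gm_only <- !full_rank & s_gg > eps & s_mm <= eps
  wm_only <- !full_rank & s_mm > eps & s_gg <= eps

  f_gm <- array(NA_real_, dim = dim(y))
  f_wm <- array(NA_real_, dim = dim(y))
  f_gm[full_rank] <- (s_mm[full_rank] * s_gy[full_rank] -
                        s_gm[full_rank] * s_my[full_rank]) / det2[full_rank]
  f_wm[full_rank] <- (s_gg[full_rank] * s_my[full_rank] -
                        s_gm[full_rank] * s_gy[full_rank]) / det2[full_rank]
  f_gm[gm_only] <- s_gy[gm_only] / s_gg[gm_only]
  f_wm[wm_only] <- s_my[wm_only] / s_mm[wm_only]

  gm_mask <- cbf$mask & !is.na(f_gm)
  wm_mask <- cbf$mask & !is.na(f_wm)
  f_gm[!gm_mask] <- 0
  f_wm[!wm_mask] <- 0
  list(gm = cbf_map(f_gm, gm_mask, pvc = TRUE),
       wm = cbf_map(f_wm, wm_mask, pvc = TRUE))
}
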