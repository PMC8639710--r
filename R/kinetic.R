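#' pCASL acquisition and quantification parameters
#'
#' Defaults follow the consensus single-PLD pCASL protocol used by the
#' analysis this package emulates: labelling efficiency 0.60, blood T1 at
#' 3 T of 1.65 s, labelling (bolus) duration 1.8 s, post-labelling delay
#' 1.8 s, blood-brain partition coefficient 0.9 ml/g, M0 scan TR 4 s, and
#' eight control-label repeats.
#'
#' @param alpha labelling efficiency (0 < alpha <= 1).
#' @param t1_blood longitudinal relaxation time of arterial blood, s.
#' @param tau labelling (bolus) duration, s.
#' @param pld post-labelling delay, s.
#' @param lambda_bbp blood-brain partition coefficient, ml/g.
#' @param tr_m0 repetition time of the M0 scan, s.
#' @param t1_tissue tissue T1 used for the M0 saturation correction, s.
#' @param noise_sd additive Gaussian noise SD per difference volume
#'   (signal units).
#' @param n_repeats number of control-label difference repeats.
#' @return object of class `acq_params`.
#' @export
acq_params <- function(alpha = 0.60, t1_blood = 1.65, tau = 1.8, pld = 1.8,
                       lambda_bbp = 0.9, tr_m0 = 4.0, t1_tissue = 1.3,
                       noise_sd = 2, n_repeats = 8L) {
  stop_if_not_scalar_number(alpha, "alpha", positive = TRUE)
  if (alpha > 1) stop("alpha must be <= 1")
  for (nm in c("t1_blood", "tau", "pld", "lambda_bbp", "tr_m0", "t1_tissue"))
    stop_if_not_scalar_number(get(nm), nm, positive = TRUE)
  stop_if_not_scalar_number(noise_sd, "noise_sd")
  if (noise_sd < 0) stop("noise_sd must be >= 0")
  if (n_repeats < 1) stop("n_repeats must be >= 1")
  structure(list(alpha = alpha, t1_blood = t1_blood, tau = tau, pld = pld,
                 lambda_bbp = lambda_bbp, tr_m0 = tr_m0,
                 t1_tissue = t1_tissue, noise_sd = noise_sd,
                 n_repeats = as.integer(n_repeats)),
            class = "acq_params")
}

#' Single-compartment pCASL tissue difference signal
#'
#' General kinetic model for the control-label difference at a single
#' post-labelling delay, with the labelled water relaxing at the blood T1
#' throughout. With `t = tau + pld`:
#' \itemize{
#'   \item `att >= t`: no label has arrived, signal 0;
#'   \item `pld < att < t`: partial delivery,
#'     `2 alpha m0b (f/6000) T1b exp(-att/T1b) (1 - exp(-(t - att)/T1b))`;
#'   \item `att <= pld`: full bolus delivered,
#'     `2 alpha m0b (f/6000) T1b exp(-pld/T1b) (1 - exp(-tau/T1b))`.
#' }
#' The expression is continuous in `att` at both branch boundaries, and in
#' the `att <= pld` branch it is exactly inverted by [quantify_cbf()].
#'
#' @param f perfusion in ml/100g/min (vectorised; recycled against `att`).
#' @param att arterial transit time, s.
#' @param m0b equilibrium magnetisation of arterial blood (signal units).
#' @param params an [acq_params()].
#' @return difference signal, same shape as the broadcast inputs.
#' @export
tissue_delta_m <- function(f, att, m0b, params) {
  if (any(f < 0)) stop("f must be >= 0")
  if (any(att <= 0)) stop("att must be > 0")
  t1b <- params$t1_blood; tau <- params$tau; w <- params$pld
  t_end <- tau + w
  # broadcast f and att against each other (either may be scalar or array)
  att_b <- att + 0 * f
  base <- 2 * params$alpha * m0b * (f / 6000) * t1b + 0 * att
  full <- base * exp(-w / t1b) * (1 - exp(-tau / t1b))
  partial <- base * exp(-att_b / t1b) * (1 - exp(-(t_end - att_b) / t1b))
  ifelse(att_b >= t_end, 0, ifelse(att_b > w, partial, full))
}

#' Macrovascular (stalled-label) difference signal
#'
#' Label still residing in feeding arteries at imaging time contributes
#' `2 alpha m0b abv exp(-att_arterial / T1b)` when the tissue has not yet
#' received it (`att_tissue > pld`) and the arterial bolus is present
#' (`att_arterial < tau + pld`); otherwise 0. This non-dispersed gated
#' bolus produces the bright-vessel / dark-distal-tissue pattern typical
#' of scans whose post-labelling delay is shorter than the transit time.
#'
#' @param abv arterial blood-volume fraction in `[0,1]`.
#' @param att_arterial transit time to the arterial compartment, s.
#' @param att_tissue transit time to the tissue microvasculature, s.
#' @param m0b arterial-blood magnetisation (signal units).
#' @param params an [acq_params()].
#' @return difference signal.
#' @export
arterial_delta_m <- function(abv, att_arterial, att_tissue, m0b, params) {
  if (any(abv < 0 | abv > 1)) stop("abv must lie in [0,1]")
  t1b <- params$t1_blood
  sig <- 2 * params$alpha * m0b * abv * exp(-att_arterial / t1b)
  gate <- (att_tissue > params$pld) & (att_arterial < params$tau + params$pld)
  ifelse(gate, sig, 0)
}

#' Synthesise a pCASL dataset from a phantom
#'
#' Builds the noiseless voxelwise difference signal as the
#' partial-volume-weighted sum of GM and WM single-compartment terms plus
#' the macrovascular term, then adds independent Gaussian noise to each
#' of `n_repeats` difference volumes and to the M0 volume. The
#' arterial-blood magnetisation entering the forward model is derived
#' from the phantom's M0 map with the same saturation correction used in
#' quantification, so noiseless synthesis and quantification are mutually
#' consistent.
#'
#' @param phantom a [build_phantom()] result.
#' @param params an [acq_params()].
#' @param seed integer seed for the noise streams.
#' @return object of class `asl_dataset`: `diff_volumes` (list of 3-D
#'   arrays), `m0_volume`, `params`, `subject` and `seed`.
#' @export
synthesize_asl <- function(phantom, params, seed = 1L) {
  if (!inherits(phantom, "phantom")) stop("phantom must be a phantom object")
  if (!inherits(params, "acq_params")) stop("params must be acq_params")
  m0b <- calibrate_m0(phantom$m0_tissue, params)
  tis <- phantom$pv_gm * tissue_delta_m(phantom$cbf_gm, phantom$att_true,
                                        m0b, params) +
         phantom$pv_wm * tissue_delta_m(phantom$cbf_wm, phantom$att_true,
                                        m0b, params)
  art <- arterial_delta_m(phantom$abv, phantom$att_arterial,
                          phantom$att_true, m0b, params)
  clean <- tis + art
  nvox <- prod(dim(clean))
  diffs <- with_seed(seed, lapply(seq_len(params$n_repeats), function(r) {
    if (params$noise_sd > 0)
      clean + array(rnorm(nvox, 0, params$noise_sd), dim = dim(clean))
    else clean
  }))
  m0 <- with_seed(derive_seed(seed, 7919L), {
    if (params$noise_sd > 0)
      phantom$m0_tissue + array(rnorm(nvox, 0, params$noise_sd),
                                dim = dim(clean))
    else phantom$m0_tissue
  })
  structure(list(diff_volumes = diffs, m0_volume = m0, params = params,
                 subject = phantom$group, seed = seed,
                 grid_dim = dim(clean)),
            class = "asl_dataset")
}

#' @export
print.asl_dataset <- function(x, ...) {
  cat(sprintf("<asl_dataset> %d repeats on %s grid (noise_sd=%.3g)\n",
              length(x$diff_volumes), paste(x$grid_dim, collapse = "x"),
              x$params$noise_sd))
  invisible(x)
}
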