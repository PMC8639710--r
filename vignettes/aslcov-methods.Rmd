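---
title: "Methods: simulating and analysing the spatial CoV of ASL perfusion maps"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: simulating and analysing the spatial CoV of ASL perfusion maps}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(aslcov)
```

# Overview

`aslcov` studies a single scientific mechanism end to end: in
single-delay arterial spin labelling (ASL), prolonged arterial transit
time (ATT) makes cerebral blood flow (CBF) maps spatially heterogeneous,
so the spatial coefficient of variation (sCoV) of a CBF map acts as a
surrogate for ATT and, across a cognitive-decline cohort, is expected to
increase with disease severity. The package simulates cohorts in which
that mechanism is true by construction, pushes them through the same
quantification and statistics a perfusion study would use, and tests
whether the analysis recovers the built-in structure.

The pipeline has five stages: phantom cohort generation, kinetic forward
simulation, CBF quantification with partial volume correction (PVC), ROI
metric extraction, and statistics (order-restricted Bayesian ANCOVA plus
classical summary tests).

# The kinetic model and its inverse

The forward model is the single-compartment general kinetic model for
pCASL at a single post-labelling delay `w`, with labelled water relaxing
with the blood T1 (`T1b`) before and after arrival. With labelling
duration `tau` and `t = tau + w`, the voxel difference signal for
perfusion `f` (ml/100g/min) and transit time `att` is

* `0` for `att >= t` (no label arrived),
* `2 a m0b (f/6000) T1b e^{-att/T1b} (1 - e^{-(t-att)/T1b})` for
  `w < att < t` (partial delivery),
* `2 a m0b (f/6000) T1b e^{-w/T1b} (1 - e^{-tau/T1b})` for `att <= w`
  (full delivery),

continuous in `att` at both boundaries. Keeping the relaxation constant
at `T1b` throughout (no exchange into the tissue T1 pool) is a
deliberate simplification: it makes the standard white-paper
quantification

`f = 6000 dM e^{w/T1b} / (2 a T1b m0b (1 - e^{-tau/T1b}))`

an *exact* algebraic inverse whenever `att <= w`, which gives the test
suite a machine-precision round-trip oracle (`tests` assert a relative
error below 1e-9; the observed error is ~1e-15). For `att > w` the
quantified CBF under-estimates the true perfusion, monotonically in
`att` — this under-delivery bias is the engine of the sCoV mechanism.

A macrovascular term models label still in feeding vessels at imaging:
`2 a m0b abv e^{-att_a/T1b}`, gated to voxels whose tissue has not yet
received label (`att > w`) while the arterial bolus is still present
(`att_a < t`). It is a non-dispersed plug bolus; dispersion kernels,
background-suppression pulses and readout physics are out of scope.

Acquisition defaults follow the consensus single-PLD protocol the
simulated study design uses: labelling efficiency `a = 0.60`, `T1b =
1.65` s, `tau = 1.8` s, `w = 1.8` s, partition coefficient `lambda =
0.9` ml/g, M0 repetition time 4 s, eight control-label repeats. The M0
saturation correction uses a single tissue T1 of 1.3 s (the study's own
correction constant is not published; the value is a typical 3 T grey
matter T1 and only rescales the calibration). Noise is additive white
Gaussian per repeat (SD 2 signal units by default, roughly 40% of the
full-delivery grey matter difference signal, i.e. a realistic
single-repeat SNR of ~2.5); temporal autocorrelation and motion are not
modelled.

# The phantom cohort

Each subject is a stylised three-shell "brain" (WM core, GM ribbon, CSF
rim) on a 32 x 32 x 24 grid of 3 x 3 x 4 mm voxels, with partial-volume
fractions mixed linearly over one voxel at shell boundaries so that PVC
has genuine mixed voxels to work on. Anatomical realism is explicitly
not a goal; statistical structure is. ROI labels (four lobes plus PCC,
precuneus, hippocampus, angular gyrus) are fixed angular sectors of the
GM shell, non-empty on any grid of 16^3 or larger.

The tissue ATT map is a subject-level scalar plus a fixed spatial
pattern:

* subject level: `base_att` (default 1.4 s, a typical grey-matter value
  in elderly cohorts) + group offset + site offset + `5 ms/year x (age -
  70)` + a subject random shift (SD 0.25 s);
* spatial: +0.2 s in the posterior vascular territory and a 0.3 s
  proximal-to-distal radial gradient, centred to zero mean over the GM
  mask so the subject-level value *is* the mean GM ATT exactly.

Group ATT offsets default to `control = scd = 0 < amci = mmci = 0.15 <
ad = 0.30` s, encoding the equality-block ordering the Bayesian analysis
should recover; regional CBF effects add mild hypoperfusion (5-10
ml/100g/min) in the parcels associated with cognitive decline. The MCI
split into aMCI/mMCI halves (23/22) is a documented guess — only the
combined n = 45 is published — and is configurable.

The macrovascular compartment deserves a note, because its calibration
is a designed trade-off. Full ASL toolboxes fit and remove a
macrovascular component during quantification; this package's
white-paper quantification does not, so the phantom's arterial blood
volume is calibrated to represent the *residual* vascular signal left
after such treatment: two feeding columns carry `abv_vessel = 0.005`
and background tissue `abv_background = 0.001`. At these levels a
stalled-label vessel voxel quantifies in the tens of ml/100g/min above
its surroundings while the grey-matter mean stays governed by tissue
under-delivery, giving a robustly negative cohort-level Pearson
correlation between GM sCoV and GM CBF (roughly -0.5 to -0.9 across
master seeds). Physically realistic uncorrected fractions (tens of
percent in a vessel voxel, ~1% microvascular background) make the
stalled-label signal exceed the entire tissue signal, so that
prolonging ATT *raises* measured mean CBF and inverts that
relationship; users can explore the uncorrected regime — including the
bright-vessel appearance of short-PLD scans — by raising `abv_*`.

All randomness flows from one master seed through `derive_seed()`
per-subject streams; identical configuration and seed reproduce
byte-identical cohorts and metric tables.

# ROI metrics

sCoV is computed with the sample (n-1) standard deviation — the
population/sample distinction is unspecified in common usage and
irrelevant at ROI sizes of hundreds of voxels — and only ever from the
non-PVC map, since PVC smooths exactly the heterogeneity being measured;
the `cbf_map` objects carry a `pvc` flag and
`extract_subject_metrics()` rejects maps on the wrong side of the
contract. The GM mask binarises the GM partial-volume map at an
inclusive 0.25 threshold. Lobe ROIs are intersected with the GM mask by
default (configurable), because whole-lobe masks would mix WM transit
behaviour into a GM statistic.

# Partial volume correction

The package implements the classical local linear-regression PVC: in a
box neighbourhood (default 5 x 5 x 3 voxels) around each voxel the
non-PVC CBF values are regressed on the GM and WM fractions without
intercept, giving pure-tissue perfusion estimates. This is a deliberate
method choice: the spatially-regularised variational-Bayes PVC used by
full ASL toolboxes is stochastic-free but iterative and
implementation-heavy, while the regression method is deterministic,
exactly testable (a noiseless two-tissue phantom is recovered to
machine precision; the suite asserts 1e-6), and shares the same intent.
Neighbourhoods whose 2 x 2 normal matrix is rank deficient are handled
conservatively: single-tissue neighbourhoods yield an estimate for that
tissue only, and colinear mixed-tissue designs are masked out rather
than extrapolated.

# Order-restricted Bayesian ANCOVA

Hypotheses are ordered partitions of the group levels, e.g.
`[control=scd] < mci < ad`: levels within a block are equal, block means
increase strictly. The model for a metric `y` is a Gaussian linear model
with intercept and covariates (age standardised; sex and site as
sum-to-zero contrasts) in *both* the null and alternative models —
they are controls, not hypotheses — and group-block effects only in the
alternative. Whether the original analyses placed priors on covariates
in both models is not documented; making them common nuisance parameters
is the choice that lets their improper priors cancel exactly in the
Bayes factor. Site enters as fixed sum-to-zero effects (a random-effect
treatment is not identifiable with three sites and is not attempted).

Block effects get a zero-centred exchangeable prior with variance
`g sigma^2`, with `g` mixed over a scaled inverse-chi-squared
distribution (1 df, scale `0.5^2`) — the standard heavy-tailed default
prior on standardised effects with scale 0.5. Effects are parameterised
on an orthonormal basis of the sum-to-zero subspace, which makes the
implied block effects exchangeable; exchangeability is what gives the
analytic prior ordering probability `1/k!` for `k` blocks.

Three computational routes are combined:

1. **Marginal likelihood ratio** of the (merged) group model versus the
   null: for fixed `g` the coefficients and error variance integrate
   analytically (flat priors on common parameters, Jeffreys on
   `sigma^2`), leaving a one-dimensional integral over `g` evaluated by
   adaptive quadrature on the log scale after locating the integrand
   peak on a coarse grid. Fully deterministic; validated in the tests
   against a brute-force two-dimensional grid integration over
   `(g, sigma^2)`.
2. **Posterior ordering probability** from a Gibbs sampler. All
   conditionals are conjugate — coefficients jointly Gaussian, `sigma^2`
   inverse-gamma, and `g` itself inverse-gamma under its scaled
   inverse-chi-squared prior — so no grid or slice step is needed for
   the scale hyperparameter. Four chains, split-half R-hat and
   autocorrelation-corrected effective sample sizes are reported; the
   suite checks the posterior mean against a Rao-Blackwellised
   quadrature oracle.
3. **Encompassing identity**: `BF = BF_full x Pr(order | data) /
   Pr(order | prior)`, with equality blocks handled by merging factor
   levels before step 1, which keeps the identity exact. Draws that
   satisfy the ordering only with ties count as violations (a
   probability-zero event under the continuous posterior, decided for
   determinism). A posterior probability of exactly zero yields BF = 0
   with a warning rather than an error, with the Monte-Carlo standard
   error reported alongside.

Equality-merged designs also answer a practical question: with the
equality `control = scd` true in the generator, the unmerged model M1
can still fit well, but it pays both an Occam penalty for the wasted
parameter and a posterior-probability penalty (the chance that the two
equal groups order correctly is ~1/2), which is why the merged model M2
wins the model comparison in most replicates of the recovery study.

# Problem sizes and runtime choices

The package's own validation uses sizes chosen to keep the full suite
fast while leaving the conclusions stable: phantom grids of 16^3 for
unit round-trips and 32 x 32 x 24 for cohort-level checks; a
100-subject (5 x 20) image-level cohort for the sCoV-CBF correlation;
and 20-replicate record-level simulation studies at n = 300 with 3000
posterior draws for model recovery (true model `[control=scd]<mci<ad`,
effects of 0.5 and 1 residual SD) and null calibration. Record-level
simulation (`simulate_metric_cohort()`) is used for the Bayesian
calibration studies because the image pipeline adds runtime but no
information once its own correctness is established separately. With 20
replicates the recovery rate carries binomial Monte-Carlo error of
roughly +/- 0.09, which is visible when comparing runs under different
master seeds.

# Known limitations

* The phantom is geometric, not anatomical; registration, segmentation
  errors, atrophy and lesions are absent, so passing tests demonstrate
  the *mechanism* and the *statistics*, not robustness to real-data
  artefacts.
* Motion, temporal autocorrelation, dispersion and background
  suppression are not modelled; the noise model is white Gaussian.
* Single-PLD only: measured CBF and ATT effects are confounded by
  design, which is precisely the phenomenon sCoV exploits — the package
  cannot (and does not try to) estimate ATT itself.
* The sCoV-CBF correlation magnitude is configuration-dependent; only
  its sign is a designed-in property.
* Bayes factors depend on the effect-prior scale (default 0.5); the
  package reports, but does not optimise, sensitivity to it.
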