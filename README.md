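# aslcov

Simulation and analysis of the **spatial coefficient of variation (sCoV)**
of cerebral blood flow (CBF) maps from pseudo-continuous arterial spin
labelling (pCASL) MRI.

## The problem

In single post-labelling-delay (PLD) ASL, the measured perfusion signal
depends on the arterial transit time (ATT): when the label has not fully
reached the capillary bed at imaging time (ATT > PLD), distal tissue
appears hypoperfused while feeding vessels stay bright. The spatial
heterogeneity of the resulting CBF map — summarised per region as

    sCoV = sigma / mu x 100%

with `sigma` and `mu` the standard deviation and mean of *non*-partial-
volume-corrected CBF inside an ROI — is therefore a surrogate marker of
ATT, and by extension of cerebrovascular health. In cohorts spanning the
trajectory from healthy ageing through subjective cognitive decline
(SCD) and mild cognitive impairment (MCI) to probable Alzheimer's
dementia (AD), sCoV is expected to rise with disease severity.

`aslcov` is for methodologists who want to study this mechanism
quantitatively without access to patient data. It provides:

* **Digital phantom cohorts** — stylised three-shell brains with
  partial-volume fractions, ground-truth CBF/ATT maps with
  group-dependent ATT prolongation and regional hypoperfusion, subject
  covariates (age, sex, site) and a macrovascular compartment.
* **Kinetic forward model** — the single-compartment pCASL general
  kinetic model (labelling efficiency 0.60, blood T1 1.65 s, labelling
  duration 1.8 s, PLD 1.8 s, 8 repeats) plus a gated stalled-label
  arterial term, with Gaussian acquisition noise.
* **Quantification** — white-paper CBF calibration (M0 saturation
  correction, partition coefficient 0.9 ml/g), which inverts the forward
  model exactly when ATT <= PLD, and local linear-regression partial
  volume correction.
* **ROI metrics** — sCoV and mean CBF over total grey matter, four
  lobes, and PCC / precuneus / hippocampus / angular gyrus parcels.
* **Order-restricted Bayesian ANCOVA** — Bayes factors for hypotheses
  such as `[control=scd] < mci < ad` against a covariates-only null, via
  g-prior marginal likelihoods and the encompassing-prior identity
  `BF = BF_full x Pr(order | posterior) / Pr(order | prior)`, with
  `Pr(order | prior) = 1/k!` for `k` ordered blocks.
* **Classical cohort statistics** — one-way ANOVA and pairwise t tests
  from summary statistics, chi-squared independence tests, vascular-risk
  scoring, Pearson and partial correlations.

## Worked example

```r
library(aslcov)

# A 122-subject cohort (controls 20, SCD 44, aMCI 23, mMCI 22, AD 13)
cfg <- pipeline_config(cohort = cohort_config(seed = 5L),
                       restrictions = default_restrictions(),
                       out_dir = "run1", seed = 5L)
res <- run_pipeline(cfg)   # simulates, quantifies and analyses in seconds

aggregate(scov_gm ~ group4, res$metrics, mean)
#    group4  scov_gm
# 1 control 31.60382
# 2     scd 31.57888
# 3     mci 31.92976
# 4      ad 33.28331

res$bf_report[, c("model", "bf_vs_null", "posterior_constraint_prob")]
#   model   bf_vs_null posterior_constraint_prob
# 1    M1  49828.77739                   0.58325
# 2    M2 102127.86110                   0.97350
# 3    M3     18.79633                   0.56750
# 4    M4     31.68883                   0.99850
```

The simulated cohort prolongs ATT equally in the MCI and AD groups
relative to (identical) controls and SCD, so GM sCoV increases across
groups and the equality-block model `M2: [control=scd] < mci < ad`
earns the largest Bayes factor, with the per-model posterior ordering
probabilities shown alongside (exact values vary with grid and seed;
the cohort-level sCoV-CBF correlation in this run is -0.83).

Single operations are available directly:

```r
p <- acq_params()
tissue_delta_m(f = 60, att = 1.0, m0b = 1, p)   # 0.00441688...
spatial_cov(array(c(40, 60, 50, 50), c(4,1,1)), array(TRUE, c(4,1,1)))
# 16.32993  (percent)
```

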