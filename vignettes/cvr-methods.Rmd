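---
title: "Methods: hypercapnic CVR, change scores and the association suite"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: hypercapnic CVR, change scores and the association suite}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cvreact)
```

This vignette documents the models implemented in `cvreact`, the assumptions
behind them, the parameters that matter, and the design decisions taken
where the underlying methodology left choices open.

## The hypercapnia paradigm and capnometry model

The gas paradigm is a block design: an initial 60 s of medical air (the
normocapnic baseline), then two 75 s blocks of 5% CO₂ in air, each followed
by 75 s of air (360 s total). The first block must be air because it defines
both the regressor's baseline window and the denominator condition of
ΔEtCO₂.

The synthetic capnogram (`simulate_capnometry()`) is a train of breaths.
Each breath is a raised-cosine rise from the inspiratory floor to a flat
end-tidal plateau occupying `plateau_fraction` of the breath, followed by a
raised-cosine fall. The flat plateau is deliberate: it gives every breath an
unambiguous maximum, so an exhaustive per-breath maximum search is a valid
oracle for the peak detector, and ground-truth breath times are pinned to
the first trace sample inside each plateau so detection can be checked for
exact agreement. Plateau values relax toward the current block target
(baseline, plus the hypercapnic boost during CO₂ blocks) through a
first-order exponential with time constant `transition_time_constant`,
mimicking physiological wash-in/wash-out while keeping the "second half of
the block is steady" assumption satisfiable.

Defaults, chosen as conventional resting-adult values since the study these
methods emulate does not report its participants' respiratory parameters
(they are free parameters, not study estimates):

| parameter | default | units | rationale |
|---|---|---|---|
| `breathing_rate` | 12 | breaths/min | typical resting adult |
| `baseline_etco2` | 40 | mmHg | normocapnia |
| `hypercapnic_boost` | 8 | mmHg | typical response to 5% CO₂ |
| `transition_time_constant` | 10 | s | physiological wash-in |
| `inspiratory_floor` | 2 | mmHg | mask re-breathing |
| `sampling_rate` | 20 | Hz | capnometer-like; ≥ 4 samples/breath enforced |
| `plateau_fraction` | 0.3 | — | end-tidal plateau share of the breath |

## End-tidal extraction and the regressor

`extract_end_tidal()` detects breaths as local maxima with a minimum
separation (`min_breath_period`, default 2 s, i.e. at most 30 breaths/min)
and a minimum topographic prominence (default 10% of the trace range, which
rejects ripple without touching genuine expiratory peaks). Flat plateaus are
run-length compressed and dated at their first sample — the same tie-break
as `which.max` — which is what makes detector-vs-oracle agreement exact
rather than approximate. Degenerate inputs (constant traces, traces shorter
than two breaths, no peak above the prominence threshold) are errors, not
empty results.

The regressor (`build_regressor()`) is the piecewise-linear interpolation of
the breath-wise envelope onto the BOLD grid — linear because it is
oracle-checkable by hand and the envelope is smooth at breath resolution —
normalized as (x − baseline mean)/max(x). Two numerical choices:

* The baseline mean used for centring is the *breath-wise* mean of the
  end-tidal series, not the sample mean of the interpolant over the window.
  Interpolation smears the first block transition back across the boundary,
  so the sample mean is contaminated by the first CO₂ block; the breath-wise
  mean is not. The centring constant only shifts the GLM intercept, but that
  intercept is used for unit conversion (below), so the uncontaminated
  version is the right one.
* The divisor is the global maximum of the interpolant, matching a literal
  reading of "divide by the maximum EtCO₂", and the identical constant is
  reused when converting the GLM coefficient back to mmHg — so the
  conversion is internally consistent whatever the interpolant's exact
  maximum is.

An optional bulk haemodynamic delay can be estimated by maximizing the
cross-correlation with the BOLD series over a 0–15 s grid (0.5 s steps). It
is off by default: the emulated analysis does not describe delay
correction, so it must not silently alter results, but the option exists
because real BOLD responses lag EtCO₂ by several seconds.

ΔEtCO₂ is the mean of per-block means over breaths in the half-open second
half (midpoint, end] of each CO₂ block, minus the mean over the initial air
block. The half-open interval is an arbitrary but unambiguous reading of
"second half"; per-block means (rather than pooling breaths) keep the two
blocks equally weighted when breath counts differ. On generator output the
recovered ΔEtCO₂ equals the planted boost exactly for instantaneous
transitions and converges monotonically to it as the wash-in time constant
shrinks — the residual bias is the exponential tail
`boost · exp(−t/τ)` averaged over the second-half window.

Trace QC codifies what is usually a visual check, with configurable numeric
thresholds: steady state within each CO₂ block (|least-squares slope of
second-half breath values| ≤ 0.02 mmHg/s) and baseline return after each
block (|post-block air mean − initial baseline| ≤ 2 mmHg). The defaults are
deliberate codifications, not study estimates; the report never gates any
computation.

## The BOLD forward model and CVR estimation

The forward model is
`s(t) = s0 (1 + CVR (e(t) − ē_base)/100) + d₁t + d₂t² + ε(t)` with
stationary AR(1) noise (`noise_sd` is the marginal SD; the lag-1
autocorrelation is the `ar1_coefficient`). It deliberately omits
haemodynamic convolution beyond the optional bulk delay, cardiac and
respiratory harmonics, and motion — so passing recovery tests shows the
estimator is correct *for this signal model*, not that real-data nuisance
structure is handled.

Estimation is OLS of the BOLD series on (intercept, normalized regressor,
polynomial drift up to order 2). Three decisions:

* **No prewhitening.** Reference fMRI tools prewhiten; at single-ROI desk
  scale with drift modelled, AR(1) noise leaves the point estimate unbiased
  and inflates only its standard error, so the estimator stays closed-form
  and oracle-checkable. The reported SEs are therefore anti-conservative
  under autocorrelated noise — a documented divergence; the unbiasedness
  (not the SE) is what the replicate tests assert.
* **Polynomial drift, not high-pass filtering.** The emulated analysis does
  not state its temporal filtering; polynomial drift keeps the normal
  equations exact. Drift columns are `t/100` and `(t/100)²` — zero at t = 0,
  so the intercept remains the drift-free baseline estimate; the scaling is
  for conditioning only.
* **Unit conversion against the fitted intercept.** Percent BOLD could be
  defined against the baseline-window mean, the series mean, or the fitted
  intercept; the emulated analysis does not say. `estimate_cvr()` fits the
  raw signal and converts via `CVR = 100 β / (β₀ · max EtCO₂)` because the
  intercept is the *drift-free* baseline: with any drift inside the modelled
  order, planted CVR is recovered exactly (machine precision), which a
  window-mean baseline cannot achieve since its mean is drift-contaminated.
  `to_percent_change()` (window-mean, configurable window) is retained for
  voxelwise maps and for users who want the conventional definition; the
  two routes agree exactly when drift is zero, and the
  normalized-regressor and raw-mmHg parameterizations agree identically
  always.

ROI means are unweighted over mask voxels; bilateral hippocampal CVR is the
simple mean of left and right. Outlier screening uses the raw MAD — no
1.4826 normal-consistency factor — because the rule it implements is stated
directly in MAD units with multiplier 6; the inequality is strict, so an
all-equal sample (MAD 0) flags nothing.

## Cross-scanner change scores

Within each wave and metric, values are z-scored with the sample (n−1) SD —
the default of base R's `scale()`. Δ = z₂ − z₁ is exactly invariant to any
positive-scale affine transform applied to one wave, which is the point of
the construction: the two waves come from different scanners. The cost,
stated plainly: Δ is relative to the cohort, supports no inference about
absolute change, and a participant can have negative Δ while their anatomy
was stable if the cohort around them changed less. Decline orientation is
attached per metric family (volumes and FA decline downward, diffusivities
upward). Participants missing a wave are dropped listwise with a reported
count (the emulated analysis studies completers); an error mode listing the
missing IDs is available.

WMH is not standardized — lesion segmentation is assumed consistent across
scanners — but expressed as log percent of total brain volume. The log base
is configurable with natural log as the default, because the source
methodology says only "log-transformed" and its printed summary statistic is
hard to reconcile with either base; no claim is made about the original
choice, and the change score Δlog is base-consistent in any case.

## The association suite

Each outcome is fit by OLS with intercept on complete cases: cross-sectional
outcomes (wave-2 values) adjust for age at wave 2 and sex; hippocampal
volume outcomes additionally adjust for total GMV — the source description
is internally inconsistent on this point (its methods say age and sex; its
results say age, sex and total GMV), and the suite follows the results-level
specification, recording the choice in the output's `covariate_note`
attribute. Longitudinal outcomes (Δ scores) adjust for age at wave 1, sex
and the inter-wave interval. GMV models use the side-matched hippocampal CVR
exposure; tract and WMH models use the bilateral average; a whole-brain
exposure variant reuses the same covariate sets since nothing different is
specified.

The Benjamini–Hochberg step-up adjustment is implemented directly (sort,
`p·m/i`, cumulative minimum from the largest rank, cap at 1, map back; ties
share adjusted values) and is property-tested against both a brute-force
step-up implementation over a grid of q levels and the independent
`stats::p.adjust` reference. Families are the four tracts within one
diffusion metric per design — exactly four comparisons per family — and the
single GMV and WMH tests are uncorrected. Published adjusted values are
reproduced at 3 decimals, except cells the source computed from unrounded
p-values, which differ by one unit in the last place when recomputed from
the printed (rounded) inputs.

Cohen's f² is R²/(1−R²) for the whole model and ΔR²/(1−R²) per predictor
(leave-one-out refits). It is undefined at R² = 1 (an error in the
primitive; `fit_association` reports `Inf` for the overall measure on exact
fits). Shapiro–Wilk is computed on residuals and reported, never used to
discard a fit — no remediation rule was specified. Sex enters as a binary
factor with "female" as the alphabetical reference level; the coding affects
only the sex coefficient, never the exposure β.

## The synthetic cohort

`simulate_cohort()` draws, per participant: sex (26% female), age at wave 1
(68.2 ± 4.4 y), inter-wave interval (8.7 ± 1.2 y, truncated at 1), and a
latent hippocampal CVR from a normal (0.205 ± 0.07 %/mmHg) truncated at zero
by rejection — CVR is a positive vasodilatory response. Hemisphere values
add small independent jitter (SD 0.02); whole-brain CVR runs 0.075 higher
with SD 0.03. Latent metric distributions take the published wave-2
descriptives as wave-1 latents (only wave-2 descriptives are printed);
annual-change base rates are conventional ageing values (−0.6%/y for
volumes, −0.002/y for FA, +0.4%/y for diffusivities) with annual SD of 5% of
the metric SD and measurement noise of 10% of the metric SD, chosen once as
realistic and not tuned thereafter. Observed values apply a per-wave affine
scanner effect (default: identity at wave 1; scale 1.05 and offset 2% of the
metric mean at wave 2). Planted cross-sectional and longitudinal effects
default to zero, so the default cohort is a null cohort; CVR is independent
of age by default. WMH is generated on the natural-log percent scale with
tissue volumes drawn separately and converted to volumes.

What this generator does *not* emulate — spatial structure, scanner noise
that is not affine, non-Gaussian metric distributions, CVR–age dependence,
informative dropout — bounds what the passing test suite demonstrates about
real cohorts.

## Problem sizes and reproducibility

All randomness flows through explicit integer seeds (`withr::with_seed`, so
the global RNG state is untouched); identical seeds give bit-identical
output. The test suite and the acceptance script use: three planted CVR
levels for exactness; 200 AR(1)-noise replicates for unbiasedness; 100
randomized traces for detector-oracle agreement; 500 null cohorts of n = 154
(the analysed sample size of the emulated study) for type-I calibration; and
400 planted-effect cohorts for CI coverage — sizes chosen so each check has
useful statistical resolution while the whole suite runs in minutes on one
CPU.
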