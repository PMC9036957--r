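---
title: "Modelling non-Gaussian diffusion decay and evaluating its parameters as biomarkers"
author: "frocdwi"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling non-Gaussian diffusion decay and evaluating its parameters as biomarkers}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(frocdwi)
```

## The signal model

Conventional diffusion-weighted MRI quantifies water mobility with the
mono-exponential (Gaussian) model $S(b) = S_0 e^{-b\,\mathrm{ADC}}$.  In
tumour tissue the decay over an extended b-value range is visibly
non-mono-exponential, and the fractional-order-calculus (FROC)
generalisation describes it with three parameters instead of one:

$$
S(b) \;=\; S_0 \exp\!\left[-D\,\mu^{2(\beta-1)}\,
  (\gamma G_d \delta)^{2\beta}
  \left(\Delta - \frac{2\beta-1}{2\beta+1}\,\delta\right)\right],
$$

where $D$ (reported in $10^{-3}\,\mathrm{mm^2/s}$) is an anomalous
diffusion coefficient, $\beta \in (0,1]$ is an intravoxel heterogeneity
exponent ($\beta = 1$ recovers Gaussian diffusion exactly; lower $\beta$
means a more heterogeneous microenvironment), and $\mu$ (µm) is a spatial
scale that keeps the units consistent and has been related to a mean free
diffusion length.  $\gamma$ is the proton gyromagnetic ratio, $G_d$ the
diffusion gradient amplitude, and $\delta$, $\Delta$ the Stejskal–Tanner
pulse duration and separation.

Clinical acquisitions rarely record $G_d$; protocols are specified by their
b-values.  The package therefore eliminates $G_d$ analytically through
$b = (\gamma G_d \delta)^2(\Delta - \delta/3)$, i.e.
$(\gamma G_d \delta)^{2\beta} = [\,b/(\Delta - \delta/3)\,]^{\beta}$,
so an acquisition is fully described by `(b, delta, Delta)`
(`acquisitionScheme()`).  The built-in `cervicalProtocol()` carries the
nine-b-value pelvic protocol (0–2000 s/mm²) used in the worked examples;
its default timing $\delta = 20$ ms, $\Delta = 40$ ms is an explicit
assumption, typical of a 3 T spin-echo EPI preparation, and can be
overridden.  All internal evaluation is done in a consistent (mm, s) unit
system; parameters are reported in the map units above.

## What the data can and cannot identify

When the b-value is varied only through the gradient amplitude at fixed
timing — the usual single-preparation protocol, and the only one the
b-value surrogate supports — the exponent above collapses to an exact power
law in $b$:

$$
-\log\frac{S(b)}{S_0} \;=\;
  \underbrace{D\,\mu^{2(\beta-1)}\,(\Delta-\delta/3)^{-\beta}
  \Big(\Delta - \tfrac{2\beta-1}{2\beta+1}\delta\Big)}_{C}\; b^{\beta}.
$$

The decay curve therefore determines exactly three quantities: $S_0$,
$\beta$, and the composite scale $C$.  $D$ and $\mu$ enter only through
the product $D\,\mu^{2(\beta-1)}$ and **cannot both be recovered from a
single-timing acquisition**; the $(D,\mu)$ direction at constant product
is an exactly flat ridge of the least-squares surface.  This is a property
of the model-plus-protocol, not of any particular optimizer.

`fitFroc()` handles this explicitly:

1. **Low-b stage.** Log-linear regression over $b \le 200$ s/mm² (the
   densely sampled quasi-Gaussian segment; configurable) initialises $S_0$
   and $D$.  The low-b slope is kept in the fit object (`stageD`) as a
   diagnostic; note that for power-law data it is a biased estimate of $D$
   whenever $\beta < 1$.
2. **Main stage.** Bounded Levenberg–Marquardt over the *identifiable*
   pair $(D, \beta)$ across all b-values, with $\mu$ held at its anchor
   (default 8 µm, a typical tissue-scale diffusion length, which is also
   the initializer) and $S_0$ at its stage-1 value.
3. **Refinement.** One joint bounded pass over $(S_0, D, \beta, \mu)$.  A
   weak quadratic anchor on $\log\mu$ (weight $10^{-3}\max S$) is appended
   to the residuals: on the flat ridge it pins the otherwise arbitrary
   $\mu$ near its anchor without measurably perturbing $S_0$, $\beta$ or
   the identifiable scale; on data that do constrain $\mu$ (e.g. a future
   multi-timing scheme) it is negligible against any real gradient.

Consequences, verified by the test suite: on noiseless signals $\beta$ and
the composite scale $C$ are recovered to numerical precision, while $D$
and $\mu$ carry a residual few-percent offset equal to the unidentifiable
part ($\hat D/D = (\mu/\mu_0)^{2(\beta-1)}$, about 2–3% for tissue-like
parameters with $\mu$ within half a micron of the anchor).  An alternative
staged design that fixes the low-b $D$ and fits $(\beta,\mu)$ — sometimes
seen in the literature — places the entire ridge ambiguity on $\mu$ and
inherits the low-b bias in $D$ (roughly +30% for $\beta \approx 0.7$ on
this protocol); we consider the anchored parameterisation strictly
preferable and report `stageD` separately.

Bounds default to $D \in [0.01, 3]$, $\beta \in (0.3, 1]$,
$\mu \in [1, 20]$ µm, $S_0 \in (0, 2\max S]$ — generous envelopes around
tissue values.  Fitting never raises on optimizer stalls; `converged` is
set FALSE and the best point returned, and `fitMap()` counts such voxels
per map rather than aborting (voxel failure must not kill a whole-lesion
analysis).  The whole procedure is deterministic: refitting the same
signal is bitwise identical.

The ADC is deliberately the simple two-point estimator
$\ln(S(0)/S(1000))/1000$, matching routine clinical practice rather than a
multi-b regression, and is exact on any mono-exponential input.  No Rician
bias correction is applied by default (at SNR 50 the floor bias at
$b = 2000$ is below $10^{-3}$ of $S_0$).

## Synthetic cohorts and phantoms

Because the patient data underlying this kind of analysis are not publicly
deposited, every downstream stage is exercised on synthetic data with the
study's statistical structure.

* `cohortPreset("subtype")` emulates a 60-patient cohort of 47 squamous
  cell carcinoma (SCC) and 13 adenocarcinoma (ACA) subjects;
  `cohortPreset("grade")` the same 60 patients split 28 low-grade / 32
  high-grade.  Per-group means and SDs of VOI-mean ADC, $\beta$, $D$ and
  $\mu$ follow the published per-group statistics (e.g. $\beta$ 0.67 ±
  0.05 in SCC vs 0.71 ± 0.08 in ACA; high-grade lower than low-grade in
  ADC, $\beta$ and $D$, with $\mu$ means nearly equal at 8.26 vs 8.27).
* Parameters are drawn **independently** per subject from truncated
  normals ($\beta$ truncated to (0.3, 1], others to the fitting bounds):
  the source tables give no covariance structure, and some cells are
  visibly non-normal (median/range are not matched).  Both points are
  limitations: passing tests show the pipeline recovers *this* structure,
  not that real lesions are truncated-normal or uncorrelated.
* `phantomTruth()` + `makePhantom()` build image-level phantoms: a
  20×20×5 grid (defaults chosen to keep full voxelwise fits at minute
  scale) with a central ellipsoidal lesion, uniform $S_0$, signals from
  the FROC forward model, and Rician noise
  $M = \sqrt{(S+n_1)^2 + n_2^2}$ at $\sigma = S_0/\mathrm{SNR}$.  No
  anatomical realism, partial volume, necrosis or motion is simulated.

All stochastic functions take a mandatory or explicit seed and restore the
caller's RNG state; a fixed configuration reproduces its outputs byte for
byte.

## The statistics pipeline

`runSimulationStudy()` mirrors a VOI-mean biomarker analysis end to end:

* **Group comparison** (`mannWhitney`): two-sided rank-sum test per
  parameter.  Exact enumeration when both groups have ≤ 8 observations
  and no ties (a common conservative switch point); otherwise the normal
  approximation with tie correction and *no* continuity correction,
  matching the asymptotic output of the mainstream clinical packages this
  analysis family is usually run in.  Bonferroni adjustment uses
  $m = 4$ (the four parameters compared per analysis).
* **ROC analysis** (`rocAnalysis`): Mann–Whitney (trapezoidal) AUC with
  ties at half credit; orientation auto-selected so AUC ≥ 0.5 and
  recorded.  The 95% CI uses the Hanley–McNeil standard error with a
  normal approximation, clipped to [0, 1] — the classical companion to
  the Hanley–McNeil curve comparison below.  The operating point
  maximises the Youden index over observed thresholds with the rule
  "score ≥ cutoff ⇒ positive"; ties in the index resolve to the lowest
  qualifying cutoff, for determinism.  Sensitivity is defined on the
  configurable positive class (high-grade, or SCC in the subtype
  analysis).  Accuracy is computed at that cutoff on the same cohort —
  in-sample, as in the design being emulated; no cross-validation is
  attempted.
* **Logistic combination** (`logisticCombine`): unpenalised ML logistic
  fit of the binary outcome on each parameter combination ($D+\beta$,
  $D+\mu$, $\beta+\mu$, $D+\beta+\mu$); the combined score is the linear
  predictor, whose ROC is invariant to monotone transforms.  Complete
  separation is flagged, not fatal — the final iterate still ranks.
* **Correlated AUC comparison** (`compareAuc`):
  $z = (A_1 - A_2)/\sqrt{SE_1^2 + SE_2^2 - 2 r\,SE_1 SE_2}$ with
  Hanley–McNeil SEs ($Q_1 = A/(2-A)$, $Q_2 = 2A^2/(1+A)$).  For paired
  curves, $r$ is the correlation between the two AUC estimators computed
  from DeLong placement components — the quantity the classical published
  lookup table approximates under a binormal model.  We compute it from
  the data rather than interpolating the table: it is exact for the
  empirical estimators and free of the binormal assumption.  Unpaired
  comparisons use $r = 0$.
* **McNemar test** (`mcnemarTest`): exact two-sided binomial on the
  discordant pairs when there are ≤ 25 of them, continuity-corrected
  chi-square $(|b-c|-1)^2/(b+c)$ beyond; zero discordance returns p = 1.

## Numerical and design choices

* Tolerances: optimizer stages run Levenberg–Marquardt at its default
  relative tolerances with a 200-iteration cap per stage; the refinement
  is only accepted if it does not worsen the data RSS.
* Degenerate inputs: all-zero signals, empty masks, one-class label
  vectors, mismatched sidecars and non-overlapping VOIs raise descriptive
  errors (or a warning plus skip at the pipeline level, where one subject
  must not abort a cohort).
* Problem sizes in the shipped tests and acceptance script — 200 voxels
  per group at SNR 50 for recovery, 50 signals against the exhaustive
  $(D,\beta,\mu)$ grid oracle at resolution (0.01, 0.01, 0.1), $10^5$
  draws for the Rician moments, 1000 replicates for the Mann–Whitney null
  calibration, ten-fold cohorts for direction checks — were chosen as the
  smallest sizes at which the checked quantities are stable to well within
  their asserted bands.
* The VOI mean uses converged voxels only, and the converged fraction is
  reported; masks must already live on the DWI grid (no resampling — the
  propagation from the b = 0 image to the maps is an identity mapping
  because every map derives from the same series).
* Voxelwise-then-average is the default analysis path; fitting the
  VOI-mean signal instead is available by averaging before `fitFroc()`.

## Known limitations

* $\mu$ is not separately identifiable from single-timing data (above);
  reported $\mu$ maps inherit the anchor scale.  Multi-timing acquisitions
  would resolve this and are not yet supported.
* Synthetic cohorts ignore inter-parameter correlation and non-normality;
  image phantoms ignore anatomy.  Agreement with the published direction
  of group differences is therefore a check of the pipeline, not evidence
  about tissue.
* In-sample operating characteristics are optimistically biased by
  construction; the package reproduces that design rather than correcting
  it.

## A minimal run

```{r, eval = FALSE}
cfg <- pipelineConfig("grade", seed = 7)
res <- runSimulationStudy(cfg)
res$comparisons   # per-parameter Mann-Whitney with Bonferroni
res$rocCombined   # sens/spec/accuracy/AUC for ADC and the combinations
res$pairedVsAdc   # Hanley-McNeil and McNemar of each combination vs ADC
```
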