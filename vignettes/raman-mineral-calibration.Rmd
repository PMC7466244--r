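---
title: "Calibrating mineral content from Raman spectra: models, choices and limits"
author: "RamanMinerals"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Calibrating mineral content from Raman spectra}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(RamanMinerals)
```

## The problem and the model

A reconstituted infant-formula sample is a dilute aqueous suspension of
lactose, protein and lipid carrying trace minerals (low ppm).
Minerals contribute almost nothing to the Raman spectrum directly —
free ions are very weak scatterers — but their concentration covaries
with the matrix constituents they bind to, and chelation perturbs
low-frequency hydration structure (roughly 170–220 cm⁻¹) and the
amino-acid binding region (roughly 760–1665 cm⁻¹). A linear latent-variable
regression can therefore calibrate ppm-scale mineral content against the
full spectrum even though no single "mineral band" exists.

The regression is PLS1: with mean-centered spectra $X$ (n samples ×
J channels) and response $y$ (ppm from ICP-AES), NIPALS extracts
components $w_a = X'y/\lVert X'y\rVert$, $t_a = Xw_a$,
$p_a = X't_a/t_a't_a$, $q_a = y't_a/t_a't_a$, deflating
$X \leftarrow X - t_ap_a'$ and $y \leftarrow y - q_at_a$. Predictions at
$a$ components use $B_a = W_a(P_a'W_a)^{-1}q_a$. Only mean-centering is
applied — all channels share intensity units (counts/s), so
unit-variance scaling would only amplify noise-dominated channels; a
`center` switch exists for the rare case that raw cross-products are
wanted.

Model complexity is selected by venetian-blinds cross-validation: sample
$i$ (dataset order) belongs to fold $i \bmod s$, a deterministic
interleave that respects the level-ordered layout of a designed
calibration series. The retained component count is the smallest $a$
whose RMSECV is within a parsimony tolerance (default 2%) of the
minimum; a fixed $a$ can be forced per model. Reported metrics are the
standard set: $R^2$, RMSE and mean signed bias on calibration,
cross-validation and (in split designs) external prediction.

## Pre-treatments

Fluorescence dominates raw fiber-probe spectra of dairy matrices, and
its amplitude varies sample to sample, injecting response-irrelevant
variance. Four pre-treatments are provided, three sharing one penalized
least-squares core:

* `whittakerSmooth(y, w, lambda)` minimises
  $\sum_i w_i(y_i-z_i)^2 + \lambda\sum_i(\Delta^2 z)_i^2$ via the
  sparse banded system $(W + \lambda D'D)z = Wy$. The second-difference
  penalty's null space is the affine functions, so $z$ tends to the OLS
  line as $\lambda \to \infty$ — a property the tests exploit as an
  oracle.
* **AsLS** (default $\lambda = 10^5$, $p = 0.01$, ≤ 50 iterations):
  weights $p$ above and $1-p$ below the running baseline; iteration
  stops when the weight pattern is stable. These are the standard
  literature defaults; $\lambda$ sets the baseline's stiffness
  (in channel⁴ units, dimensionless in practice) and $p$ how strongly
  peaks are treated as outliers above the baseline.
* **airPLS** (default $\lambda = 10^5$, tolerance $10^{-3}$, ≤ 30
  iterations): weight 0 at or above the baseline and
  $\exp(t\,\lvert d_i\rvert/\lvert d^-\rvert_1)$ below it at iteration
  $t$; terminates when the $\ell_1$ mass of negative residuals falls
  below tolerance × $\lVert y\rVert_1$.
* **BOC** is defined here as subtraction of the per-spectrum minimum.
  The name "baseline offset correction" is used loosely in the applied
  literature; minimum-offset is the common reading and the one
  implemented.
* **Savitzky–Golay first derivative** (window 7, degree 2) is delegated
  to the `signal` package's filter matrices, whose edge handling — the
  terminal window's polynomial fit evaluated at the edge positions — is
  exactly the behaviour required for the operator to be linear and
  polynomial-exact. Derivatives are returned per channel index, not per
  cm⁻¹: the axis spacing is a constant factor that cancels after
  centering inside PLSR, and treating it this way avoids committing to
  an axis spacing (see below).

Every baseline method returns baseline, corrected spectrum and final
weights, with `baseline + corrected` reconstructing the input to within
one ulp of the floating-point additions.

## Variable selection

* **VIP** accumulates each channel's share of explained response
  variance over components; the mean of squared scores is exactly 1 by
  construction, and the default cutoff of 1 ("greater than average
  influence") is used because selected-channel counts, not cutoffs, are
  what such studies report.
* **sMC** regresses each centered channel on the fitted response and
  flags channels whose one-regressor F statistic exceeds the
  $F(1, n-2)$ critical value. A channel with zero residual is capped at
  the largest double and flagged. Of the three methods this one has the
  least-standardized definition in the applied literature; the
  implementation here is the F-test form stated above.
* **Martens' uncertainty test** records the coefficient vector of each
  cross-validation segment model, forms the delete-group jackknife
  variance $\frac{M-1}{M}\sum_m (b_j^{(m)}-b_j)^2$, and compares
  $\lvert b_j\rvert/se_j$ with the two-sided t critical value at the
  model's residual degrees of freedom $n - A - 1$. The segment count
  would be the naive df choice, but the jackknife pools deviations
  measured on all $n$ samples; using the residual df keeps the test's
  empirical type-I rate near nominal (the test suite measures ≈ 3.6%
  at $\alpha = 5\%$ on pure noise, versus ≈ 1.3% with df $= M-1$).
  Zero jackknife variance with a zero coefficient marks a channel
  non-significant; with a nonzero coefficient (degenerate identical
  segments) it is flagged.

Selection is one-pass — select once on the full-variable model, refit
and re-cross-validate on the retained channels — not iterative
elimination.

## Study designs and the quasi-random split

`evaluatePipeline` chains averaging → pre-treatment → cropping →
optional exclusion → optional split → CV/fit → optional selection →
validation prediction, and fills the report row used by `runGrid`
(which shares pre-treatments across a grid of configurations and marks
each element's lowest-RMSECV model).

"Quasi-random selection" of calibration/validation sets is implemented
as seeded rank-stratified alternation: samples are ranked on the
response, the global minimum and maximum are forced into calibration,
and remaining ranks alternate between the sets with a seeded swap per
rank pair, then sizes are trimmed to exactly $(n_{cal}, n-n_{cal})$.
This is standard calibration-design practice: it spreads both sets over
the response range while guaranteeing the validation set never
extrapolates. It shapes all split-design results, so it is worth
stating that any other reasonable splitter would change the prediction
rows, not the calibration machinery.

Outlier exclusion is an explicit id list in the configuration, never
automatic — mirroring how a single anomalous reference value is removed
by inspection in practice.

## The simulator: what it emulates and what it does not

`simulateDataset` reproduces the study design: 19 powder formulas,
levels 3/5/8/10/13% w/w, 83 aqueous samples (15 formulas at all five
levels, seven extra 13% samples, one extra 8% sample), duplicate scans,
a 3473-channel axis over 50–3398 cm⁻¹. Ground truth is bilinear:
intensities $= C S$ plus a per-scan fluorescence baseline
(log-normal amplitude × $e^{-\nu/1500}$ plus a proportional linear
tilt), a per-scan multiplicative factor (log-normal, sd 0.03,
representing probe repositioning), and additive noise whose sd rises
linearly from 1.5 cps below 1800 cm⁻¹ to 4× that at the axis end —
the high-shift noise inflation seen in fiber-probe CCD data.

Key design decisions:

* **Minerals act only through covariance.** Element concentrations are
  density (ppm per % w/w, drawn per formula with stratified coverage of
  the Table-1-scale range) × powder level, and each element modulates a
  dedicated component with support in 170–220 and 760–1665 cm⁻¹,
  proportionally to its ppm. There are no element-specific sharp peaks,
  matching the physics. Modulation presets make Ca/Mg/Fe/Zn "strong",
  K/Na "moderate" and Cu "weak", so both easy and hard calibration
  regimes are testable.
* **Default scales** put matrix bands at tens–hundreds of cps, mineral
  modulation at tens of cps, and fluorescence at ~900 cps mean — the
  background dominates the raw signal, which is precisely why the
  baseline-corrected models should (and in the tests do) beat raw-data
  models on every element.

What the simulator does **not** emulate: cosmic spikes (removed by
vendor software upstream), detector nonlinearity and wavelength drift,
scattering/turbidity effects of fat globules, chemical rank deficiency
between co-varying constituents beyond the built-in level correlation,
and reference-method error in $y$ (ICP repeatability is ~0.01–0.03 ppm,
negligible at simulation scale). Passing parameter-recovery tests
therefore demonstrates the correctness of the pipeline's computations
and its qualitative behaviour under a realistic covariance structure —
not that any particular R²CV is attainable on real instrument data.

`simulateSaltSpectra` provides the matching control experiment: one
spectrum per 1 M chloride salt, each a water background plus
salt-specific features confined to 50–465 cm⁻¹ — so the generated set
reproduces the observation that salt solutions differ most below
465 cm⁻¹ while high-shift regions are noise-limited.

## Numerical choices and degenerate inputs

* Whittaker systems are solved by sparse Cholesky on the banded normal
  equations; $\lambda = 0$ returns the input, all-zero weights are an
  error.
* NIPALS stops with an error if the residual $X'y$ norm underflows
  (exact fit reached before the requested component count) — the
  requested $A$ must respect $\min(n-1, J)$.
* The chosen-component tie-break is "smallest $a$ within 2% of minimum
  RMSECV"; `runGrid`'s best-model tie-break is fewest components.
* Axis spacing is treated as data: instrument nominal spacing and
  channel counts disagree in practice (a nominal 2 cm⁻¹ grid versus up
  to 3473 reported variables over 50–3398 cm⁻¹, implying ≈ 0.964 cm⁻¹).
  Nothing assumes uniform spacing except the S–G derivative, which
  checks it to 1e-6 relative and errors otherwise. The simulator's
  default of 3473 channels is chosen for consistency with the largest
  reported variable count.
* Cropping is closed-interval on both endpoints, matching inclusive
  range notation like "50–1800 cm⁻¹".
* Repeatability is the pooled within-sample replicate standard
  deviation (the reference texts leave the formula implicit); an
  `isoLimit` flag gives the ISO repeatability limit 2.8 × SD.
* The curve-quality gate "< 10% maximum error" is read as the maximum
  relative back-prediction error over non-blank standards; the blank is
  excluded because relative error at 0 ppm is undefined.
* Below-detection reference values (negative ppm) are passed through
  unmodified — flagging is the caller's job, censoring would bias the
  summaries.

## Problem sizes used in the checks

The test suite and the acceptance script run at desk scale, chosen so
the full default simulation (166 × 3473) is exercised once for the
study-level checks while unit properties use 60–500 channel problems:
oracle comparisons at 20 × 50 with up to 5 components, type-I
calibration at n = 60, J = 200 over 50 seeds, and selection-recovery
at 40 × 500. These sizes are the package's own verification design;
they keep every property sharply testable with exact or simulated
ground truth.

## Known limitations

* AsLS leaves a small composition-dependent envelope bias under broad
  bands (its baseline rides partway into wide features such as the
  water envelope); on noiseless simulated data the cross-validated
  error floor is therefore ~1% of response sd rather than machine zero.
  This is a property of the method, not a defect of the solver.
* sMC follows one published formulation of a loosely-specified method;
  selected-channel sets from other software may differ.
* The quasi-random splitter is one defensible reading of an undefined
  phrase; split-design metrics depend on it.
* PLS1 only (one response at a time), matching the per-element modeling
  design; no PLS2.
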